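## shared fixtures, built in code

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
})

## tiny annotation: genes on one or two chromosomes, evenly spaced
makeTestAnnotation <- function(nGenes = 5, spacing = 10000,
                               geneLen = 4000, chromLen = 1e6,
                               strand = rep("+", nGenes),
                               chrom = rep("chr1", nGenes)) {
    st <- (seq_len(nGenes) - 1L) * spacing + 1001L
    en <- st + geneLen - 1L
    si <- Seqinfo(unique(chrom), rep(chromLen, length(unique(chrom))))
    span <- GRanges(chrom, IRanges(st, en), strand = strand, seqinfo = si)
    names(span) <- sprintf("g%02d", seq_len(nGenes))
    exl <- GRangesList(lapply(seq_len(nGenes), function(i) {
        GRanges(chrom[i],
                IRanges(c(st[i], en[i] - 499L), c(st[i] + 499L, en[i])),
                strand = strand[i], seqinfo = si)
    }))
    names(exl) <- names(span)
    makeGenomeAnnotation(span, exl)
}

## MethylationCalls from a plain table
makeTestMeth <- function(chrom, pos, meth, cov, condition = "parental") {
    o <- order(chrom, pos)
    gr <- GRanges(chrom[o], IRanges(pos[o], width = 1L))
    mcols(gr) <- DataFrame(meth = meth[o], coverage = as.integer(cov[o]))
    new("MethylationCalls", calls = gr, condition = condition)
}

makeTestPeaks <- function(starts, ends, chrom = "chr1", mark = "H3K27ac",
                          condition = "parental", replicate = "1") {
    chrom <- rep(chrom, length.out = length(starts))
    o <- order(chrom, starts)
    gr <- GRanges(chrom[o], IRanges(starts[o], ends[o]))
    new("PeakSet", peaks = gr, mark = mark, condition = condition,
        replicate = replicate)
}

## random interval set for property tests
randomRanges <- function(n, chroms = c("chr1", "chr2"), maxPos = 50000,
                         maxWidth = 300) {
    st <- sample.int(maxPos, n, replace = TRUE)
    w <- sample.int(maxWidth, n, replace = TRUE)
    GRanges(sample(chroms, n, replace = TRUE), IRanges(st, st + w - 1L))
}

## small, fast generator config for structural tests
smallConfig <- function(seed = 7, ...) {
    syntheticConfig(seed = seed, nChroms = 2, chromLength = 2.5e6,
                    nGenes = 400, nDerepressed = 30, nUp = 24, nDown = 40,
                    nNotExpressed = 20, nCommonEnhancers = 60,
                    nUniqueAEnhancers = 30, nUniqueBExtra = 40, ...)
}

## the default-scale bundle is expensive; build it once per test run
.fixtureEnv <- new.env(parent = emptyenv())

defaultBundle <- function(seed = 1) {
    key <- paste0("bundle", seed)
    if (is.null(.fixtureEnv[[key]]))
        .fixtureEnv[[key]] <- simulateEpigenome(syntheticConfig(seed = seed))
    .fixtureEnv[[key]]
}

smallBundle <- function(seed = 7) {
    key <- paste0("small", seed)
    if (is.null(.fixtureEnv[[key]]))
        .fixtureEnv[[key]] <- simulateEpigenome(smallConfig(seed = seed))
    .fixtureEnv[[key]]
}
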