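#' Read per-CpG methylation calls
#'
#' Reads a 4-column, headerless, bedGraph-like TSV: chromosome, position,
#' methylation (fraction in `[0,1]` or percent in `[0,100]`, declared via
#' `dialect`, never guessed), and read coverage. Coverage-0 rows are
#' retained; they are dropped later by the coverage filter of
#' [aggregateRegionMethylation()].
#'
#' @param path Input TSV.
#' @param condition Condition label stored on the object.
#' @param dialect `"fraction"` or `"percent"`.
#' @param zeroBased Are positions 0-based (bedGraph convention)? Default
#'   FALSE: positions are taken as 1-based.
#' @return A [MethylationCalls].
#' @export
readMethylation <- function(path, condition,
                            dialect = c("fraction", "percent"),
                            zeroBased = FALSE) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) .stopf("methylation file not found: %s", path)
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("chrom", "pos", "meth", "cov"),
                             colClasses = c("character", "integer",
                                            "numeric", "integer"))
    hi <- if (dialect == "percent") 100 else 1
    bad <- which(tab$meth < 0 | tab$meth > hi)
    if (length(bad))
        .stopf("%s line %d: methylation value %s outside [0, %s]",
               path, bad[1], format(tab$meth[bad[1]]), format(hi))
    dup <- which(duplicated(paste(tab$chrom, tab$pos)))
    if (length(dup))
        .stopf("%s line %d: duplicate position %s:%d",
               path, dup[1], tab$chrom[dup[1]], tab$pos[dup[1]])
    if (any(tab$cov < 0))
        .stopf("%s: negative coverage", path)
    meth <- if (dialect == "percent") tab$meth / 100 else tab$meth
    pos <- if (zeroBased) tab$pos + 1L else tab$pos
    gr <- GRanges(tab$chrom, IRanges(pos, width = 1L))
    mcols(gr) <- DataFrame(meth = meth, coverage = as.integer(tab$cov))
    gr <- .sortGR(gr)
    new("MethylationCalls", calls = gr, condition = condition)
}

#' Write methylation calls in the format readMethylation() reads
#' @param meth A [MethylationCalls].
#' @param path Output TSV.
#' @param dialect `"fraction"` or `"percent"`.
#' @return `path`, invisibly.
#' @export
writeMethylation <- function(meth, path,
                             dialect = c("fraction", "percent")) {
    dialect <- match.arg(dialect)
    gr <- methCalls(meth)
    val <- mcols(gr)$meth
    if (dialect == "percent") val <- val * 100
    utils::write.table(
        data.frame(chrom = as.character(seqnames(gr)), pos = start(gr),
                   meth = signif(val, 7), cov = mcols(gr)$coverage),
        path, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
    invisible(path)
}

#' Region-level methylation: unweighted mean over covered CpGs
#'
#' For every region, the mean methylated fraction over the CpGs that fall
#' inside it and pass the coverage filter (the study used all CpGs with at
#' least 3x sequencing coverage). Regions with no qualifying CpG get `NA`.
#' The mean is unweighted across CpGs by default, matching a mean-of-ratios
#' summarization; set `weighted = TRUE` for a coverage-weighted mean.
#'
#' @param meth A [MethylationCalls].
#' @param regions `GRanges` of regions to summarize.
#' @param minCoverage Minimum read coverage for a CpG to be used (default 3).
#' @param weighted Coverage-weight the mean? Default FALSE.
#' @return A [S4Vectors::DataFrame] along `regions` with `mean_meth`
#'   (numeric, NA when no CpG qualifies) and `n_cpgs_used` (integer).
#' @export
aggregateRegionMethylation <- function(meth, regions, minCoverage = 3,
                                       weighted = FALSE) {
    stopifnot(minCoverage >= 1)
    gr <- methCalls(meth)
    keep <- mcols(gr)$coverage >= minCoverage
    gr <- gr[keep]
    ab <- .sharedLevels(regions, gr)
    regions <- ab$a; gr <- ab$b
    hits <- GenomicRanges::findOverlaps(regions, gr, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    n <- length(regions)
    cnt <- tabulate(q, nbins = n)
    m <- mcols(gr)$meth[s]
    if (weighted) {
        w <- mcols(gr)$coverage[s]
        num <- rep(0, n); den <- rep(0, n)
        if (length(q)) {
            num <- unname(rowsum(m * w, q, reorder = TRUE))
            den <- unname(rowsum(w + 0, q, reorder = TRUE))
            mean_meth <- rep(NA_real_, n)
            mean_meth[sort(unique(q))] <- num / den
        } else mean_meth <- rep(NA_real_, n)
    } else {
        mean_meth <- rep(NA_real_, n)
        if (length(q)) {
            sums <- rowsum(m, q, reorder = TRUE)
            idx <- sort(unique(q))
            mean_meth[idx] <- sums / cnt[idx]
        }
    }
    DataFrame(mean_meth = as.numeric(mean_meth),
              n_cpgs_used = as.integer(cnt))
}

#' Median methylation per genomic compartment in two conditions
#'
#' Summarizes promoters (-100..+700 around the TSS), gene bodies (the full
#' gene span) and supplied random regions in a parental and a derived
#' methylome: region means via [aggregateRegionMethylation()], then the
#' median over regions with data.
#'
#' @param parental,derived [MethylationCalls] for the two conditions.
#' @param ann A [GenomeAnnotation].
#' @param randomRegions `GRanges`, e.g. from [sampleRandomRegions()].
#' @param minCoverage Coverage filter, default 3.
#' @param upstream,downstream Promoter window extents, defaults 100/700.
#' @return A 2x3 matrix of medians (fractions), rows = conditions, columns =
#'   `promoters`, `gene_bodies`, `random`.
#' @export
compartmentMedians <- function(parental, derived, ann, randomRegions,
                               minCoverage = 3, upstream = 100,
                               downstream = 700) {
    regs <- list(promoters = promoterWindows(ann, upstream, downstream),
                 gene_bodies = geneRanges(ann),
                 random = randomRegions)
    out <- matrix(NA_real_, 2, 3,
                  dimnames = list(c(conditionLabel(parental),
                                    conditionLabel(derived)),
                                  names(regs)))
    for (j in seq_along(regs)) {
        for (i in 1:2) {
            m <- aggregateRegionMethylation(
                if (i == 1) parental else derived, regs[[j]], minCoverage)
            v <- m$mean_meth[!is.na(m$mean_meth)]
            if (!length(v))
                .stopf("compartment '%s' has no region with covered CpGs",
                       names(regs)[j])
            out[i, j] <- stats::median(v)
        }
    }
    out
}

#' Classify promoter methylation as high or low
#'
#' A promoter is `high` when its mean methylation strictly exceeds the
#' threshold (the study called promoters with average methylation greater
#' than 50% highly methylated); `NA` inputs propagate as `"missing"`.
#'
#' @param meanMeth Numeric vector of promoter mean methylation fractions.
#' @param threshold Strict threshold in (0,1), default 0.5.
#' @return Character vector: `"high"`, `"low"` or `"missing"`.
#' @export
classifyPromoterMethylation <- function(meanMeth, threshold = 0.5) {
    stopifnot(threshold > 0, threshold < 1)
    ifelse(is.na(meanMeth), "missing",
           ifelse(meanMeth > threshold, "high", "low"))
}

#' Binned methylation profile around anchor positions
#'
#' Averages methylation in fixed-width bins of strand-oriented offset around
#' a set of anchors (HOMER-style ratio profile: +/- `flank` bp in `bin`-bp
#' bins). The offset of a CpG is its position minus the anchor on `+`
#' anchors and the reverse on `-` anchors; a bin averages all (anchor, CpG)
#' pairs whose offset falls inside it, so a CpG near two anchors contributes
#' twice. Empty bins are `NA`.
#'
#' @param meth A [MethylationCalls].
#' @param anchors Width-1 `GRanges` with strand (`*` is treated as `+`).
#' @param flank Half-window in bp (default 2500); must be divisible by
#'   `bin`.
#' @param bin Bin width in bp (default 100).
#' @param minCoverage Coverage filter, default 3.
#' @return A `data.frame` with `offset_start`, `offset_end` (half-open
#'   offset bins), `mean_meth` and `n_pairs`, with `2 * flank / bin` rows.
#' @export
methylationProfile <- function(meth, anchors, flank = 2500, bin = 100,
                               minCoverage = 3) {
    if (flank %% bin != 0) .stopf("flank must be divisible by bin")
    gr <- methCalls(meth)
    gr <- gr[mcols(gr)$coverage >= minCoverage]
    nb <- 2L * flank / bin
    starts <- seq(-flank, flank - bin, by = bin)
    ## generous symmetric window, then exact offset filter
    win <- GRanges(seqnames(anchors),
                   IRanges(pmax(start(anchors) - flank, 1L),
                           start(anchors) + flank),
                   seqinfo = seqinfo(anchors))
    ab <- .sharedLevels(win, gr)
    win <- ab$a; gr <- ab$b
    hits <- GenomicRanges::findOverlaps(win, gr, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    minus <- as.character(strand(anchors))[q] == "-"
    off <- ifelse(minus, start(anchors)[q] - start(gr)[s],
                  start(gr)[s] - start(anchors)[q])
    keep <- off >= -flank & off < flank
    off <- off[keep]; s <- s[keep]
    idx <- floor(off / bin) + flank / bin + 1L
    mean_meth <- rep(NA_real_, nb)
    n_pairs <- tabulate(idx, nbins = nb)
    if (length(idx)) {
        sums <- rowsum(mcols(gr)$meth[s], idx, reorder = TRUE)
        present <- sort(unique(idx))
        mean_meth[present] <- sums / n_pairs[present]
    }
    data.frame(offset_start = starts, offset_end = starts + bin,
               mean_meth = mean_meth, n_pairs = n_pairs)
}

#' Sample random fixed-length regions from a genome
#'
#' Uniform over the genome: each region's chromosome is drawn with
#' probability proportional to its length (minus the region length), and its
#' start uniformly within bounds. Reproducible for a given `seed`; the
#' caller's RNG state is untouched.
#'
#' @param chromSizes Named vector of chromosome lengths (or a `Seqinfo`).
#' @param n Number of regions (> 0).
#' @param width Region length in bp (default 10000, the fixed length used
#'   for the random-region compartment).
#' @param seed Optional integer seed.
#' @return A `GRanges` of `n` regions.
#' @export
sampleRandomRegions <- function(chromSizes, n, width = 10000, seed = NULL) {
    if (is(chromSizes, "Seqinfo"))
        chromSizes <- stats::setNames(
            GenomeInfoDb::seqlengths(chromSizes),
            GenomeInfoDb::seqnames(chromSizes))
    if (n <= 0) .stopf("n must be positive")
    if (any(width > chromSizes))
        .stopf("region length %d exceeds a chromosome length", width)
    .withSeed(seed, {
        room <- chromSizes - width + 1
        chr <- sample(names(chromSizes), n, replace = TRUE,
                      prob = room / sum(room))
        st <- floor(stats::runif(n, 1, room[chr] + 1))
        GRanges(chr, IRanges(as.integer(st), width = as.integer(width)),
                seqinfo = Seqinfo(names(chromSizes),
                                  unname(as.integer(chromSizes))))
    })
}
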