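#' Read a BED3+/BED6 peak file into a PeakSet
#'
#' @param path BED file (0-based half-open on disk; converted on read).
#' @param mark One of `H3K4me3`, `H3K27ac`, `H3K4me1`, `RNAPII`.
#' @param condition Condition label.
#' @param replicate Replicate identifier (default `"1"`).
#' @return A [PeakSet].
#' @export
readPeaks <- function(path, mark, condition, replicate = "1") {
    if (!file.exists(path)) .stopf("peak file not found: %s", path)
    gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                   error = function(e)
                       .stopf("failed to parse BED %s: %s", path,
                              conditionMessage(e)))
    strand(gr) <- "*"
    new("PeakSet", peaks = .sortGR(granges(gr, use.mcols = TRUE)),
        mark = mark, condition = condition, replicate = replicate)
}

#' Write a PeakSet (or GRanges) as BED
#' @param peaks A [PeakSet] or `GRanges`.
#' @param path Output BED file.
#' @return `path`, invisibly.
#' @export
writePeaks <- function(peaks, path) {
    gr <- if (is(peaks, "PeakSet")) peakRanges(peaks) else peaks
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr))
    nm <- names(gr)
    if (!is.null(nm)) df$name <- nm
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Replicate-consensus peaks
#'
#' Keeps the replicate-1 peaks that overlap at least one replicate-2 peak
#' (only peaks present in both replicates are used downstream). Replicate-1
#' coordinates are retained, preserving peak identity; set
#' `coordinates = "intersection"` to take the overlapped portion instead.
#'
#' @param rep1,rep2 [PeakSet]s with the same mark and condition.
#' @param coordinates `"rep1"` (default) or `"intersection"`.
#' @return A [PeakSet] (replicate label `"consensus"`).
#' @export
consensusPeaks <- function(rep1, rep2,
                           coordinates = c("rep1", "intersection")) {
    coordinates <- match.arg(coordinates)
    if (rep1@mark != rep2@mark || rep1@condition != rep2@condition)
        .stopf("replicates disagree: %s/%s vs %s/%s",
               rep1@mark, rep1@condition, rep2@mark, rep2@condition)
    a <- peakRanges(rep1); b <- peakRanges(rep2)
    keep <- rangesOverlap(a, b)
    out <- a[keep]
    if (coordinates == "intersection" && length(out)) {
        redb <- GenomicRanges::reduce(b, ignore.strand = TRUE)
        hits <- GenomicRanges::findOverlaps(out, redb,
                                            ignore.strand = TRUE)
        q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
        ## span of the overlapped portion, one range per kept rep1 peak
        st <- tapply(pmax(start(out)[q], start(redb)[s]), q, min)
        en <- tapply(pmin(end(out)[q], end(redb)[s]), q, max)
        out <- GRanges(seqnames(out), IRanges(as.integer(st),
                                              as.integer(en)),
                       seqinfo = seqinfo(out))
    }
    new("PeakSet", peaks = out, mark = rep1@mark,
        condition = rep1@condition, replicate = "consensus")
}

## TSS-proximity windows: +/- window bp around every TSS, both boundary
## bases included
.tssWindows <- function(ann, window) {
    g <- geneRanges(ann)
    tss <- mcols(g)$tss
    .grClamped(seqnames(g), tss - window, tss + window, seqinfo(g))
}

#' Split peaks into promoter-proximal and promoter-distal
#'
#' A peak is proximal when it overlaps the +/- `window` bp window around any
#' TSS (the study used +/- 2 kb) and distal otherwise; the split is an
#' exhaustive, disjoint partition.
#'
#' @param peaks A [PeakSet].
#' @param ann A [GenomeAnnotation].
#' @param window Half-window in bp, default 2000.
#' @return List with [PeakSet] elements `proximal` and `distal`.
#' @export
splitByTssProximity <- function(peaks, ann, window = 2000) {
    stopifnot(window > 0)
    gr <- peakRanges(peaks)
    prox <- if (length(geneRanges(ann)))
        rangesOverlap(gr, .tssWindows(ann, window))
    else rep(FALSE, length(gr))
    mk <- function(x) new("PeakSet", peaks = x, mark = peaks@mark,
                          condition = peaks@condition,
                          replicate = peaks@replicate)
    list(proximal = mk(gr[prox]), distal = mk(gr[!prox]))
}

#' Define enhancers as promoter-distal H3K27ac peaks
#'
#' @param h3k27ac A consensus H3K27ac [PeakSet].
#' @param ann A [GenomeAnnotation].
#' @param window TSS proximity half-window, default 2000.
#' @return A [PeakSet] of enhancers (the distal part of the split).
#' @export
defineEnhancers <- function(h3k27ac, ann, window = 2000) {
    if (h3k27ac@mark != "H3K27ac")
        .stopf("enhancers are defined from H3K27ac peaks, got %s",
               h3k27ac@mark)
    splitByTssProximity(h3k27ac, ann, window)$distal
}

#' Compare two enhancer sets: common and condition-unique enhancers
#'
#' An A-enhancer overlapping at least one B-enhancer is common (reported in
#' A's coordinates, with the number of matched B-enhancers in
#' `n_b_matches`); the rest are unique to A, and symmetrically for B. The
#' count of B-enhancers overlapping A (the B-side common count, which can
#' differ when overlaps are many-to-one) is kept in
#' `metadata(common)$n_common_b`.
#'
#' @param a,b Enhancer [PeakSet]s (e.g. from [defineEnhancers()]).
#' @return An [EnhancerComparison].
#' @export
compareEnhancers <- function(a, b) {
    ga <- peakRanges(a); gb <- peakRanges(b)
    hitsA <- rangesOverlap(ga, gb)
    hitsB <- rangesOverlap(gb, ga)
    common <- ga[hitsA]
    mcols(common)$n_b_matches <- unname(
        GenomicRanges::countOverlaps(.sharedLevels(common, gb)$a,
                                     .sharedLevels(common, gb)$b,
                                     ignore.strand = TRUE))
    metadata(common)$n_common_b <- sum(hitsB)
    new("EnhancerComparison", common = common, uniqueA = ga[!hitsA],
        uniqueB = gb[!hitsB],
        conditions = c(a@condition, b@condition))
}

#' Genomic compartment of each peak: exonic, intronic or intergenic
#'
#' Labels by the peak midpoint with exon > intron > intergenic precedence:
#' exonic when the midpoint lies in any exon, intronic when it lies in a
#' gene span but not an exon, intergenic otherwise. Using the midpoint gives
#' every peak exactly one label.
#'
#' @param x A `GRanges`, [PeakSet] or [EnhancerComparison].
#' @param ann A [GenomeAnnotation].
#' @return For `GRanges`/[PeakSet]: a character vector of labels. For an
#'   [EnhancerComparison]: the comparison with a `compartment` metadata
#'   column filled on all three sets.
#' @export
annotateCompartment <- function(x, ann) {
    if (is(x, "EnhancerComparison")) {
        for (slot in c("common", "uniqueA", "uniqueB")) {
            gr <- slot(x, slot)
            mcols(gr)$compartment <- annotateCompartment(gr, ann)
            slot(x, slot) <- gr
        }
        return(x)
    }
    gr <- if (is(x, "PeakSet")) peakRanges(x) else x
    mid <- .midpoints(gr)
    exon <- rangesOverlap(mid, unlist(exonRanges(ann)))
    genic <- rangesOverlap(mid, geneRanges(ann))
    ifelse(exon, "exonic", ifelse(genic, "intronic", "intergenic"))
}

#' Parental methylation of compared enhancers
#'
#' Attaches the parental-condition mean methylation (coverage-filtered,
#' unweighted, as in [aggregateRegionMethylation()]) to every enhancer of an
#' [EnhancerComparison]. New (unique-B) enhancers are expected to be more
#' methylated in the parental line than common ones.
#'
#' @param cmp An [EnhancerComparison].
#' @param parental Parental-condition [MethylationCalls].
#' @param minCoverage Coverage filter, default 3.
#' @return The comparison with a `parental_meth` metadata column on all
#'   three sets.
#' @export
enhancerParentalMethylation <- function(cmp, parental, minCoverage = 3) {
    for (slot in c("common", "uniqueA", "uniqueB")) {
        gr <- slot(cmp, slot)
        agg <- aggregateRegionMethylation(parental, gr, minCoverage)
        mcols(gr)$parental_meth <- agg$mean_meth
        slot(cmp, slot) <- gr
    }
    cmp
}

#' Fraction of new enhancers carrying a poised mark in the parental line
#'
#' The fraction of condition-B-unique ("new") enhancers that overlap at
#' least one parental H3K4me1 peak, i.e. that were poised before the loss of
#' DNA methylation.
#'
#' @param newEnhancers `GRanges` or [PeakSet] of new enhancers (non-empty).
#' @param parentalH3K4me1 Parental H3K4me1 [PeakSet] (or `GRanges`).
#' @return A fraction in `[0, 1]`.
#' @export
poisedFraction <- function(newEnhancers, parentalH3K4me1) {
    ne <- if (is(newEnhancers, "PeakSet")) peakRanges(newEnhancers)
          else newEnhancers
    if (!length(ne)) .stopf("newEnhancers must be non-empty")
    k4 <- if (is(parentalH3K4me1, "PeakSet")) peakRanges(parentalH3K4me1)
          else parentalH3K4me1
    mean(rangesOverlap(ne, k4))
}
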