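#' Strand-oriented promoter windows around the TSS
#'
#' The window runs from `upstream` bp 5' of the TSS to `downstream` bp 3' of
#' it, includes the TSS base itself (so its width is
#' `upstream + downstream + 1`), and is clipped to the chromosome bounds.
#' The study's promoter definition is -100 to +700 bp around the TSS.
#'
#' @param ann A [GenomeAnnotation] (or a `GRanges` of genes carrying `tss`
#'   metadata and strand).
#' @param upstream,downstream Non-negative extents in bp; defaults 100/700.
#' @return A `GRanges` named by gene id, parallel to the genes.
#' @examples
#' ## a '+' gene with TSS at 1001 gets the window 901-1701 (width 801)
#' @export
promoterWindows <- function(ann, upstream = 100, downstream = 700) {
    stopifnot(upstream >= 0, downstream >= 0)
    g <- if (is(ann, "GenomeAnnotation")) geneRanges(ann) else ann
    tss <- mcols(g)$tss
    plus <- as.character(strand(g)) == "+"
    st <- ifelse(plus, tss - upstream, tss - downstream)
    en <- ifelse(plus, tss + downstream, tss + upstream)
    win <- .grClamped(seqnames(g), st, en, seqinfo(g),
                      strand = strand(g))
    names(win) <- mcols(g)$gene_id
    mcols(win)$gene_id <- mcols(g)$gene_id
    win
}

#' Do two interval sets overlap by at least one base?
#'
#' Overlap requires a shared base on the same chromosome; intervals that
#' merely abut do not overlap. This is the single overlap rule used for
#' replicate consensus, enhancer comparison and proximity splitting.
#'
#' @param a,b `GRanges`.
#' @return Logical vector along `a`: does each range of `a` overlap any
#'   range of `b`?
#' @export
rangesOverlap <- function(a, b) {
    ab <- .sharedLevels(a, b)
    IRanges::overlapsAny(ab$a, ab$b, type = "any", ignore.strand = TRUE)
}

#' Distance from anchor positions to the nearest interval
#'
#' Distance is 0 when the anchor falls inside a target and otherwise the
#' coordinate gap to the closest interval edge (an anchor one base away from
#' an interval is at distance 1). Only same-chromosome targets are
#' considered; anchors on chromosomes without targets get `NA` distance (the
#' "unreachable" sentinel). Ties are broken by smaller target start, then
#' smaller end, then input order.
#'
#' @param anchors Width-1 `GRanges` (e.g. TSS positions).
#' @param targets Non-empty `GRanges`.
#' @return A [S4Vectors::DataFrame] along `anchors` with columns `distance`
#'   (integer or NA) and `target` (index into `targets` or NA).
#' @export
nearestDistance <- function(anchors, targets) {
    if (length(targets) == 0L) .stopf("targets must be non-empty")
    n <- length(anchors)
    dist <- rep(NA_integer_, n)
    tgt <- rep(NA_integer_, n)
    ab <- .sharedLevels(anchors, targets)
    anchors <- ab$a; targets <- ab$b
    hits <- GenomicRanges::distanceToNearest(anchors, targets,
                                             select = "all",
                                             ignore.strand = TRUE)
    if (length(hits)) {
        qh <- S4Vectors::queryHits(hits)
        th <- S4Vectors::subjectHits(hits)
        d0 <- mcols(hits)$distance
        inside <- start(anchors)[qh] >= start(targets)[th] &
                  start(anchors)[qh] <= end(targets)[th]
        d <- ifelse(inside, 0L, d0 + 1L)
        ## per anchor: min adjusted distance, ties by (start, end, index)
        o <- order(qh, d, start(targets)[th], end(targets)[th], th)
        keep <- !duplicated(qh[o])
        qh <- qh[o][keep]; th <- th[o][keep]; d <- d[o][keep]
        dist[qh] <- as.integer(d)
        tgt[qh] <- th
    }
    DataFrame(distance = dist, target = tgt)
}
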