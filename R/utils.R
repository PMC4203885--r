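# internal helpers

.clip01 <- function(x) pmin(1, pmax(0, x))

## run code with a locally seeded RNG, restoring the caller's RNG state
.withSeed <- function(seed, code) {
    if (is.null(seed)) return(code)
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    code
}

## beta shapes from mean and concentration
.betaShapes <- function(mean, conc) {
    stopifnot(mean > 0, mean < 1, conc > 0)
    c(shape1 = mean * conc, shape2 = (1 - mean) * conc)
}

## beta shapes whose median is `med`, at fixed concentration: bisect the mean
.betaShapesForMedian <- function(med, conc) {
    stopifnot(med > 0, med < 1)
    f <- function(mu) {
        s <- .betaShapes(mu, conc)
        stats::qbeta(0.5, s[1], s[2]) - med
    }
    mu <- stats::uniroot(f, c(0.01, 0.99), tol = 1e-9)$root
    .betaShapes(mu, conc)
}

## midpoint of ranges as width-1 GRanges (floor((start+end)/2))
.midpoints <- function(gr) {
    mid <- floor((start(gr) + end(gr)) / 2)
    GRanges(seqnames(gr), IRanges(mid, width = 1L),
            seqinfo = seqinfo(gr))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## GRanges clamped to chromosome bounds (avoids out-of-bound warnings)
.grClamped <- function(chrom, start, end, si, strand = NULL) {
    sl <- GenomeInfoDb::seqlengths(si)[as.character(chrom)]
    st <- pmax(as.integer(start), 1L)
    en <- as.integer(end)
    en <- ifelse(is.na(sl), en, pmin(en, sl))
    if (is.null(strand))
        GRanges(chrom, IRanges(st, en), seqinfo = si)
    else GRanges(chrom, IRanges(st, en), strand = strand, seqinfo = si)
}

## put two GRanges on the union of their seqlevels so overlap machinery
## does not warn about disjoint sequence universes
.sharedLevels <- function(a, b) {
    lv <- union(seqlevels(a), seqlevels(b))
    if (!identical(seqlevels(a), lv))
        GenomeInfoDb::seqlevels(a) <- lv
    if (!identical(seqlevels(b), lv))
        GenomeInfoDb::seqlevels(b) <- lv
    list(a = a, b = b)
}

## sorted order for GRanges by (chrom, start, end)
.grOrder <- function(gr)
    order(as.integer(seqnames(gr)), start(gr), end(gr))

.sortGR <- function(gr) gr[.grOrder(gr)]
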