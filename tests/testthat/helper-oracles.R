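## brute-force O(n*m) oracles, written independently of the implementation:
## plain loops over data frames in 1-based closed coordinates

grDf <- function(gr) data.frame(chrom = as.character(seqnames(gr)),
                                start = start(gr), end = end(gr))

## distance 0 inside, else gap to nearest edge; ties by (start, end, order)
bfNearest <- function(anchorChrom, anchorPos, targets) {
    n <- length(anchorPos)
    dist <- rep(NA_real_, n); tgt <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
        best <- Inf; bestJ <- NA_integer_
        for (j in seq_len(nrow(targets))) {
            if (targets$chrom[j] != anchorChrom[i]) next
            d <- if (anchorPos[i] >= targets$start[j] &&
                     anchorPos[i] <= targets$end[j]) 0
                 else min(abs(anchorPos[i] - targets$start[j]),
                          abs(anchorPos[i] - targets$end[j]))
            better <- d < best ||
                (d == best && !is.na(bestJ) &&
                 (targets$start[j] < targets$start[bestJ] ||
                  (targets$start[j] == targets$start[bestJ] &&
                   targets$end[j] < targets$end[bestJ])))
            if (better) { best <- d; bestJ <- j }
        }
        if (is.finite(best)) { dist[i] <- best; tgt[i] <- bestJ }
    }
    list(distance = dist, target = tgt)
}

bfOverlapAny <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i)
        any(b$chrom == a$chrom[i] & b$start <= a$end[i] &
            b$end >= a$start[i]), logical(1))
}

## unweighted mean over CpGs with coverage >= minCov inside each region
bfAggregate <- function(cpg, regions, minCov) {
    vapply(seq_len(nrow(regions)), function(r) {
        sel <- cpg$chrom == regions$chrom[r] &
            cpg$pos >= regions$start[r] & cpg$pos <= regions$end[r] &
            cpg$cov >= minCov
        if (!any(sel)) NA_real_ else mean(cpg$meth[sel])
    }, numeric(1))
}

## binned strand-oriented profile
bfProfile <- function(cpg, anchors, flank, bin, minCov) {
    nb <- 2 * flank / bin
    sums <- numeric(nb); cnts <- integer(nb)
    for (i in seq_len(nrow(anchors))) {
        for (j in seq_len(nrow(cpg))) {
            if (cpg$chrom[j] != anchors$chrom[i] || cpg$cov[j] < minCov)
                next
            off <- if (anchors$strand[i] == "-")
                anchors$pos[i] - cpg$pos[j]
            else cpg$pos[j] - anchors$pos[i]
            if (off < -flank || off >= flank) next
            k <- floor(off / bin) + flank / bin + 1
            sums[k] <- sums[k] + cpg$meth[j]
            cnts[k] <- cnts[k] + 1L
        }
    }
    ifelse(cnts > 0, sums / cnts, NA_real_)
}

## rep1 intervals overlapping any rep2 interval
bfConsensus <- function(a, b) which(bfOverlapAny(a, b))

## common/unique partition counts
bfCompare <- function(a, b) {
    ca <- bfOverlapAny(a, b); cb <- bfOverlapAny(b, a)
    list(common_a = sum(ca), unique_a = sum(!ca),
         common_b = sum(cb), unique_b = sum(!cb))
}

## midpoint-in-span counting
bfIntragenic <- function(enh, spans) {
    mids <- floor((enh$start + enh$end) / 2)
    vapply(seq_len(nrow(spans)), function(g)
        sum(enh$chrom == spans$chrom[g] & mids >= spans$start[g] &
            mids <= spans$end[g]), integer(1))
}
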