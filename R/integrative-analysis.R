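#' Do de-repressed promoters gain a new H3K4me3 peak?
#'
#' Partitions a set of de-repressed genes by the H3K4me3 status of their
#' +/- `window` bp promoter window: `gained_new` when the window overlaps a
#' condition-B-unique peak, otherwise `in_common` when it overlaps a common
#' peak, otherwise `neither`. The three groups partition the input.
#'
#' @param genes Character vector of gene ids (the de-repressed set).
#' @param newPeaks [PeakSet] or `GRanges`: promoter-proximal H3K4me3 peaks
#'   unique to condition B.
#' @param commonPeaks [PeakSet] or `GRanges`: H3K4me3 peaks common to both
#'   conditions.
#' @param ann A [GenomeAnnotation].
#' @param window TSS half-window in bp, default 2000.
#' @return List with `status` (named character vector along `genes`) and
#'   `counts` (named integer vector over the three groups).
#' @export
derepressedK4me3Overlap <- function(genes, newPeaks, commonPeaks, ann,
                                    window = 2000) {
    g <- geneRanges(ann)
    sel <- match(genes, mcols(g)$gene_id)
    if (anyNA(sel)) .stopf("unknown gene id(s): %s",
                           paste(head(genes[is.na(sel)], 3), collapse = ", "))
    win <- .tssWindows(ann, window)[sel]
    np <- if (is(newPeaks, "PeakSet")) peakRanges(newPeaks) else newPeaks
    cp <- if (is(commonPeaks, "PeakSet")) peakRanges(commonPeaks)
          else commonPeaks
    gained <- rangesOverlap(win, np)
    common <- !gained & rangesOverlap(win, cp)
    status <- ifelse(gained, "gained_new",
                     ifelse(common, "in_common", "neither"))
    names(status) <- genes
    counts <- c(gained_new = sum(gained), in_common = sum(common),
                neither = sum(!gained & !common))
    list(status = status, counts = counts)
}

#' Distance from gene TSSs to the nearest newly acquired H3K4me3 site
#'
#' For genes whose promoter neither gained nor kept an H3K4me3 peak, how far
#' is the nearest condition-B-unique H3K4me3 site? Reports the per-gene
#' nearest distance, the number of genes with a site within `near` bp
#' (inclusive), and the median distance over reachable genes — a screen for
#' the use of alternative promoters.
#'
#' @param genes Character vector of gene ids.
#' @param newPeaks [PeakSet] or `GRanges` of new H3K4me3 peaks (may be
#'   empty: all genes are then unreachable).
#' @param ann A [GenomeAnnotation].
#' @param near Distance cutoff in bp, default 20000 (inclusive).
#' @return List with `distances` (named integer vector, NA = unreachable),
#'   `n_within` and `median_distance` (NA when no gene is reachable).
#' @export
alternativePromoterScan <- function(genes, newPeaks, ann, near = 20000) {
    g <- geneRanges(ann)
    sel <- match(genes, mcols(g)$gene_id)
    tss <- GRanges(seqnames(g)[sel],
                   IRanges(mcols(g)$tss[sel], width = 1L),
                   seqinfo = seqinfo(g))
    np <- if (is(newPeaks, "PeakSet")) peakRanges(newPeaks) else newPeaks
    if (!length(np)) {
        d <- rep(NA_integer_, length(genes))
    } else {
        d <- nearestDistance(tss, np)$distance
    }
    names(d) <- genes
    list(distances = d,
         n_within = sum(!is.na(d) & d <= near),
         median_distance = if (all(is.na(d))) NA_real_
                           else stats::median(d[!is.na(d)]))
}

#' TSS distance to the nearest enhancer of each category
#'
#' For every gene, the distance from its TSS to the nearest common,
#' unique-A and unique-B enhancer, with per-category summaries: the fraction
#' of genes with an enhancer within `near` bp (inclusive; over all genes in
#' the set) and the median distance over reachable genes.
#'
#' @param genes Character vector of gene ids.
#' @param cmp An [EnhancerComparison].
#' @param ann A [GenomeAnnotation].
#' @param near Cutoff in bp, default 20000.
#' @return List with `distances` (DataFrame: gene_id, common, unique_a,
#'   unique_b) and `summary` (data.frame per category: `frac_within`,
#'   `median_distance`).
#' @export
geneEnhancerDistances <- function(genes, cmp, ann, near = 20000) {
    g <- geneRanges(ann)
    sel <- match(genes, mcols(g)$gene_id)
    if (anyNA(sel)) .stopf("unknown gene id(s)")
    tss <- GRanges(seqnames(g)[sel],
                   IRanges(mcols(g)$tss[sel], width = 1L),
                   seqinfo = seqinfo(g))
    sets <- list(common = cmp@common, unique_a = cmp@uniqueA,
                 unique_b = cmp@uniqueB)
    dists <- lapply(sets, function(s) {
        if (!length(s)) rep(NA_integer_, length(genes))
        else nearestDistance(tss, s)$distance
    })
    summ <- data.frame(
        category = names(sets),
        frac_within = vapply(dists, function(d)
            if (!length(genes)) 0
            else sum(!is.na(d) & d <= near) / length(genes), numeric(1)),
        median_distance = vapply(dists, function(d)
            if (all(is.na(d))) NA_real_
            else stats::median(as.numeric(d[!is.na(d)])), numeric(1)),
        row.names = NULL)
    list(distances = DataFrame(gene_id = genes,
                               common = dists$common,
                               unique_a = dists$unique_a,
                               unique_b = dists$unique_b),
         summary = summ)
}

#' Count intragenic enhancers per gene
#'
#' An enhancer belongs to a gene when its midpoint lies within the gene
#' span. Counts are reported per gene and per comparison category, with the
#' intronic/exonic sub-split (by the midpoint's exon membership in the
#' assigned gene), a histogram of genes by unique-B enhancer count, and a
#' flag for genes with more than one unique-B enhancer (enhancer
#' "spreading").
#'
#' @param genes Character vector of gene ids.
#' @param cmp An [EnhancerComparison].
#' @param ann A [GenomeAnnotation].
#' @return List with `counts` (DataFrame per gene: common/unique_a/unique_b
#'   counts, `unique_b_intronic`, `unique_b_exonic`, `spreading`),
#'   `histogram` (table of genes by unique-B count) and `totals`
#'   (n unique-B intragenic enhancers, intronic, exonic, genes with >= 1).
#' @export
countIntragenicEnhancers <- function(genes, cmp, ann) {
    g <- geneRanges(ann)
    sel <- match(genes, mcols(g)$gene_id)
    if (anyNA(sel)) .stopf("unknown gene id(s)")
    spans <- g[sel]
    exl <- exonRanges(ann)[mcols(spans)$gene_id]
    countCat <- function(enh) {
        if (!length(enh)) return(list(n = integer(length(genes)),
                                      hits = NULL))
        mid <- .midpoints(enh)
        ab <- .sharedLevels(mid, spans)
        mid <- ab$a
        hits <- GenomicRanges::findOverlaps(mid, ab$b,
                                            ignore.strand = TRUE)
        list(n = unname(GenomicRanges::countOverlaps(ab$b, mid,
                                                     ignore.strand = TRUE)),
             hits = hits, mid = mid)
    }
    cc <- countCat(cmp@common)
    ca <- countCat(cmp@uniqueA)
    cb <- countCat(cmp@uniqueB)
    ## intronic/exonic sub-split for unique-B, by the assigned gene's exons
    intronic <- exonic <- integer(length(genes))
    if (!is.null(cb$hits) && length(cb$hits)) {
        q <- S4Vectors::queryHits(cb$hits)   # enhancer midpoints
        s <- S4Vectors::subjectHits(cb$hits) # gene index within `genes`
        inExon <- vapply(seq_along(q), function(i)
            rangesOverlap(cb$mid[q[i]], exl[[s[i]]]), logical(1))
        exonic <- tabulate(s[inExon], nbins = length(genes))
        intronic <- tabulate(s[!inExon], nbins = length(genes))
    }
    counts <- DataFrame(gene_id = genes, common = cc$n, unique_a = ca$n,
                        unique_b = cb$n,
                        unique_b_intronic = intronic,
                        unique_b_exonic = exonic,
                        spreading = cb$n > 1L)
    list(counts = counts,
         histogram = table(factor(cb$n, levels = 0:max(c(cb$n, 1)))),
         totals = c(unique_b_total = sum(cb$n),
                    unique_b_intronic = sum(intronic),
                    unique_b_exonic = sum(exonic),
                    genes_with_unique_b = sum(cb$n > 0),
                    genes_spreading = sum(cb$n > 1)))
}

#' CpG-island promoters
#'
#' A gene has a CGI promoter when its TSS base lies inside a supplied CpG
#' island interval. Also reports the mean length of the islands that contain
#' at least one TSS of the gene set.
#'
#' @param genes Character vector of gene ids.
#' @param cgi `GRanges` of CpG islands (may be empty: all FALSE).
#' @param ann A [GenomeAnnotation].
#' @return List with `is_cgi` (named logical) and `mean_cgi_length`
#'   (NA when no island contains a TSS).
#' @export
promoterCgiClassification <- function(genes, cgi, ann) {
    g <- geneRanges(ann)
    sel <- match(genes, mcols(g)$gene_id)
    if (anyNA(sel)) .stopf("unknown gene id(s)")
    tss <- GRanges(seqnames(g)[sel],
                   IRanges(mcols(g)$tss[sel], width = 1L),
                   seqinfo = seqinfo(g))
    if (!length(cgi)) {
        flags <- rep(FALSE, length(genes))
        len <- NA_real_
    } else {
        flags <- rangesOverlap(tss, cgi)
        withTss <- rangesOverlap(cgi, tss)
        len <- if (any(withTss)) mean(width(cgi[withTss])) else NA_real_
    }
    list(is_cgi = stats::setNames(flags, genes), mean_cgi_length = len)
}

#' Scan promoter sequences for a degenerate TATA box
#'
#' Searches the sense strand for the degenerate motif (default `TATAWAW`,
#' W = A/T) allowing up to `maxMismatch` mismatches, with the motif start
#' constrained to a window of offsets relative to the TSS (default -40 to
#' -20; sequences are aligned so that their last base is the TSS, offset 0).
#' An `N` in the sequence matches nothing.
#'
#' @param seqs A [Biostrings::DNAStringSet] (or character vector) of
#'   promoter sequences ending at the TSS.
#' @param motif Degenerate motif, default `"TATAWAW"`.
#' @param maxMismatch Allowed mismatches, default 1.
#' @param window Integer length-2: allowed motif-start offsets, default
#'   `c(-40, -20)`.
#' @return A `data.frame` with `has_tata`, `best_offset` (NA when absent)
#'   and `mismatches`.
#' @export
tataScan <- function(seqs, motif = "TATAWAW", maxMismatch = 1,
                     window = c(-40, -20)) {
    if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
    pat <- Biostrings::DNAString(motif)
    k <- length(pat)
    lo <- min(window); hi <- max(window)
    need <- -lo + 1L
    out <- data.frame(has_tata = logical(length(seqs)),
                      best_offset = NA_integer_,
                      mismatches = NA_integer_)
    rownames(out) <- names(seqs)
    for (i in seq_along(seqs)) {
        s <- seqs[[i]]
        L <- length(s)
        if (L < need)
            .stopf("sequence %d too short (%d bp) to cover offset %d",
                   i, L, lo)
        starts <- (L + lo):(L + hi)      # motif-start string positions
        starts <- starts[starts >= 1 & starts + k - 1L <= L]
        mm <- vapply(starts, function(st)
            Biostrings::neditStartingAt(pat, s, starting.at = st,
                                        fixed = "subject"),
            integer(1))
        ok <- mm <= maxMismatch
        if (any(ok)) {
            best <- which(mm == min(mm))[1]
            out$has_tata[i] <- TRUE
            out$best_offset[i] <- starts[best] - L
            out$mismatches[i] <- mm[best]
        }
    }
    out
}
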