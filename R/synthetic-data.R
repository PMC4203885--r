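#' Configuration for the synthetic epigenome generator
#'
#' Defaults encode the statistical structure the generator emulates: a
#' bimodal parental promoter methylome whose median region mean is 30%
#' methylation, gene-body and background methylation with median 84%,
#' residual methylation in the demethylated condition (promoter median
#' 0.5%, gene body 13%, random regions 9%), condition-unique distal H3K27ac
#' enhancers preferentially planted inside up-regulated genes (47% of the
#' new ones pre-marked with parental H3K4me1), and expression classes with
#' replicate noise. Desk scale is 2 chromosomes x 10 Mb and 2,000 genes
#' (roughly 2e5 CpGs), keeping every class populated while running in
#' seconds.
#'
#' @param seed Integer seed; the whole bundle is reproducible from it.
#' @param nChroms,chromLength,nGenes Genome scale; `nGenes` must be a
#'   multiple of `nChroms`.
#' @param cpgDensity CpGs per bp (uniform), default 0.01.
#' @param promoterMeth List: `lowMean`, `highMean` (beta mode means,
#'   defaults 0.03/0.90), `lowConc`, `highConc` (concentrations), `target`
#'   (median promoter region mean, default 0.30). The high-mode weight is
#'   calibrated analytically by [calibrateMixture()].
#' @param bodyMethMedian,randomMethMedian Parental target medians for gene
#'   bodies and random regions (defaults 0.84).
#' @param derivedTargets Named fractions `promoter`, `body`, `random`:
#'   target medians in the demethylated condition (defaults 0.005, 0.13,
#'   0.09).
#' @param coverageMean Poisson mean of per-CpG read coverage (default 10, so
#'   the 3x coverage filter is exercised by a ~1% tail).
#' @param nDerepressed,nUp,nDown,nNotExpressed Planted class sizes
#'   (defaults 120/80/160/100 of 2,000; remaining genes are unchanged).
#' @param fracUpWithIntragenic Fraction of up genes hosting new intragenic
#'   enhancers (default 0.40).
#' @param fracSpreading Among hosts, fraction carrying 2-5 new enhancers
#'   rather than one (default 0.59).
#' @param exonicEnhancerFrac Fraction of intragenic enhancers whose midpoint
#'   is exonic (default 0.08).
#' @param fracNewEnhancersPoised Fraction of new (B-unique) enhancers given
#'   a parental H3K4me1 peak (default 0.47).
#' @param fracDerepressedNewK4me3 Fraction of de-repressed genes gaining a
#'   B-unique promoter H3K4me3 peak (default 0.40).
#' @param fracDerepressedCommonK4me3 Among the non-gaining de-repressed
#'   genes, fraction whose promoter carries a common H3K4me3 peak
#'   (default 0.13).
#' @param nCommonEnhancers,nUniqueAEnhancers,nUniqueBExtra Distal enhancer
#'   counts besides the host-gene plantings (defaults 300/150/210).
#' @param enhancerWidth Length-2 range of enhancer widths in bp.
#' @param nReplicates Expression replicates per condition (default 2).
#' @param replicateNoiseSd Lognormal replicate noise sd on the log2 scale
#'   (default 0.1).
#' @param peakJitter Max per-edge jitter of replicate-2 peaks in bp
#'   (default 25; replicate 1 carries the planted coordinates).
#' @param cpgNoiseSd Per-CpG additive noise sd around the regional
#'   methylation level (default 0.04).
#' @param cgiFrac,tataFrac Named fractions of CGI / TATA promoters per class
#'   (`de_repressed`, `up`, `down`, `other`).
#' @param conditions Length-2 condition labels.
#' @return A validated config list of class `demethylscope_config`.
#' @export
syntheticConfig <- function(seed = 1,
                            nChroms = 2,
                            chromLength = 1e7,
                            nGenes = 2000,
                            cpgDensity = 0.01,
                            promoterMeth = list(lowMean = 0.03,
                                                highMean = 0.90,
                                                lowConc = 4,
                                                highConc = 1.2,
                                                target = 0.30),
                            bodyMethMedian = 0.84,
                            randomMethMedian = 0.84,
                            derivedTargets = c(promoter = 0.005,
                                               body = 0.13,
                                               random = 0.09),
                            coverageMean = 10,
                            nDerepressed = 120,
                            nUp = 80,
                            nDown = 160,
                            nNotExpressed = 100,
                            fracUpWithIntragenic = 0.40,
                            fracSpreading = 0.59,
                            exonicEnhancerFrac = 0.08,
                            fracNewEnhancersPoised = 0.47,
                            fracDerepressedNewK4me3 = 0.40,
                            fracDerepressedCommonK4me3 = 0.13,
                            nCommonEnhancers = 300,
                            nUniqueAEnhancers = 150,
                            nUniqueBExtra = 210,
                            enhancerWidth = c(500, 700),
                            nReplicates = 2,
                            replicateNoiseSd = 0.1,
                            peakJitter = 25,
                            cpgNoiseSd = 0.04,
                            cgiFrac = c(de_repressed = 0.58, up = 0.75,
                                        down = 0.83, other = 0.60),
                            tataFrac = c(de_repressed = 0.10, up = 0.10,
                                         down = 0.07, other = 0.08),
                            conditions = c("parental", "demethylated")) {
    cfg <- as.list(environment())
    class(cfg) <- "demethylscope_config"
    .validateConfig(cfg)
    cfg
}

.validateConfig <- function(cfg) {
    with(cfg, {
        fr <- c(cpgDensity, fracUpWithIntragenic, fracSpreading,
                exonicEnhancerFrac, fracNewEnhancersPoised,
                fracDerepressedNewK4me3, fracDerepressedCommonK4me3,
                derivedTargets, cgiFrac, tataFrac)
        if (any(fr < 0 | fr > 1))
            .stopf("config fractions must lie in [0, 1]")
        if (nGenes %% nChroms != 0)
            .stopf("nGenes must be a multiple of nChroms")
        if (nDerepressed + nUp + nDown + nNotExpressed > nGenes)
            .stopf("class sizes exceed nGenes")
        if (any(c(nGenes, nChroms, chromLength, coverageMean,
                  nReplicates) <= 0))
            .stopf("counts must be positive")
        if (nReplicates < 2)
            .stopf("at least 2 expression replicates per condition")
        slot <- floor(chromLength / (nGenes / nChroms))
        if (slot < 6000)
            .stopf("infeasible config: only %d bp per gene (need >= 6000)",
                   slot)
        if (length(conditions) != 2L)
            .stopf("exactly two condition labels required")
        invisible(TRUE)
    })
}

#' Calibrate the high-mode weight of a two-beta methylation mixture
#'
#' Finds the mixture weight of the high mode such that the analytic median
#' of `(1-w) * Beta(lowMean, lowConc) + w * Beta(highMean, highConc)` equals
#' `targetMedian` (to within `tol`). The weight is clamped to 0 (or 1) when
#' the target is at or below the low mode's median (at or above the high
#' mode's); targets outside `(0, 1)` or outside the attainable range are an
#' error.
#'
#' @param targetMedian Target median of the mixture, in (0, 1).
#' @param lowMean,highMean Mode means (defaults 0.03 and 0.90).
#' @param lowConc,highConc Beta concentrations (defaults 4 and 1.2).
#' @param tol Median tolerance, default 1e-4.
#' @return The high-mode weight in `[0, 1]`.
#' @export
calibrateMixture <- function(targetMedian, lowMean = 0.03, highMean = 0.90,
                             lowConc = 4, highConc = 1.2, tol = 1e-4) {
    if (targetMedian <= 0 || targetMedian >= 1)
        .stopf("targetMedian must lie in (0, 1)")
    if (lowMean >= highMean) .stopf("lowMean must be < highMean")
    sl <- .betaShapes(lowMean, lowConc)
    sh <- .betaShapes(highMean, highConc)
    medOf <- function(w) {
        f <- function(m) (1 - w) * stats::pbeta(m, sl[1], sl[2]) +
            w * stats::pbeta(m, sh[1], sh[2]) - 0.5
        stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = tol / 10)$root
    }
    if (targetMedian <= stats::qbeta(0.5, sl[1], sl[2]) + tol) return(0)
    if (targetMedian >= stats::qbeta(0.5, sh[1], sh[2]) - tol) return(1)
    stats::uniroot(function(w) medOf(w) - targetMedian, c(0, 1),
                   tol = 1e-7)$root
}

## monotone step-function bisection: smallest x in [lo, hi] with
## f(x) >= target (f nondecreasing); boundary-clamped
.bisect <- function(f, lo, hi, target, iters = 45) {
    if (f(hi) <= target) return(hi)
    if (f(lo) >= target) return(lo)
    for (i in seq_len(iters)) {
        mid <- (lo + hi) / 2
        if (f(mid) < target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
}

## stratified quantiles of Beta(shapes), randomly permuted
.stratBeta <- function(n, shapes) {
    if (n == 0L) return(numeric())
    sample(stats::qbeta((seq_len(n) - 0.5) / n, shapes[1], shapes[2]))
}

#' Generate a synthetic paired-condition epigenome
#'
#' Builds a complete, internally consistent input bundle with planted
#' ground-truth labels: gene models on evenly spaced slots, a bimodal
#' parental promoter methylome (per-mode stratified beta quantiles, so the
#' configured compartment medians are hit at desk scale), body and
#' background methylation calibrated to the configured parental medians,
#' a demethylated condition obtained by per-compartment scaling calibrated
#' to the configured residual medians (never exceeding the parental value
#' at any CpG), replicated peak sets for four marks in two conditions,
#' expression with planted classes, CpG islands, promoter sequences with
#' planted TATA boxes, and a tumor-suppressor list. Deterministic given the
#' config seed.
#'
#' @param config A [syntheticConfig()].
#' @return A [SyntheticBundle].
#' @seealso [writeBundle()], [readBundle()]
#' @export
simulateEpigenome <- function(config = syntheticConfig()) {
    .validateConfig(config)
    .withSeed(config$seed, .simulate(config))
}

.simulate <- function(cfg) {
    n <- cfg$nGenes
    nCh <- cfg$nChroms
    gpc <- n / nCh
    slot <- floor(cfg$chromLength / gpc)
    chroms <- paste0("chr", seq_len(nCh))
    sizes <- stats::setNames(rep(as.integer(cfg$chromLength), nCh), chroms)
    si <- Seqinfo(chroms, unname(sizes))

    ## ---- gene layout -----------------------------------------------------
    chrom <- rep(chroms, each = gpc)
    slotStart <- rep((seq_len(gpc) - 1L) * slot + 1L, nCh)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    cls <- rep("unchanged", n)
    ord <- sample.int(n)
    take <- function(k, what) {
        if (k == 0L) return(integer())
        idx <- ord[seq_len(k)]; ord <<- ord[-seq_len(k)]
        cls[idx] <<- what; idx
    }
    drGenes <- take(cfg$nDerepressed, "de_repressed")
    upGenes <- take(cfg$nUp, "up")
    downGenes <- take(cfg$nDown, "down")
    neGenes <- take(cfg$nNotExpressed, "not_expressed")

    hosts <- sort(sample(upGenes,
                         round(cfg$fracUpWithIntragenic * cfg$nUp)))
    lenMax <- min(8800, slot - 1200)
    len <- round(stats::runif(n, 4000, lenMax))
    len[hosts] <- lenMax
    plus <- strand == "+"
    gStart <- ifelse(plus, slotStart + 600L,
                     slotStart + slot - 600L - len + 1L)
    gEnd <- gStart + len - 1L
    tss <- ifelse(plus, gStart, gEnd)
    ids <- sprintf("G%04d", seq_len(n))
    nms <- sprintf("GENE%04d", seq_len(n))

    ## ---- promoter methylation levels ------------------------------------
    pm <- cfg$promoterMeth
    w <- calibrateMixture(pm$target, pm$lowMean, pm$highMean,
                          pm$lowConc, pm$highConc)
    nHigh <- round(w * n); nLow <- n - nHigh
    shLow <- .betaShapes(pm$lowMean, pm$lowConc)
    shHigh <- .betaShapes(pm$highMean, pm$highConc)
    thHigh <- .stratBeta(nHigh, shHigh)
    thLow <- .stratBeta(nLow, shLow)
    if (nHigh < cfg$nDerepressed)
        .stopf("infeasible config: fewer high-mode promoters than %s",
               "de-repressed genes")
    ## de-repressed genes need convincingly methylated parental promoters
    eligHigh <- which(thHigh >= 0.7)
    if (length(eligHigh) < cfg$nDerepressed)
        eligHigh <- order(thHigh, decreasing = TRUE)[
            seq_len(cfg$nDerepressed)]
    drTheta <- eligHigh[sample.int(length(eligHigh))][
        seq_len(cfg$nDerepressed)]
    restHigh <- setdiff(seq_len(nHigh), drTheta)
    ## remaining high promoters go to silent-in-both genes: the
    ## not_expressed class first, then a draw of unchanged genes
    unchAll <- which(cls == "unchanged")
    highGenes <- c(drGenes, neGenes,
                   unchAll[sample.int(length(unchAll))][
                       seq_len(max(0, nHigh - cfg$nDerepressed -
                                      cfg$nNotExpressed))])
    if (length(highGenes) > nHigh)
        highGenes <- highGenes[seq_len(nHigh)]
    lowGenes <- setdiff(seq_len(n), highGenes)
    eligLow <- which(thLow <= 0.45)
    nUD <- cfg$nUp + cfg$nDown
    if (length(eligLow) < nUD)
        eligLow <- order(thLow)[seq_len(nUD)]
    udTheta <- sample(eligLow, nUD)
    theta <- numeric(n)
    theta[drGenes] <- thHigh[drTheta]
    otherHigh <- setdiff(highGenes, drGenes)
    theta[otherHigh] <- sample(thHigh[restHigh])[
        seq_along(otherHigh)]
    theta[c(upGenes, downGenes)] <- thLow[udTheta]
    otherLow <- setdiff(lowGenes, c(upGenes, downGenes))
    theta[otherLow] <- sample(thLow[-udTheta])[seq_along(otherLow)]

    ## ---- enhancer placement ----------------------------------------------
    ew <- cfg$enhancerWidth
    placed <- list()   # list of lists: chrom, start, end, category,
                       # compartmentPlanted, host (gene index or NA)
    genic <- vector("list", n)   # occupied intervals per gene (absolute)
    slotOcc <- vector("list", n) # occupied intergenic intervals per slot

    zoneOf <- function(i) {
        ## absolute interval where an intragenic enhancer may sit in gene i
        lo <- max(gStart[i], slotStart[i] + 2300L,
                  if (plus[i]) tss[i] + 2300L else gStart[i] + 100L)
        hi <- min(gEnd[i], slotStart[i] + slot - 2300L,
                  if (plus[i]) gEnd[i] - 100L else tss[i] - 2300L)
        c(lo, hi)
    }
    gapOf <- function(i) {
        ## absolute intergenic interval in gene i's slot
        if (plus[i]) c(gEnd[i] + 200L, slotStart[i] + slot - 2300L)
        else c(slotStart[i] + 2300L, gStart[i] - 200L)
    }
    fits <- function(st, en, occ) {
        !length(occ) || all(vapply(occ, function(iv)
            en < iv[1] - 100L || st > iv[2] + 100L, logical(1)))
    }
    tryPlace <- function(zone, occ, width) {
        if (zone[2] - zone[1] + 1L < width) return(NULL)
        for (t in seq_len(30)) {
            st <- floor(stats::runif(1, zone[1], zone[2] - width + 2))
            en <- st + width - 1L
            if (fits(st, en, occ)) return(c(st, en))
        }
        NULL
    }
    addPlaced <- function(ch, st, en, cat, comp, host) {
        placed[[length(placed) + 1L]] <<- list(
            chrom = ch, start = st, end = en, category = cat,
            compartment = comp, host = host)
    }

    ## host-gene plantings (unique-B intragenic), cell-partitioned zones
    kHost <- ifelse(stats::runif(length(hosts)) < cfg$fracSpreading,
                    sample(2:5, length(hosts), replace = TRUE), 1L)
    for (h in seq_along(hosts)) {
        i <- hosts[h]
        z <- zoneOf(i)
        k <- kHost[h]
        cap <- floor((z[2] - z[1] + 1L) / (ew[2] + 100L))
        if (cap < 1L)
            .stopf("infeasible config: no intron space for enhancers %s",
                   sprintf("in gene %s", ids[i]))
        k <- min(k, cap)
        kHost[h] <- k
        cellW <- floor((z[2] - z[1] + 1L) / k)
        for (j in seq_len(k)) {
            width <- round(stats::runif(1, ew[1], ew[2]))
            cz <- c(z[1] + (j - 1L) * cellW,
                    z[1] + j * cellW - 1L)
            st <- floor(stats::runif(1, cz[1],
                                     max(cz[1], cz[2] - width - 50L) + 1))
            en <- st + width - 1L
            comp <- if (stats::runif(1) < cfg$exonicEnhancerFrac)
                "exonic" else "intronic"
            genic[[i]] <- c(genic[[i]], list(c(st, en)))
            addPlaced(chrom[i], st, en, "unique_b", comp, i)
        }
    }

    ## remaining placements: common / unique-A / extra unique-B
    nonHost <- setdiff(seq_len(n), hosts)
    bigEnough <- nonHost[len[nonHost] >= 6500]
    placeOne <- function(cat) {
        comp <- sample(c("intergenic", "intronic", "exonic"), 1,
                       prob = c(0.50, 0.45, 0.05))
        width <- round(stats::runif(1, ew[1], ew[2]))
        for (t in seq_len(60)) {
            if (comp == "intergenic") {
                i <- sample.int(n, 1)
                iv <- tryPlace(gapOf(i), slotOcc[[i]], width)
                if (!is.null(iv)) {
                    slotOcc[[i]] <<- c(slotOcc[[i]], list(iv))
                    addPlaced(chrom[i], iv[1], iv[2], cat, comp, NA_integer_)
                    return(invisible())
                }
            } else {
                i <- bigEnough[sample.int(length(bigEnough), 1)]
                iv <- tryPlace(zoneOf(i), genic[[i]], width)
                if (!is.null(iv)) {
                    genic[[i]] <<- c(genic[[i]], list(iv))
                    addPlaced(chrom[i], iv[1], iv[2], cat, comp, i)
                    return(invisible())
                }
            }
        }
        .stopf("infeasible config: could not place a %s enhancer", cat)
    }
    for (j in seq_len(cfg$nCommonEnhancers)) placeOne("common")
    for (j in seq_len(cfg$nUniqueAEnhancers)) placeOne("unique_a")
    for (j in seq_len(cfg$nUniqueBExtra)) placeOne("unique_b")

    enhDf <- data.frame(
        id = sprintf("ENH%04d", seq_along(placed)),
        chrom = vapply(placed, `[[`, character(1), "chrom"),
        start = vapply(placed, function(p) as.integer(p$start), integer(1)),
        end = vapply(placed, function(p) as.integer(p$end), integer(1)),
        category = vapply(placed, `[[`, character(1), "category"),
        compartment = vapply(placed, `[[`, character(1), "compartment"),
        host = vapply(placed, function(p) as.integer(p$host), integer(1)),
        stringsAsFactors = FALSE)
    enhGR <- GRanges(enhDf$chrom, IRanges(enhDf$start, enhDf$end),
                     seqinfo = si)
    names(enhGR) <- enhDf$id
    isB <- enhDf$category == "unique_b"
    poised <- rep(FALSE, nrow(enhDf))
    poised[sample(which(isB),
                  round(cfg$fracNewEnhancersPoised * sum(isB)))] <- TRUE
    enhDf$poised <- ifelse(isB, poised, NA)

    ## ---- exon structure ---------------------------------------------------
    exonList <- vector("list", n)
    for (i in seq_len(n)) {
        occ <- genic[[i]]
        if (length(occ)) {
            ## end-exons plus a tiny exon around each exonic midpoint
            ex <- list(c(gStart[i], gStart[i] + 249L),
                       c(gEnd[i] - 249L, gEnd[i]))
            here <- which(enhDf$host == i & enhDf$compartment == "exonic")
            for (e in here) {
                mid <- floor((enhDf$start[e] + enhDf$end[e]) / 2)
                ex <- c(ex, list(c(mid - 40L, mid + 40L)))
            }
            m <- do.call(rbind, ex)
            m <- m[order(m[, 1]), , drop = FALSE]
            exonList[[i]] <- m
        } else {
            nEx <- sample(2:6, 1)
            bw <- floor(len[i] / nEx)
            L <- round(stats::runif(nEx, 100, 400))
            st <- gStart[i] + (seq_len(nEx) - 1L) * bw
            en <- st + L - 1L
            st[nEx] <- gEnd[i] - L[nEx] + 1L
            en[nEx] <- gEnd[i]
            exonList[[i]] <- cbind(st, en)
        }
    }
    exFlat <- do.call(rbind, exonList)
    exN <- vapply(exonList, nrow, integer(1))
    exGR <- GRanges(rep(chrom, exN),
                    IRanges(as.integer(exFlat[, 1]),
                            as.integer(exFlat[, 2])),
                    strand = rep(strand, exN), seqinfo = si)
    exl <- S4Vectors::split(exGR, factor(rep(ids, exN), levels = ids))
    span <- GRanges(chrom, IRanges(gStart, gEnd), strand = strand,
                    seqinfo = si)
    names(span) <- ids
    ann <- makeGenomeAnnotation(span, exl, names = nms)

    ## ---- CpG islands -------------------------------------------------------
    clsKey <- ifelse(cls %in% c("de_repressed", "up", "down"), cls, "other")
    cgiFlag <- stats::runif(n) < cfg$cgiFrac[clsKey]
    cgiL <- pmin(pmax(round(stats::rnorm(n, 1000, 150)), 400L), 1600L)
    up40 <- round(cgiL * 0.4)
    cgiGR <- .grClamped(chrom[cgiFlag], tss[cgiFlag] - up40[cgiFlag],
                        tss[cgiFlag] + (cgiL[cgiFlag] - up40[cgiFlag]) - 1L,
                        si)
    names(cgiGR) <- sprintf("CGI%04d", seq_len(sum(cgiFlag)))

    ## ---- promoter sequences with planted TATA boxes ------------------------
    tataFlag <- stats::runif(n) < cfg$tataFrac[clsKey]
    seqLen <- 150L
    pat <- Biostrings::DNAString("TATAWAW")
    motifChars <- c("T", "A", "T", "A", "W", "A", "W")
    randSeq <- function(k) vapply(seq_len(k), function(i)
        paste(sample(c("A", "C", "G", "T"), seqLen, replace = TRUE),
              collapse = ""), character(1))
    ## motif starts allowed at offsets -40..-20 => scan that window only
    winHit <- function(seqs) {
        sub <- Biostrings::subseq(Biostrings::DNAStringSet(seqs),
                                  seqLen - 40L, seqLen - 14L)
        Biostrings::vcountPattern(pat, sub, max.mismatch = 1,
                                  fixed = "subject") > 0L
    }
    seqs <- randSeq(n)
    ## TATA-negative promoters must carry no spurious <=1-mismatch match
    for (round in seq_len(50)) {
        bad <- which(!tataFlag & winHit(seqs))
        if (!length(bad)) break
        seqs[bad] <- randSeq(length(bad))
    }
    for (i in which(tataFlag)) {
        inst <- vapply(motifChars, function(ch)
            if (ch == "W") sample(c("A", "T"), 1) else ch, character(1))
        if (stats::runif(1) < 0.5) {
            j <- sample(7, 1)
            inst[j] <- if (motifChars[j] == "W") sample(c("C", "G"), 1)
                else sample(setdiff(c("A", "C", "G", "T"),
                                    motifChars[j]), 1)
        }
        p0 <- seqLen + sample(-40:-20, 1)
        s <- seqs[i]
        substr(s, p0, p0 + 6L) <- paste(inst, collapse = "")
        seqs[i] <- s
    }
    promoterSeq <- Biostrings::DNAStringSet(seqs)
    names(promoterSeq) <- ids

    ## ---- CpG positions and parental methylation ----------------------------
    nPer <- round(cfg$chromLength * cfg$cpgDensity)
    cpgPos <- lapply(chroms, function(ch)
        sort(sample.int(cfg$chromLength - 1L, nPer)))
    cpg <- GRanges(rep(chroms, each = nPer),
                   IRanges(unlist(cpgPos), width = 1L), seqinfo = si)
    nC <- length(cpg)

    promWin <- promoterWindows(ann, 100, 700)
    activeEnh <- enhGR[enhDf$category %in% c("common", "unique_a")]
    comp <- rep("intergenic", nC)
    ovGene <- GenomicRanges::findOverlaps(cpg, span, ignore.strand = TRUE,
                                          select = "first")
    comp[!is.na(ovGene)] <- "body"
    ovEnh <- GenomicRanges::findOverlaps(cpg, activeEnh,
                                         ignore.strand = TRUE,
                                         select = "first")
    comp[!is.na(ovEnh)] <- "enhA"
    ovProm <- GenomicRanges::findOverlaps(cpg, promWin,
                                          ignore.strand = TRUE,
                                          select = "first")
    comp[!is.na(ovProm)] <- "promoter"

    noise <- stats::rnorm(nC, 0, cfg$cpgNoiseSd)
    par <- numeric(nC)
    ip <- comp == "promoter"
    par[ip] <- .clip01(theta[ovProm[ip]] + noise[ip])
    ie <- comp == "enhA"
    thetaEnh <- stats::rbeta(length(activeEnh), 0.05 * 8, 0.95 * 8)
    par[ie] <- .clip01(thetaEnh[ovEnh[ie]] + noise[ie])

    ## gene-body levels solved so span means hit stratified targets
    shBody <- .betaShapesForMedian(cfg$bodyMethMedian, 12)
    tBody <- .stratBeta(n, shBody)
    ib <- comp == "body"
    gOf <- ovGene
    inSpan <- !is.na(gOf)
    fixedInSpan <- inSpan & (ip | ie)
    sFix <- rep(0, n); nFix <- rep(0L, n)
    if (any(fixedInSpan)) {
        agg <- rowsum(par[fixedInSpan], gOf[fixedInSpan], reorder = TRUE)
        gidx <- as.integer(rownames(agg))
        sFix[gidx] <- agg
        nFix[gidx] <- tabulate(gOf[fixedInSpan], nbins = n)[gidx]
    }
    nBody <- tabulate(gOf[ib], nbins = n)
    bLevel <- rep(cfg$bodyMethMedian, n)
    has <- nBody > 0
    bLevel[has] <- .clip01((tBody[has] * (nFix[has] + nBody[has]) -
                            sFix[has]) / nBody[has])
    par[ib] <- .clip01(bLevel[gOf[ib]] + noise[ib])

    ## intergenic levels: stratified quantiles shifted so the random-region
    ## parental median hits its target
    ii <- comp == "intergenic"
    nI <- sum(ii)
    baseI <- .stratBeta(nI, shBody)
    calReg <- sampleRandomRegions(sizes, 600, 10000)
    hitsCal <- GenomicRanges::findOverlaps(calReg, cpg,
                                           ignore.strand = TRUE)
    qr <- S4Vectors::queryHits(hitsCal); sr <- S4Vectors::subjectHits(hitsCal)
    iMap <- which(ii)
    regMedian <- function(values) {
        sums <- rowsum(values[sr], qr, reorder = TRUE)
        cnts <- tabulate(qr, nbins = length(calReg))
        idx <- as.integer(rownames(sums))
        stats::median(sums / cnts[idx])
    }
    parWith <- function(delta) {
        v <- par
        v[iMap] <- .clip01(baseI + delta + noise[iMap])
        v
    }
    delta <- .bisect(function(d) regMedian(parWith(d)), -0.5, 0.5,
                     cfg$randomMethMedian)
    par <- parWith(delta)

    ## ---- demethylated condition: per-compartment scaling --------------------
    fEnh <- 0.5
    promAgg <- GenomicRanges::findOverlaps(promWin, cpg,
                                           ignore.strand = TRUE)
    qp <- S4Vectors::queryHits(promAgg); sp <- S4Vectors::subjectHits(promAgg)
    medOver <- function(values, q, s, ngroup) {
        sums <- rowsum(values[s], q, reorder = TRUE)
        cnts <- tabulate(q, nbins = ngroup)
        idx <- as.integer(rownames(sums))
        stats::median(sums / cnts[idx])
    }
    fac <- function(fp, fb, fi) {
        f <- c(promoter = fp, enhA = fEnh, body = fb, intergenic = fi)
        par * f[comp]
    }
    fProm <- .bisect(function(x)
        medOver(fac(x, 0, 0), qp, sp, length(promWin)),
        0, 1, cfg$derivedTargets[["promoter"]])
    spanAgg <- GenomicRanges::findOverlaps(span, cpg, ignore.strand = TRUE)
    qs <- S4Vectors::queryHits(spanAgg); ss <- S4Vectors::subjectHits(spanAgg)
    fBody <- .bisect(function(x)
        medOver(fac(fProm, x, 0), qs, ss, length(span)),
        0, 1, cfg$derivedTargets[["body"]])
    fInter <- .bisect(function(x)
        medOver(fac(fProm, fBody, x), qr, sr, length(calReg)),
        0, 1, cfg$derivedTargets[["random"]])
    der <- pmin(par, fac(fProm, fBody, fInter) *
                     exp(stats::rnorm(nC, 0, 0.1)))

    covP <- stats::rpois(nC, cfg$coverageMean)
    covD <- stats::rpois(nC, cfg$coverageMean)
    mkMeth <- function(values, cov, condition) {
        gr <- cpg
        mcols(gr) <- DataFrame(meth = round(values, 6),
                               coverage = as.integer(cov))
        new("MethylationCalls", calls = gr, condition = condition)
    }
    methP <- mkMeth(par, covP, cfg$conditions[1])
    methD <- mkMeth(der, covD, cfg$conditions[2])

    ## ---- expression ---------------------------------------------------------
    sdr <- cfg$replicateNoiseSd
    tA <- tB <- numeric(n)
    highProm <- theta > 0.5
    unch <- which(cls == "unchanged")
    tA[unch] <- ifelse(highProm[unch], stats::runif(length(unch), 0, 1.2),
                       stats::runif(length(unch), 1.6, 6))
    tB[unch] <- tA[unch]
    tA[drGenes] <- stats::runif(length(drGenes), 0, 1.4)
    tB[drGenes] <- stats::runif(length(drGenes), 2.6, 6)
    tA[upGenes] <- stats::runif(length(upGenes), 2, 5)
    tB[upGenes] <- tA[upGenes] + stats::runif(length(upGenes), 1.0, 2.5)
    tA[downGenes] <- stats::runif(length(downGenes), 2, 5)
    tB[downGenes] <- tA[downGenes] - stats::runif(length(downGenes),
                                                  1.0, 2.5)
    tB[downGenes] <- pmax(tB[downGenes], 0.2)
    ## not_expressed genes stay exactly zero in both conditions
    rep1 <- function(t) pmax(0, 2^(t + stats::rnorm(n, 0, sdr)) - 1)
    nr <- cfg$nReplicates
    valsA <- vapply(seq_len(nr), function(r) rep1(tA), numeric(n))
    valsB <- vapply(seq_len(nr), function(r) rep1(tB), numeric(n))
    zero <- cls == "not_expressed"
    valsA[zero, ] <- 0; valsB[zero, ] <- 0
    vals <- cbind(valsA, valsB)
    colnames(vals) <- c(paste0(cfg$conditions[1], "_rep", seq_len(nr)),
                        paste0(cfg$conditions[2], "_rep", seq_len(nr)))
    rownames(vals) <- ids
    expr <- makeExpressionTable(vals, rep(cfg$conditions, each = nr))

    ## ---- peaks -----------------------------------------------------------
    activeProm <- which(!highProm)
    gainK4 <- sample(drGenes, round(cfg$fracDerepressedNewK4me3 *
                                        length(drGenes)))
    restDr <- setdiff(drGenes, gainK4)
    commonK4 <- sample(restDr, round(cfg$fracDerepressedCommonK4me3 *
                                         length(restDr)))
    promPeak <- function(g) .grClamped(chrom[g], tss[g] - 500L,
                                       tss[g] + 500L, si)
    k4A <- promPeak(sort(c(activeProm, commonK4)))
    k4B <- promPeak(sort(c(activeProm, commonK4, gainK4)))
    rnapA <- promPeak(activeProm)
    rnapB <- promPeak(activeProm)
    enhA <- enhGR[enhDf$category %in% c("common", "unique_a")]
    enhB <- enhGR[enhDf$category %in% c("common", "unique_b")]
    k27A <- .sortGR(c(promPeak(activeProm), granges(enhA)))
    k27B <- .sortGR(c(promPeak(sort(c(activeProm, drGenes))),
                      granges(enhB)))
    k4me1A <- .sortGR(c(granges(enhA),
                        granges(enhGR[which(enhDf$poised %in% TRUE)])))
    k4me1B <- .sortGR(granges(enhB))
    jitter <- function(gr) {
        j <- cfg$peakJitter
        st <- pmax(start(gr) + round(stats::runif(length(gr), -j, j)), 1L)
        en <- pmax(end(gr) + round(stats::runif(length(gr), -j, j)),
                   st + 50L)
        .sortGR(GRanges(seqnames(gr), IRanges(st, en), seqinfo = si))
    }
    mkPair <- function(gr, mark, condition) {
        r1 <- new("PeakSet", peaks = .sortGR(granges(gr)), mark = mark,
                  condition = condition, replicate = "1")
        r2 <- new("PeakSet", peaks = jitter(gr), mark = mark,
                  condition = condition, replicate = "2")
        stats::setNames(list(r1, r2),
                        paste0(mark, "_", condition, "_rep", 1:2))
    }
    cd <- cfg$conditions
    peaks <- c(mkPair(k4A, "H3K4me3", cd[1]), mkPair(k4B, "H3K4me3", cd[2]),
               mkPair(k27A, "H3K27ac", cd[1]),
               mkPair(k27B, "H3K27ac", cd[2]),
               mkPair(k4me1A, "H3K4me1", cd[1]),
               mkPair(k4me1B, "H3K4me1", cd[2]),
               mkPair(rnapA, "RNAPII", cd[1]),
               mkPair(rnapB, "RNAPII", cd[2]))

    ## ---- TSG list ---------------------------------------------------------
    tsg <- c(nms[sample(drGenes, min(12, length(drGenes)))],
             nms[sample(upGenes, min(6, length(upGenes)))],
             nms[sample(downGenes, min(8, length(downGenes)))],
             nms[sample(unch, min(12, length(unch)))],
             sprintf("TSGX%02d", 1:5))

    ## ---- ground truth -------------------------------------------------------
    k4Group <- rep(NA_character_, n)
    k4Group[gainK4] <- "gained_new"
    k4Group[commonK4] <- "in_common"
    k4Group[setdiff(restDr, commonK4)] <- "neither"
    truthGenes <- data.frame(
        gene_id = ids, name = nms, class = cls, chrom = chrom,
        strand = strand, tss = tss, start = gStart, end = gEnd,
        promoter_theta = round(theta, 6),
        promoter_state = ifelse(theta > 0.5, "high", "low"),
        cgi = cgiFlag, tata = tataFlag, tsg = nms %in% tsg,
        k4me3_group = k4Group, stringsAsFactors = FALSE)
    truthEnh <- enhDf
    truthEnh$host_gene <- ifelse(is.na(enhDf$host), NA_character_,
                                 ids[enhDf$host])
    truthEnh$host <- NULL

    new("SyntheticBundle", annotation = ann, methParental = methP,
        methDerived = methD, peaks = peaks, expression = expr,
        cgi = cgiGR, promoterSeq = promoterSeq, tsg = tsg,
        truth = list(genes = truthGenes, enhancers = truthEnh,
                     calibration = list(mixture_weight = w,
                                        background_shift = delta,
                                        f_promoter = fProm,
                                        f_body = fBody,
                                        f_intergenic = fInter)),
        config = unclass(cfg))
}
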