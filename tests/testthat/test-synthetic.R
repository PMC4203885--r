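test_that("config validation rejects impossible settings", {
    expect_error(syntheticConfig(nGenes = 10, nDerepressed = 8, nUp = 2,
                                 nDown = 2, nNotExpressed = 0),
                 "class sizes")
    expect_error(syntheticConfig(nGenes = 2001), "multiple")
    expect_error(syntheticConfig(fracNewEnhancersPoised = 1.2), "0, 1")
    expect_error(syntheticConfig(nGenes = 4000, chromLength = 1e6,
                                 nChroms = 2), "infeasible")
})

test_that("mixture calibration hits the analytic median and the bounds", {
    shL <- c(0.03 * 4, 0.97 * 4)
    shH <- c(0.90 * 1.2, 0.10 * 1.2)
    medL <- qbeta(0.5, shL[1], shL[2])
    medH <- qbeta(0.5, shH[1], shH[2])
    expect_equal(calibrateMixture(medL), 0)
    expect_equal(calibrateMixture(medH), 1)
    expect_error(calibrateMixture(1.2), "\\(0, 1\\)")

    w <- calibrateMixture(0.30)
    expect_gt(w, 0); expect_lt(w, 1)
    ## analytic check: mixture CDF at 0.30 is 0.5
    expect_equal((1 - w) * pbeta(0.3, shL[1], shL[2]) +
                 w * pbeta(0.3, shH[1], shH[2]), 0.5, tolerance = 1e-3)
    ## Monte-Carlo check: the mixture density at the calibrated median is
    ## ~0.15, so the sample median has sd ~ 1/(2 f sqrt(n)); at 1e6 draws
    ## a 0.01 tolerance is a 3-sigma bound
    set.seed(17)
    nDraw <- 1e6
    hi <- runif(nDraw) < w
    draws <- ifelse(hi, rbeta(nDraw, shH[1], shH[2]),
                    rbeta(nDraw, shL[1], shL[2]))
    expect_lt(abs(median(draws) - 0.30), 0.01)
})

test_that("generation is deterministic per seed", {
    b1 <- smallBundle(seed = 7)
    b2 <- simulateEpigenome(smallConfig(seed = 7))
    expect_identical(methCalls(b1@methParental),
                     methCalls(b2@methParental))
    expect_identical(b1@truth$genes, b2@truth$genes)
    expect_identical(as.character(b1@promoterSeq),
                     as.character(b2@promoterSeq))
    b3 <- simulateEpigenome(smallConfig(seed = 8))
    expect_false(identical(b1@truth$genes$class, b3@truth$genes$class))
})

test_that("the demethylated condition never exceeds the parental one", {
    b <- smallBundle()
    p <- mcols(methCalls(b@methParental))$meth
    d <- mcols(methCalls(b@methDerived))$meth
    expect_true(all(d <= p))
    ## region means inherit the inequality
    regs <- sampleRandomRegions(
        seqlengths(geneRanges(b@annotation)), 100, 5000, seed = 3)
    aggP <- aggregateRegionMethylation(b@methParental, regs, 1)$mean_meth
    aggD <- aggregateRegionMethylation(b@methDerived, regs, 1)$mean_meth
    ok <- !is.na(aggP)
    expect_true(all(aggD[ok] <= aggP[ok]))
})

test_that("emitted files pass their own readers' validation", {
    dir <- withr::local_tempdir()
    writeBundle(smallBundle(), dir)
    rep <- cmdValidate(dir)
    expect_true(all(rep$ok))
    back <- readBundle(dir)
    b <- smallBundle()
    expect_equal(length(geneRanges(back$annotation)),
                 length(geneRanges(b@annotation)))
    expect_equal(mcols(methCalls(back$methParental))$meth,
                 mcols(methCalls(b@methParental))$meth,
                 tolerance = 1e-5)
    expect_equal(length(back$peaks), length(b@peaks))
})

test_that("planted structure is recovered by the downstream operations", {
    b <- smallBundle()
    ann <- b@annotation
    truth <- b@truth
    cons <- function(mark, cond)
        consensusPeaks(b@peaks[[paste0(mark, "_", cond, "_rep1")]],
                       b@peaks[[paste0(mark, "_", cond, "_rep2")]])
    eA <- defineEnhancers(cons("H3K27ac", "parental"), ann)
    eB <- defineEnhancers(cons("H3K27ac", "demethylated"), ann)
    cmp <- compareEnhancers(eA, eB)
    v <- vennCounts(cmp)
    te <- truth$enhancers
    expect_equal(v$common_a, sum(te$category == "common"))
    expect_equal(v$unique_a, sum(te$category == "unique_a"))
    expect_equal(v$unique_b, sum(te$category == "unique_b"))
    ## unique-B intervals are exactly the planted ones
    ub <- sort(cmp@uniqueB)
    planted <- te[te$category == "unique_b", ]
    planted <- planted[order(planted$chrom, planted$start), ]
    expect_equal(as.character(seqnames(ub)), planted$chrom)
    expect_equal(start(ub), planted$start)
    expect_equal(end(ub), planted$end)
    ## compartment labels match the planted ones exactly
    cmp <- annotateCompartment(cmp, ann)
    expect_equal(unname(mcols(ub <- sort(cmp@uniqueB))$compartment),
                 planted$compartment)
    ## poised fraction equals the planted fraction
    pf <- poisedFraction(cmp@uniqueB, cons("H3K4me1", "parental"))
    expect_equal(pf, mean(planted$poised))
    ## new enhancers are parental-methylated, common ones are not
    cmp <- enhancerParentalMethylation(cmp, b@methParental)
    expect_gt(median(mcols(cmp@uniqueB)$parental_meth, na.rm = TRUE),
              median(mcols(cmp@common)$parental_meth, na.rm = TRUE))
})

test_that("generator emulates the host-gene intragenic enhancer design", {
    b <- smallBundle()
    te <- b@truth$enhancers
    tg <- b@truth$genes
    upIds <- tg$gene_id[tg$class == "up"]
    hosted <- te[te$category == "unique_b" & !is.na(te$host_gene) &
                 te$host_gene %in% upIds, ]
    expect_gt(nrow(hosted), 0)
    cons <- function(mark, cond)
        consensusPeaks(b@peaks[[paste0(mark, "_", cond, "_rep1")]],
                       b@peaks[[paste0(mark, "_", cond, "_rep2")]])
    cmp <- compareEnhancers(
        defineEnhancers(cons("H3K27ac", "parental"), b@annotation),
        defineEnhancers(cons("H3K27ac", "demethylated"), b@annotation))
    res <- countIntragenicEnhancers(upIds, cmp, b@annotation)
    plantedPerGene <- table(factor(hosted$host_gene, levels = upIds))
    expect_equal(unname(res$counts$unique_b),
                 unname(as.integer(plantedPerGene)))
    expect_equal(res$counts$unique_b_intronic +
                 res$counts$unique_b_exonic, res$counts$unique_b)
})

test_that("parental compartment medians sit at the configured targets", {
    b <- defaultBundle(seed = 1)
    rr <- sampleRandomRegions(seqlengths(geneRanges(b@annotation)),
                              1000, 10000, seed = 5)
    med <- compartmentMedians(b@methParental, b@methDerived,
                              b@annotation, rr)
    expect_lt(abs(med[1, "promoters"] - 0.30), 0.02)
    expect_lt(abs(med[1, "gene_bodies"] - 0.84), 0.03)
    expect_lt(abs(med[1, "random"] - 0.84), 0.02)
})
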