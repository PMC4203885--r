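test_that("methylation reading validates and honors the dialect", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("chr1\t100\t0.8\t5", "chr1\t200\t0.6\t2",
                 "chr2\t50\t0.4\t3"), f)
    m <- readMethylation(f, "parental")
    expect_equal(length(methCalls(m)), 3L)
    expect_equal(conditionLabel(m), "parental")

    ## percent dialect: 84 becomes fraction 0.84
    writeLines("chr1\t100\t84\t5", f)
    mp <- readMethylation(f, "parental", dialect = "percent")
    expect_equal(mcols(methCalls(mp))$meth, 0.84)

    ## duplicate position and out-of-range values are named errors
    writeLines(c("chr1\t100\t0.8\t5", "chr1\t100\t0.6\t3"), f)
    expect_error(readMethylation(f, "x"), "line 2.*duplicate")
    writeLines("chr1\t100\t1.4\t5", f)
    expect_error(readMethylation(f, "x"), "line 1.*outside")

    ## round trip through the writer
    writeLines(c("chr1\t100\t0.8\t5", "chr1\t200\t0.6\t2"), f)
    m <- readMethylation(f, "parental")
    f2 <- withr::local_tempfile(fileext = ".tsv")
    writeMethylation(m, f2)
    m2 <- readMethylation(f2, "parental")
    expect_equal(mcols(methCalls(m2))$meth, mcols(methCalls(m))$meth)
})

test_that("region aggregation applies the 3x coverage rule, unweighted", {
    m <- makeTestMeth(rep("chr1", 3), c(100, 200, 300),
                      c(0.8, 0.6, 0.4), c(5, 2, 3))
    reg <- GRanges("chr1", IRanges(1, 1000))
    agg <- aggregateRegionMethylation(m, reg, minCoverage = 3)
    expect_equal(agg$mean_meth, 0.6)   # the coverage-2 CpG is excluded
    expect_equal(agg$n_cpgs_used, 2L)

    ## region without CpGs is missing, not zero
    agg2 <- aggregateRegionMethylation(m, GRanges("chr1",
                                                  IRanges(5000, 6000)))
    expect_true(is.na(agg2$mean_meth))
    expect_equal(agg2$n_cpgs_used, 0L)

    ## coverage-weighted variant
    aggW <- aggregateRegionMethylation(m, reg, minCoverage = 3,
                                       weighted = TRUE)
    expect_equal(aggW$mean_meth, (0.8 * 5 + 0.4 * 3) / 8)
})

test_that("raising the coverage filter never adds CpGs", {
    set.seed(5)
    m <- makeTestMeth(rep("chr1", 200), sample.int(20000, 200),
                      runif(200), rpois(200, 4))
    regs <- randomRanges(30, chroms = "chr1", maxPos = 18000,
                         maxWidth = 2000)
    prev <- aggregateRegionMethylation(m, regs, 1)$n_cpgs_used
    for (mc in 2:6) {
        cur <- aggregateRegionMethylation(m, regs, mc)$n_cpgs_used
        expect_true(all(cur <= prev))
        prev <- cur
    }
})

test_that("region aggregation matches the brute-force oracle", {
    set.seed(21)
    for (i in 1:25) {
        nC <- sample(50:200, 1)
        cpg <- data.frame(chrom = sample(c("chr1", "chr2"), nC, TRUE),
                          pos = sample.int(30000, nC),
                          meth = runif(nC), cov = rpois(nC, 4))
        cpg <- cpg[!duplicated(cpg[c("chrom", "pos")]), ]
        m <- makeTestMeth(cpg$chrom, cpg$pos, cpg$meth, cpg$cov)
        regs <- randomRanges(8, maxPos = 28000, maxWidth = 3000)
        agg <- aggregateRegionMethylation(m, regs, 3)
        expect_equal(agg$mean_meth, bfAggregate(cpg, grDf(regs), 3))
        expect_true(all(agg$mean_meth >= 0 & agg$mean_meth <= 1,
                        na.rm = TRUE))
    }
})

test_that("promoter methylation classification is strict at the cutoff", {
    expect_equal(classifyPromoterMethylation(c(0.62, 0.50, 0.49, NA)),
                 c("high", "low", "low", "missing"))
})

test_that("compartment medians behave under constant and scaled input", {
    ann <- makeTestAnnotation(nGenes = 4)
    set.seed(3)
    pos <- sort(sample.int(60000, 600))
    mP <- makeTestMeth(rep("chr1", 600), pos, rep(0.5, 600),
                       rep(10, 600), "parental")
    mD <- makeTestMeth(rep("chr1", 600), pos, rep(0.05, 600),
                       rep(10, 600), "derived")
    rr <- sampleRandomRegions(c(chr1 = 1e6), 20, 5000, seed = 1)
    med <- compartmentMedians(mP, mD, ann, rr)
    expect_true(all(med["parental", ] == 0.5))
    expect_equal(unname(med["derived", ]), unname(med["parental", ]) * 0.1)
})

test_that("methylation profile bins strand-oriented offsets", {
    ## single CpG 50 bp downstream of a '+' anchor -> bin [0,100)
    m <- makeTestMeth("chr1", 1050, 0.9, 10)
    anchor <- GRanges("chr1", IRanges(1000, 1000), strand = "+")
    pr <- methylationProfile(m, anchor, flank = 2500, bin = 100)
    expect_equal(nrow(pr), 50L)
    hit <- pr$offset_start == 0
    expect_equal(pr$mean_meth[hit], 0.9)
    expect_true(all(is.na(pr$mean_meth[!hit])))

    ## CpG 50 bp left of a '-' anchor lands in the same bin
    m2 <- makeTestMeth("chr1", 950, 0.7, 10)
    anchorM <- GRanges("chr1", IRanges(1000, 1000), strand = "-")
    pr2 <- methylationProfile(m2, anchorM, flank = 2500, bin = 100)
    expect_equal(pr2$mean_meth[pr2$offset_start == 0], 0.7)

    expect_error(methylationProfile(m, anchor, flank = 2500, bin = 300),
                 "divisible")
})

test_that("methylation profile matches the brute-force double loop", {
    set.seed(31)
    for (i in 1:15) {
        nC <- sample(80:150, 1)
        cpg <- data.frame(chrom = sample(c("chr1", "chr2"), nC, TRUE),
                          pos = sample.int(20000, nC),
                          meth = runif(nC), cov = rpois(nC, 5))
        cpg <- cpg[!duplicated(cpg[c("chrom", "pos")]), ]
        m <- makeTestMeth(cpg$chrom, cpg$pos, cpg$meth, cpg$cov)
        nA <- sample(3:10, 1)
        anc <- data.frame(chrom = sample(c("chr1", "chr2"), nA, TRUE),
                          pos = sample.int(20000, nA),
                          strand = sample(c("+", "-"), nA, TRUE))
        anchors <- GRanges(anc$chrom, IRanges(anc$pos, width = 1),
                           strand = anc$strand)
        pr <- methylationProfile(m, anchors, flank = 1000, bin = 100,
                                 minCoverage = 3)
        expect_equal(pr$mean_meth,
                     bfProfile(cpg, anc, 1000, 100, 3))
    }
})

test_that("random region sampling is seeded and length-weighted", {
    sizes <- c(chr1 = 900000, chr2 = 100000)
    r1 <- sampleRandomRegions(sizes, 1000, 1000, seed = 99)
    r2 <- sampleRandomRegions(sizes, 1000, 1000, seed = 99)
    expect_identical(r1, r2)
    expect_true(all(start(r1) >= 1))
    expect_true(all(end(r1) <= sizes[as.character(seqnames(r1))]))
    ## chromosome counts ~ Binomial(n, 0.9): allow 3 sigma
    n1 <- sum(seqnames(r1) == "chr1")
    expect_lt(abs(n1 - 900), 3 * sqrt(1000 * 0.9 * 0.1) + 1)
    expect_error(sampleRandomRegions(sizes, 0, 1000), "positive")
    expect_error(sampleRandomRegions(sizes, 10, 2e5), "exceeds")
})
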