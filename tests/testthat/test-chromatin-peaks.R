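test_that("replicate consensus keeps rep1 peaks present in rep2", {
    r1 <- makeTestPeaks(c(1, 501), c(100, 600))
    r2 <- makeTestPeaks(51, 150, replicate = "2")
    cons <- consensusPeaks(r1, r2)
    expect_equal(start(peakRanges(cons)), 1L)
    expect_equal(end(peakRanges(cons)), 100L)

    ## identical replicates: identity
    consId <- consensusPeaks(r1, makeTestPeaks(c(1, 501), c(100, 600),
                                               replicate = "2"))
    expect_identical(granges(peakRanges(consId)), granges(peakRanges(r1)))

    ## mark/condition mismatch is an error
    r3 <- makeTestPeaks(1, 100, mark = "H3K4me3")
    expect_error(consensusPeaks(r1, r3), "disagree")

    ## intersection coordinates
    consI <- consensusPeaks(r1, r2, coordinates = "intersection")
    expect_equal(start(peakRanges(consI)), 51L)
    expect_equal(end(peakRanges(consI)), 100L)
})

test_that("consensus matches the brute-force filter on random replicates", {
    set.seed(41)
    for (i in 1:30) {
        a <- randomRanges(sample(5:60, 1))
        b <- randomRanges(sample(5:60, 1))
        r1 <- new("PeakSet", peaks = sort(a), mark = "H3K27ac",
                  condition = "c", replicate = "1")
        r2 <- new("PeakSet", peaks = sort(b), mark = "H3K27ac",
                  condition = "c", replicate = "2")
        cons <- peakRanges(consensusPeaks(r1, r2))
        keep <- bfConsensus(grDf(sort(a)), grDf(b))
        expect_identical(granges(cons), granges(sort(a))[keep])
    }
})

test_that("TSS-proximity split is an exhaustive boundary-inclusive partition", {
    ann <- makeTestAnnotation(nGenes = 1)   # tss = 1001
    ## peak just inside the +2 kb edge (window 1..3001) is proximal
    pk <- makeTestPeaks(c(2501, 3002, 8000), c(3001, 3100, 8100))
    sp <- splitByTssProximity(pk, ann, 2000)
    expect_equal(start(peakRanges(sp$proximal)), 2501L)
    expect_equal(start(peakRanges(sp$distal)), c(3002L, 8000L))
    expect_equal(length(peakRanges(sp$proximal)) +
                 length(peakRanges(sp$distal)), 3L)

    ## conservation on random input
    set.seed(51)
    for (i in 1:10) {
        pk <- new("PeakSet", peaks = sort(randomRanges(40, "chr1")),
                  mark = "H3K27ac", condition = "c", replicate = "1")
        sp <- splitByTssProximity(pk, ann, 2000)
        expect_equal(length(peakRanges(sp$proximal)) +
                     length(peakRanges(sp$distal)), 40L)
    }
})

test_that("enhancers are the distal H3K27ac peaks", {
    ann <- makeTestAnnotation(nGenes = 2)   # tss 1001, 11001
    pk <- makeTestPeaks(c(900, 5000, 10500), c(1200, 5400, 11500))
    enh <- defineEnhancers(pk, ann)
    expect_equal(start(peakRanges(enh)), 5000L)
    ## all peaks proximal -> empty enhancer set
    pkProx <- makeTestPeaks(c(900, 10500), c(1200, 11500))
    expect_equal(length(peakRanges(defineEnhancers(pkProx, ann))), 0L)
    ## no genes -> everything is an enhancer
    annEmpty <- suppressWarnings(
        readAnnotation(withr::local_tempfile(lines = character(),
                                             fileext = ".gtf"), "gtf"))
    expect_equal(length(peakRanges(defineEnhancers(pk, annEmpty))), 3L)
    ## wrong mark is an error
    pkBad <- makeTestPeaks(1, 100, mark = "H3K4me3")
    expect_error(defineEnhancers(pkBad, ann), "H3K27ac")
})

test_that("enhancer comparison partitions both sides", {
    a <- makeTestPeaks(1, 100)
    b <- makeTestPeaks(c(51, 901), c(150, 950), replicate = "2",
                       condition = "derived")
    cmp <- compareEnhancers(a, b)
    v <- vennCounts(cmp)
    expect_equal(v$common_a, 1L)
    expect_equal(v$unique_a, 0L)
    expect_equal(v$unique_b, 1L)
    expect_equal(v$common_b, 1L)

    ## disjoint sets are all unique
    b2 <- makeTestPeaks(5000, 5100, condition = "derived")
    v2 <- vennCounts(compareEnhancers(a, b2))
    expect_equal(v2$common_a, 0L)
    expect_equal(v2$unique_a, 1L)
    expect_equal(v2$unique_b, 1L)
})

test_that("enhancer comparison counts match the brute-force oracle", {
    set.seed(61)
    for (i in 1:30) {
        a <- sort(randomRanges(sample(5:80, 1)))
        b <- sort(randomRanges(sample(5:80, 1)))
        cmp <- compareEnhancers(
            new("PeakSet", peaks = a, mark = "H3K27ac", condition = "A",
                replicate = "1"),
            new("PeakSet", peaks = b, mark = "H3K27ac", condition = "B",
                replicate = "1"))
        v <- vennCounts(cmp)
        bf <- bfCompare(grDf(a), grDf(b))
        expect_equal(v$common_a, bf$common_a)
        expect_equal(v$unique_a, bf$unique_a)
        expect_equal(v$common_b, bf$common_b)
        expect_equal(v$unique_b, bf$unique_b)
        expect_equal(v$common_a + v$unique_a, length(a))
        expect_equal(v$common_b + v$unique_b, length(b))
    }
})

test_that("compartment labels use midpoint with exon precedence", {
    ann <- makeTestAnnotation(nGenes = 1)
    ## gene 1001-5000, exons 1001-1500 and 4501-5000
    expect_equal(annotateCompartment(GRanges("chr1", IRanges(1100, 1300)),
                                     ann), "exonic")
    expect_equal(annotateCompartment(GRanges("chr1", IRanges(2000, 2500)),
                                     ann), "intronic")
    expect_equal(annotateCompartment(GRanges("chr1", IRanges(7000, 7400)),
                                     ann), "intergenic")
})

test_that("enhancer parental methylation is the region aggregate", {
    m <- makeTestMeth(rep("chr1", 2), c(120, 160), c(0.9, 0.7), c(4, 8))
    a <- makeTestPeaks(100, 200)
    b <- makeTestPeaks(5000, 5100, condition = "derived")
    cmp <- enhancerParentalMethylation(compareEnhancers(a, b), m)
    expect_equal(mcols(cmp@uniqueA)$parental_meth, 0.8)
    expect_true(is.na(mcols(cmp@uniqueB)$parental_meth))
})

test_that("poised fraction counts overlap with parental H3K4me1", {
    newEnh <- GRanges("chr1", IRanges(seq(1, by = 1000, length.out = 10),
                                      width = 200))
    k4 <- GRanges("chr1", IRanges(start(newEnh)[1:4], width = 50))
    expect_equal(poisedFraction(newEnh, k4), 0.4)
    expect_equal(poisedFraction(newEnh, GRanges("chr2", IRanges(1, 2))), 0)
    expect_equal(poisedFraction(newEnh, newEnh), 1)
    expect_error(poisedFraction(GRanges(), k4), "non-empty")
})
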