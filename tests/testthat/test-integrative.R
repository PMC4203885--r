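test_that("de-repressed promoter H3K4me3 partition conserves the input", {
    ann <- makeTestAnnotation(nGenes = 6)  # tss at 1001, 11001, ...
    tss <- mcols(geneRanges(ann))$tss
    genes <- mcols(geneRanges(ann))$gene_id
    newPk <- GRanges("chr1", IRanges(tss[1:2] - 50, tss[1:2] + 50))
    commonPk <- GRanges("chr1", IRanges(tss[3] - 50, tss[3] + 50))
    res <- derepressedK4me3Overlap(genes, newPk, commonPk, ann)
    expect_equal(unname(res$status[1:3]),
                 c("gained_new", "gained_new", "in_common"))
    expect_equal(sum(res$counts), length(genes))
    expect_equal(unname(res$counts),
                 c(2L, 1L, 3L))
})

test_that("alternative promoter scan summarizes nearest new peaks", {
    ann <- makeTestAnnotation(nGenes = 3)
    genes <- mcols(geneRanges(ann))$gene_id
    tss <- mcols(geneRanges(ann))$tss
    ## a peak 10 kb from gene 1's TSS counts as within 20 kb
    pk <- GRanges("chr1", IRanges(tss[1] + 10000, tss[1] + 10200))
    res <- alternativePromoterScan(genes, pk, ann, near = 20000)
    expect_equal(unname(res$distances["g01"]), 10000L)
    expect_equal(res$n_within, 3L)  # genes are 10 kb apart

    ## peaks on another chromosome are unreachable
    pk2 <- GRanges("chr9", IRanges(1000, 1200))
    res2 <- alternativePromoterScan(genes, pk2, ann)
    expect_true(all(is.na(res2$distances)))
    expect_equal(res2$n_within, 0L)
    expect_true(is.na(res2$median_distance))

    ## empty peak set: all unreachable
    res3 <- alternativePromoterScan(genes, GRanges(), ann)
    expect_true(all(is.na(res3$distances)))
})

test_that("gene-enhancer distances match the brute-force oracle", {
    set.seed(111)
    ann <- makeTestAnnotation(nGenes = 12, chromLen = 2e6)
    genes <- mcols(geneRanges(ann))$gene_id
    tss <- mcols(geneRanges(ann))$tss
    for (i in 1:20) {
        mkps <- function() new("PeakSet",
            peaks = sort(randomRanges(sample(3:30, 1), "chr1",
                                      maxPos = 150000)),
            mark = "H3K27ac", condition = "x", replicate = "1")
        cmp <- compareEnhancers(mkps(), mkps())
        res <- geneEnhancerDistances(genes, cmp, ann, near = 20000)
        for (cat in c("common", "unique_a", "unique_b")) {
            gr <- slot(cmp, c(common = "common", unique_a = "uniqueA",
                              unique_b = "uniqueB")[[cat]])
            d <- res$distances[[cat]]
            if (!length(gr)) {
                expect_true(all(is.na(d)))
                next
            }
            bf <- bfNearest(rep("chr1", length(genes)), tss, grDf(gr))
            expect_equal(as.numeric(d), bf$distance)
            summ <- res$summary[res$summary$category == cat, ]
            expect_equal(summ$frac_within,
                         sum(!is.na(bf$distance) &
                             bf$distance <= 20000) / length(genes))
            expect_equal(summ$median_distance,
                         median(bf$distance[!is.na(bf$distance)]))
        }
    }
    ## a TSS inside an enhancer has distance 0; a single far enhancer
    ## defines the median
    far <- new("PeakSet",
               peaks = GRanges("chr1", IRanges(tss[1] + 42000,
                                               tss[1] + 42400)),
               mark = "H3K27ac", condition = "x", replicate = "1")
    inside <- new("PeakSet",
                  peaks = GRanges("chr1", IRanges(tss[1] - 10, tss[1] + 10)),
                  mark = "H3K27ac", condition = "y", replicate = "1")
    cmp2 <- compareEnhancers(inside, far)
    res2 <- geneEnhancerDistances(genes[1], cmp2, ann)
    expect_equal(res2$distances$unique_a[1], 0L)
    expect_equal(res2$summary$median_distance[
        res2$summary$category == "unique_b"], 42000)
    expect_equal(res2$summary$frac_within[
        res2$summary$category == "unique_b"], 0)
})

test_that("intragenic enhancer counting is midpoint-based and half-open", {
    ann <- makeTestAnnotation(nGenes = 2)   # gene 1: 1001-5000
    genes <- mcols(geneRanges(ann))$gene_id
    ## midpoint exactly at the base after the gene end is not counted
    beyond <- GRanges("chr1", IRanges(4901, 5101))   # midpoint 5001
    atEnd <- GRanges("chr1", IRanges(4899, 5101))    # midpoint 5000
    mk <- function(gr, cond) new("PeakSet", peaks = gr, mark = "H3K27ac",
                                 condition = cond, replicate = "1")
    cmpBeyond <- compareEnhancers(mk(GRanges(), "a"), mk(beyond, "b"))
    cmpAt <- compareEnhancers(mk(GRanges(), "a"), mk(atEnd, "b"))
    expect_equal(countIntragenicEnhancers(genes, cmpBeyond,
                                          ann)$counts$unique_b[1], 0L)
    expect_equal(countIntragenicEnhancers(genes, cmpAt,
                                          ann)$counts$unique_b[1], 1L)

    ## three planted unique-B enhancers: count 3 and the spreading flag
    three <- GRanges("chr1", IRanges(c(2000, 2800, 3600), width = 400))
    cmp3 <- compareEnhancers(mk(GRanges(), "a"), mk(three, "b"))
    res3 <- countIntragenicEnhancers(genes, cmp3, ann)
    expect_equal(res3$counts$unique_b[1], 3L)
    expect_true(res3$counts$spreading[1])
    expect_equal(res3$counts$unique_b_intronic[1] +
                 res3$counts$unique_b_exonic[1], 3L)
    expect_equal(sum(res3$histogram), length(genes))
})

test_that("intragenic counts match the brute-force oracle", {
    set.seed(121)
    ann <- makeTestAnnotation(nGenes = 10, chromLen = 2e6)
    genes <- mcols(geneRanges(ann))$gene_id
    spans <- grDf(geneRanges(ann))
    for (i in 1:20) {
        a <- sort(randomRanges(sample(3:40, 1), "chr1", maxPos = 120000))
        b <- sort(randomRanges(sample(3:40, 1), "chr1", maxPos = 120000))
        cmp <- compareEnhancers(
            new("PeakSet", peaks = a, mark = "H3K27ac", condition = "a",
                replicate = "1"),
            new("PeakSet", peaks = b, mark = "H3K27ac", condition = "b",
                replicate = "1"))
        res <- countIntragenicEnhancers(genes, cmp, ann)
        expect_equal(res$counts$common, bfIntragenic(grDf(cmp@common),
                                                     spans))
        expect_equal(res$counts$unique_a, bfIntragenic(grDf(cmp@uniqueA),
                                                       spans))
        expect_equal(res$counts$unique_b, bfIntragenic(grDf(cmp@uniqueB),
                                                       spans))
        expect_equal(res$counts$unique_b_intronic +
                     res$counts$unique_b_exonic, res$counts$unique_b)
    }
})

test_that("CGI promoters are TSS-inside-island, half-open at the edge", {
    ann <- makeTestAnnotation(nGenes = 2)   # tss 1001, 11001
    ## islands as 0-based [1000, 2000) and [10000, 11000): 1-based ends 2000
    ## and 11000, so tss 11001 sits one base past its island
    cgi <- GRanges("chr1", IRanges(c(1001, 10001), c(2000, 11000)))
    res <- promoterCgiClassification(c("g01", "g02"), cgi, ann)
    expect_equal(unname(res$is_cgi), c(TRUE, FALSE))
    expect_equal(res$mean_cgi_length, 1000)
    resE <- promoterCgiClassification(c("g01", "g02"), GRanges(), ann)
    expect_false(any(resE$is_cgi))
    expect_true(is.na(resE$mean_cgi_length))
})

test_that("TATA scan honors the offset window, W code and mismatches", {
    L <- 150
    base <- strrep("C", L)
    plant <- function(inst, off) {
        s <- base
        substr(s, L + off, L + off + 6) <- inst
        s
    }
    ## exact instance at -30
    res <- tataScan(plant("TATAAAA", -30))
    expect_true(res$has_tata)
    expect_equal(res$best_offset, -30L)
    expect_equal(res$mismatches, 0L)
    ## one mismatch at the W position (C not in {A,T})
    expect_true(tataScan(plant("TATACAA", -30))$has_tata)
    expect_equal(tataScan(plant("TATACAA", -30))$mismatches, 1L)
    ## two mismatches fail at maxMismatch = 1
    expect_false(tataScan(plant("TACACAA", -30))$has_tata)
    ## outside the window: no hit
    expect_false(tataScan(plant("TATAAAA", -50))$has_tata)
    expect_false(tataScan(plant("TATAAAA", -10))$has_tata)
    ## N matches nothing: one N on top of one mismatch pushes past the cap
    expect_false(tataScan(plant("TANACAA", -30))$has_tata)
    expect_true(tataScan(plant("TANAAAA", -30))$has_tata)
    ## too-short sequence errors
    expect_error(tataScan(strrep("A", 30)), "too short")
})

test_that("allowing fewer mismatches never finds more TATA boxes", {
    set.seed(131)
    seqs <- vapply(1:200, function(i)
        paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = ""),
        character(1))
    hit0 <- tataScan(seqs, maxMismatch = 0)$has_tata
    hit1 <- tataScan(seqs, maxMismatch = 1)$has_tata
    expect_true(all(hit1[hit0]))
})
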