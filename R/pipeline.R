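#' Default analysis parameters
#'
#' Every numeric constant of the pipeline in one place, at the study's
#' values: coverage filter 3x, promoter window -100/+700, TSS proximity
#' 2 kb, high-methylation cutoff 0.5, de-repression log2 cuts 1.5/2.5,
#' differential thresholds P < 0.05 and fold change > 1.2, "nearby"
#' distance 20 kb, profile flank 2,500 bp with 100-bp bins, and 1,000
#' random 10-kb regions.
#'
#' @param minCoverage,upstream,downstream,proximalWindow,methHighCutoff
#'   See description.
#' @param lowCut,highCut,pCut,fcCut,near,profileFlank,profileBin
#'   See description.
#' @param nRandomRegions,randomRegionWidth Random-region compartment size.
#' @param seed Seed for the random-region draw.
#' @return A named list of parameters.
#' @export
analysisParams <- function(minCoverage = 3, upstream = 100,
                           downstream = 700, proximalWindow = 2000,
                           methHighCutoff = 0.5, lowCut = 1.5,
                           highCut = 2.5, pCut = 0.05, fcCut = 1.2,
                           near = 20000, profileFlank = 2500,
                           profileBin = 100, nRandomRegions = 1000,
                           randomRegionWidth = 10000, seed = 1) {
    as.list(environment())
}

#' Run the full integrative analysis
#'
#' Orchestrates the whole comparison of a parental and a demethylated
#' epigenome: replicate consensus for every mark, promoter-proximal /
#' distal splitting, enhancer definition and comparison with compartment
#' and parental-methylation annotation, the poised-enhancer fraction,
#' compartment methylation medians, expression classing, the de-repressed
#' promoter H3K4me3 overlap and alternative-promoter scan, TSS-enhancer
#' distances and intragenic enhancer counts for the up- and down-regulated
#' sets, CGI/TATA promoter characterization, and the tumor-suppressor
#' overlap. Deterministic given inputs and `params$seed`.
#'
#' @param inputs A [SyntheticBundle] or the list returned by
#'   [readBundle()]: `annotation`, `methParental`, `methDerived`, `peaks`
#'   (named `<mark>_<condition>_rep<i>`), `expression`, and optionally
#'   `cgi`, `promoterSeq`, `tsg`.
#' @param params [analysisParams()].
#' @return A list with `manifest` (headline counts/fractions/medians,
#'   JSON-ready) and `tables` (per-analysis tables).
#' @export
runFullAnalysis <- function(inputs, params = analysisParams()) {
    if (is(inputs, "SyntheticBundle"))
        inputs <- list(annotation = inputs@annotation,
                       methParental = inputs@methParental,
                       methDerived = inputs@methDerived,
                       peaks = inputs@peaks,
                       expression = inputs@expression,
                       cgi = inputs@cgi,
                       promoterSeq = inputs@promoterSeq,
                       tsg = inputs@tsg)
    ann <- inputs$annotation
    p <- params
    condA <- conditionLabel(inputs$methParental)
    condB <- conditionLabel(inputs$methDerived)
    stage <- function(name, expr) tryCatch(expr, error = function(e)
        .stopf("stage '%s' failed: %s", name, conditionMessage(e)))

    cons <- stage("consensus", {
        pk <- inputs$peaks
        out <- list()
        for (mark in unique(vapply(pk, function(x) x@mark, character(1))))
            for (cond in c(condA, condB)) {
                r1 <- pk[[paste0(mark, "_", cond, "_rep1")]]
                r2 <- pk[[paste0(mark, "_", cond, "_rep2")]]
                if (!is.null(r1) && !is.null(r2))
                    out[[paste0(mark, "_", cond)]] <- consensusPeaks(r1, r2)
            }
        out
    })

    ## enhancers: promoter-distal H3K27ac in each condition
    enh <- stage("enhancers", {
        eA <- defineEnhancers(cons[[paste0("H3K27ac_", condA)]], ann,
                              p$proximalWindow)
        eB <- defineEnhancers(cons[[paste0("H3K27ac_", condB)]], ann,
                              p$proximalWindow)
        cmp <- compareEnhancers(eA, eB)
        cmp <- annotateCompartment(cmp, ann)
        cmp <- enhancerParentalMethylation(cmp, inputs$methParental,
                                           p$minCoverage)
        cmp
    })
    poised <- stage("poised", {
        k4me1 <- cons[[paste0("H3K4me1_", condA)]]
        if (is.null(k4me1) || !length(enh@uniqueB)) NA_real_
        else poisedFraction(enh@uniqueB, k4me1)
    })

    ## methylation compartments
    randomRegions <- sampleRandomRegions(
        seqlengths(geneRanges(ann)), p$nRandomRegions,
        p$randomRegionWidth, seed = p$seed)
    medians <- stage("compartment_medians",
        compartmentMedians(inputs$methParental, inputs$methDerived, ann,
                           randomRegions, p$minCoverage, p$upstream,
                           p$downstream))

    ## promoter methylation state
    promWin <- promoterWindows(ann, p$upstream, p$downstream)
    promMeth <- aggregateRegionMethylation(inputs$methParental, promWin,
                                           p$minCoverage)
    promState <- classifyPromoterMethylation(promMeth$mean_meth,
                                             p$methHighCutoff)

    ## expression classes
    classes <- stage("expression",
        classifyGenes(inputs$expression, p$lowCut, p$highCut, p$pCut,
                      p$fcCut))
    clsVec <- stats::setNames(as.character(classes$class),
                              classes$gene_id)
    drGenes <- classes$gene_id[classes$class == "de_repressed"]
    upGenes <- classes$gene_id[classes$class == "up"]
    downGenes <- classes$gene_id[classes$class == "down"]

    ## de-repressed promoters vs H3K4me3
    k4 <- stage("derepressed_k4me3", {
        a <- splitByTssProximity(cons[[paste0("H3K4me3_", condA)]], ann,
                                 p$proximalWindow)$proximal
        b <- splitByTssProximity(cons[[paste0("H3K4me3_", condB)]], ann,
                                 p$proximalWindow)$proximal
        newB <- peakRanges(b)[!rangesOverlap(peakRanges(b), peakRanges(a))]
        commonB <- peakRanges(b)[rangesOverlap(peakRanges(b),
                                               peakRanges(a))]
        ov <- derepressedK4me3Overlap(drGenes, newB, commonB, ann,
                                      p$proximalWindow)
        neither <- names(ov$status)[ov$status == "neither"]
        alt <- alternativePromoterScan(neither, newB, ann, p$near)
        list(newB = newB, overlap = ov, alt = alt)
    })

    ## enhancer-gene distance structure
    distUp <- geneEnhancerDistances(upGenes, enh, ann, p$near)
    distDown <- geneEnhancerDistances(downGenes, enh, ann, p$near)
    intraUp <- countIntragenicEnhancers(upGenes, enh, ann)
    intraDown <- countIntragenicEnhancers(downGenes, enh, ann)

    ## promoter characterization (optional inputs)
    cgiRes <- tataRes <- tsgRes <- NULL
    if (!is.null(inputs$cgi)) {
        cgiRes <- lapply(list(de_repressed = drGenes, up = upGenes,
                              down = downGenes), function(g)
            promoterCgiClassification(g, inputs$cgi, ann))
    }
    if (!is.null(inputs$promoterSeq)) {
        tataRes <- lapply(list(de_repressed = drGenes, up = upGenes,
                               down = downGenes), function(g) {
            sc <- tataScan(inputs$promoterSeq[g])
            mean(sc$has_tata)
        })
    }
    if (!is.null(inputs$tsg)) {
        g <- geneRanges(ann)
        nameOf <- stats::setNames(mcols(g)$name, mcols(g)$gene_id)
        tsgRes <- list(
            de_repressed = annotateTsg(unname(nameOf[drGenes]),
                                       inputs$tsg),
            up = annotateTsg(unname(nameOf[upGenes]), inputs$tsg))
    }

    venn <- vennCounts(enh)
    manifest <- list(
        conditions = c(condA, condB),
        n_genes = nrow(classes),
        class_sizes = as.list(table(classes$class)),
        promoter_state_counts = as.list(table(promState)),
        compartment_medians_percent = list(
            parental = as.list(round(100 * medians[1, ], 4)),
            derived = as.list(round(100 * medians[2, ], 4))),
        enhancer_venn = venn,
        enhancer_compartments = lapply(
            list(common = enh@common, unique_a = enh@uniqueA,
                 unique_b = enh@uniqueB),
            function(gr) as.list(table(mcols(gr)$compartment))),
        enhancer_parental_meth_median = lapply(
            list(common = enh@common, unique_a = enh@uniqueA,
                 unique_b = enh@uniqueB),
            function(gr) {
                v <- mcols(gr)$parental_meth
                if (all(is.na(v))) NA else stats::median(v, na.rm = TRUE)
            }),
        poised_fraction = poised,
        derepressed_k4me3 = as.list(k4$overlap$counts),
        alternative_promoter = list(
            n_genes = length(k4$overlap$status[
                k4$overlap$status == "neither"]),
            n_within = k4$alt$n_within,
            median_distance = k4$alt$median_distance),
        gene_enhancer_distances = list(up = distUp$summary,
                                       down = distDown$summary),
        intragenic_enhancers = list(up = as.list(intraUp$totals),
                                    down = as.list(intraDown$totals)),
        cgi = if (!is.null(cgiRes)) lapply(cgiRes, function(x)
            list(frac_cgi = mean(x$is_cgi),
                 mean_cgi_length = x$mean_cgi_length)),
        tata_fraction = tataRes,
        tsg_overlap = if (!is.null(tsgRes)) lapply(tsgRes, length))

    tables <- list(gene_classes = classes,
                   promoter_methylation = DataFrame(
                       gene_id = names(promWin),
                       mean_meth = promMeth$mean_meth,
                       n_cpgs_used = promMeth$n_cpgs_used,
                       state = promState),
                   enhancer_comparison = enh,
                   distances_up = distUp$distances,
                   distances_down = distDown$distances,
                   intragenic_up = intraUp$counts,
                   intragenic_down = intraDown$counts,
                   derepressed_k4me3 = k4$overlap$status,
                   alt_promoter_distances = k4$alt$distances)
    list(manifest = manifest, tables = tables)
}
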