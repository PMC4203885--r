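#' Accessors for DemethylScope classes
#'
#' `geneRanges()`, `exonRanges()` and `intronRanges()` expose the gene
#' models of a [GenomeAnnotation]; `methCalls()` the CpG calls of a
#' [MethylationCalls]; `peakRanges()` the intervals of a [PeakSet];
#' `exprValues()` the matrix of an [ExpressionTable]; `conditionLabel()`
#' the condition of an object that carries one. `vennCounts()` summarizes an
#' [EnhancerComparison] as the four numbers of its Venn diagram.
#'
#' @param object An object of the documented class.
#' @return `geneRanges`/`peakRanges`: a `GRanges`; `exonRanges`,
#'   `intronRanges`: a `GRangesList` named by gene id; `methCalls`: a
#'   width-1 `GRanges` with `meth` and `coverage`; `exprValues`: a numeric
#'   matrix; `conditionLabel`: a character scalar (length 2 for an
#'   [EnhancerComparison]); `vennCounts`: a list with `common_a`,
#'   `common_b`, `unique_a`, `unique_b`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneRanges", function(object) standardGeneric("geneRanges"))
#' @rdname accessors
#' @export
setGeneric("exonRanges", function(object) standardGeneric("exonRanges"))
#' @rdname accessors
#' @export
setGeneric("intronRanges", function(object) standardGeneric("intronRanges"))
#' @rdname accessors
#' @export
setGeneric("methCalls", function(object) standardGeneric("methCalls"))
#' @rdname accessors
#' @export
setGeneric("peakRanges", function(object) standardGeneric("peakRanges"))
#' @rdname accessors
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("conditionLabel",
    function(object) standardGeneric("conditionLabel"))
#' @rdname accessors
#' @export
setGeneric("vennCounts", function(object) standardGeneric("vennCounts"))

#' @rdname accessors
#' @export
setMethod("geneRanges", "GenomeAnnotation", function(object) object@genes)

#' @rdname accessors
#' @export
setMethod("exonRanges", "GenomeAnnotation", function(object) object@exons)

#' @rdname accessors
#' @export
setMethod("intronRanges", "GenomeAnnotation", function(object) {
    ## complement of the exons within each gene span
    sp <- object@genes
    names(sp) <- mcols(sp)$gene_id
    IRanges::psetdiff(sp, object@exons)
})

#' @rdname accessors
#' @export
setMethod("methCalls", "MethylationCalls", function(object) object@calls)

#' @rdname accessors
#' @export
setMethod("peakRanges", "PeakSet", function(object) object@peaks)

#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionTable", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("conditionLabel", "MethylationCalls",
    function(object) object@condition)

#' @rdname accessors
#' @export
setMethod("conditionLabel", "PeakSet", function(object) object@condition)

#' @rdname accessors
#' @export
setMethod("conditionLabel", "EnhancerComparison",
    function(object) object@conditions)

#' @rdname accessors
#' @export
setMethod("vennCounts", "EnhancerComparison", function(object) {
    list(common_a = length(object@common),
         common_b = metadata(object@common)$n_common_b,
         unique_a = length(object@uniqueA),
         unique_b = length(object@uniqueB))
})
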