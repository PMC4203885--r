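#' @import methods
#' @import GenomicRanges
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#'   runValue endoapply queryHits subjectHits
#' @importFrom IRanges IRanges subsetByOverlaps
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
#'   seqlevels<- Seqinfo seqinfo seqinfo<-
#' @importFrom BiocGenerics start end width strand strand<-
#' @importFrom utils head
#' @importFrom stats median setNames
#' @importClassesFrom Biostrings DNAStringSet
NULL

.CHIP_MARKS <- c("H3K4me3", "H3K27ac", "H3K4me1", "RNAPII")

#' GenomeAnnotation: one-transcript gene models with exon structure
#'
#' Holds the gene models every analysis is anchored on: one transcript model
#' per gene, with the gene span running from the TSS to the transcript end,
#' an explicit strand-oriented TSS, and non-overlapping exons whose
#' within-span complement defines the introns. Chromosome lengths travel in
#' the `seqinfo` of the gene ranges.
#'
#' @slot genes A [GenomicRanges::GRanges] with one range per gene and
#'   metadata columns `gene_id`, `name` and `tss` (1-based TSS position;
#'   equal to `start` on `+` genes and `end` on `-` genes).
#' @slot exons A [GenomicRanges::GRangesList] parallel to `genes`
#'   (same names, in the same order), each element sorted and disjoint and
#'   contained in the gene span.
#'
#' @seealso [readAnnotation()], [geneRanges()], [exonRanges()],
#'   [intronRanges()], [promoterWindows()]
#' @export
setClass("GenomeAnnotation",
    slots = c(genes = "GRanges", exons = "GRangesList"))

setValidity("GenomeAnnotation", function(object) {
    g <- object@genes
    msg <- character()
    need <- c("gene_id", "name", "tss")
    if (!all(need %in% colnames(mcols(g))))
        return(paste("genes must carry metadata columns:",
                     paste(need, collapse = ", ")))
    ids <- mcols(g)$gene_id
    if (anyDuplicated(ids))
        msg <- c(msg, "gene_ids must be unique")
    if (length(g)) {
        plus <- as.character(strand(g)) == "+"
        minus <- as.character(strand(g)) == "-"
        tss <- mcols(g)$tss
        if (any(plus & tss != start(g)) || any(minus & tss != end(g)))
            msg <- c(msg, "tss must equal start on '+' and end on '-' genes")
        if (any(!plus & !minus))
            msg <- c(msg, "gene strand must be '+' or '-'")
        sl <- seqlengths(g)[as.character(seqnames(g))]
        bad <- !is.na(sl) & (end(g) > sl | start(g) < 1L)
        if (any(bad))
            msg <- c(msg, "gene spans must lie inside their chromosome")
    }
    if (length(object@exons) != length(g))
        msg <- c(msg, "exons must be parallel to genes")
    if (length(g) && !identical(names(object@exons), as.character(ids)))
        msg <- c(msg, "exons must be named by gene_id, in gene order")
    if (length(g)) {
        es <- BiocGenerics::start(object@exons)
        ee <- BiocGenerics::end(object@exons)
        if (any(min(es) < start(g)) || any(max(ee) > end(g)))
            msg <- c(msg, "exons must lie within their gene span")
        red <- range(IRanges::reduce(object@exons))
        if (any(sum(IRanges::width(IRanges::reduce(object@exons))) !=
                sum(IRanges::width(object@exons))))
            msg <- c(msg, "exons of a gene must be non-overlapping")
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' MethylationCalls: per-CpG methylation fractions for one condition
#'
#' A sorted, per-chromosome-unique set of CpG methylation calls: one width-1
#' position per CpG with the methylated fraction (in `[0, 1]`) and the read
#' coverage supporting it. Coverage-0 calls are retained at this stage and
#' excluded later by the coverage filter in [aggregateRegionMethylation()].
#'
#' @slot calls A width-1 [GenomicRanges::GRanges] with metadata columns
#'   `meth` (numeric fraction) and `coverage` (integer).
#' @slot condition Single condition label, e.g. `"parental"`.
#'
#' @seealso [readMethylation()], [aggregateRegionMethylation()]
#' @export
setClass("MethylationCalls",
    slots = c(calls = "GRanges", condition = "character"))

setValidity("MethylationCalls", function(object) {
    gr <- object@calls
    msg <- character()
    if (length(object@condition) != 1L)
        msg <- c(msg, "condition must be a single label")
    if (!all(c("meth", "coverage") %in% colnames(mcols(gr))))
        return("calls must carry metadata columns meth and coverage")
    if (length(gr)) {
        if (any(width(gr) != 1L))
            msg <- c(msg, "calls must be width-1 positions")
        m <- mcols(gr)$meth
        if (any(m < 0 | m > 1, na.rm = TRUE))
            msg <- c(msg, "meth fractions must lie in [0, 1]")
        if (any(mcols(gr)$coverage < 0L))
            msg <- c(msg, "coverage must be >= 0")
        if (is.unsorted(order(as.integer(seqnames(gr)), start(gr))))
            msg <- c(msg, "calls must be sorted")
        if (any(duplicated(paste(seqnames(gr), start(gr)))))
            msg <- c(msg, "positions must be unique per chromosome")
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' PeakSet: called ChIP-seq peaks for one mark, condition and replicate
#'
#' Container for the output of an external peak caller: an interval set for
#' one histone mark (or RNAPII), one condition and one replicate. Scores are
#' carried along if present but never used for classification.
#'
#' @slot peaks A sorted [GenomicRanges::GRanges].
#' @slot mark One of `H3K4me3`, `H3K27ac`, `H3K4me1`, `RNAPII`.
#' @slot condition Condition label.
#' @slot replicate Replicate identifier.
#'
#' @seealso [readPeaks()], [consensusPeaks()], [splitByTssProximity()]
#' @export
setClass("PeakSet",
    slots = c(peaks = "GRanges", mark = "character",
              condition = "character", replicate = "character"))

setValidity("PeakSet", function(object) {
    msg <- character()
    if (length(object@mark) != 1L || !object@mark %in% .CHIP_MARKS)
        msg <- c(msg, paste("mark must be one of:",
                            paste(.CHIP_MARKS, collapse = ", ")))
    if (length(object@condition) != 1L || length(object@replicate) != 1L)
        msg <- c(msg, "condition and replicate must be single labels")
    if (length(object@peaks) &&
        is.unsorted(order(as.integer(seqnames(object@peaks)),
                          start(object@peaks), end(object@peaks))))
        msg <- c(msg, "peaks must be sorted")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' EnhancerComparison: common/unique partition of two enhancer sets
#'
#' Result of [compareEnhancers()]: enhancers of condition A that overlap at
#' least one condition-B enhancer (`common`, reported in A's coordinates with
#' the number of matched B enhancers), the remaining A enhancers
#' (`uniqueA`), and the B enhancers with no A overlap (`uniqueB`). Because
#' overlaps can be many-to-one, the common count seen from B's side is kept
#' in `metadata(common)$n_common_b`. Compartment labels and parental
#' methylation are attached by [annotateCompartment()] and
#' [enhancerParentalMethylation()].
#'
#' @slot common,uniqueA,uniqueB [GenomicRanges::GRanges] of enhancer
#'   intervals; metadata columns `compartment` and `parental_meth` are filled
#'   by the annotation helpers.
#' @slot conditions Character vector of length 2: the A and B labels.
#'
#' @export
setClass("EnhancerComparison",
    slots = c(common = "GRanges", uniqueA = "GRanges", uniqueB = "GRanges",
              conditions = "character"))

setValidity("EnhancerComparison", function(object) {
    if (length(object@conditions) != 2L)
        return("conditions must name the two compared conditions")
    TRUE
})

#' ExpressionTable: normalized expression with replicate structure
#'
#' Normalized, linear-scale expression values (rows = genes, columns =
#' samples) together with the condition each column belongs to. Per-condition
#' means of `log2(x + pseudocount)` drive the gene classing.
#'
#' @slot values Non-negative numeric matrix, rownames = gene ids.
#' @slot condition Factor parallel to the columns of `values` with exactly
#'   two levels (condition A first).
#'
#' @seealso [readExpression()], [classifyGenes()]
#' @export
setClass("ExpressionTable",
    slots = c(values = "matrix", condition = "factor"))

setValidity("ExpressionTable", function(object) {
    msg <- character()
    v <- object@values
    if (is.null(rownames(v)))
        msg <- c(msg, "values must have gene ids as rownames")
    if (any(!is.finite(v)) || any(v < 0))
        msg <- c(msg, "expression values must be finite and >= 0")
    if (length(object@condition) != ncol(v))
        msg <- c(msg, "condition must be parallel to the columns")
    if (nlevels(object@condition) != 2L)
        msg <- c(msg, "exactly two conditions are required")
    else if (any(table(object@condition) < 1L))
        msg <- c(msg, "every condition needs at least one replicate")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' SyntheticBundle: a generated epigenome with ground truth
#'
#' In-memory result of [simulateEpigenome()]: every input the pipeline reads
#' (annotation, two methylomes, replicated peak sets, expression, CpG
#' islands, promoter sequences, tumor-suppressor list) plus the planted
#' ground-truth labels and the generating configuration.
#'
#' @slot annotation A [GenomeAnnotation].
#' @slot methParental,methDerived [MethylationCalls] for the two conditions.
#' @slot peaks Named list of [PeakSet] (`<mark>_<condition>_rep<i>`).
#' @slot expression An [ExpressionTable].
#' @slot cgi [GenomicRanges::GRanges] of CpG islands.
#' @slot promoterSeq [Biostrings::DNAStringSet] of promoter sequences whose
#'   last base is the TSS, named by gene id.
#' @slot tsg Character vector of tumor-suppressor gene names.
#' @slot truth List with `genes` and `enhancers` data frames of planted
#'   labels.
#' @slot config The [syntheticConfig()] list used for generation.
#'
#' @export
setClass("SyntheticBundle",
    slots = c(annotation = "GenomeAnnotation",
              methParental = "MethylationCalls",
              methDerived = "MethylationCalls",
              peaks = "list",
              expression = "ExpressionTable",
              cgi = "GRanges",
              promoterSeq = "DNAStringSet",
              tsg = "character",
              truth = "list",
              config = "list"))

## -- show methods ----------------------------------------------------------

setMethod("show", "GenomeAnnotation", function(object) {
    cat("GenomeAnnotation with", length(object@genes), "genes on",
        length(seqlevels(object@genes)), "chromosomes\n")
    if (length(object@genes))
        cat("  exons per gene:",
            paste(range(lengths(object@exons)), collapse = "-"), "\n")
})

setMethod("show", "MethylationCalls", function(object) {
    cat("MethylationCalls [", object@condition, "]: ",
        length(object@calls), " CpGs", sep = "")
    if (length(object@calls))
        cat(", mean meth ",
            round(mean(mcols(object@calls)$meth), 3), sep = "")
    cat("\n")
})

setMethod("show", "PeakSet", function(object) {
    cat("PeakSet ", object@mark, " [", object@condition, "/",
        object@replicate, "]: ", length(object@peaks), " peaks\n", sep = "")
})

setMethod("show", "EnhancerComparison", function(object) {
    v <- vennCounts(object)
    cat("EnhancerComparison ", object@conditions[1], " vs ",
        object@conditions[2], "\n", sep = "")
    cat("  common (A view): ", v$common_a, "   common (B view): ",
        v$common_b, "\n  unique to ", object@conditions[1], ": ",
        v$unique_a, "\n  unique to ", object@conditions[2], ": ",
        v$unique_b, "\n", sep = "")
})

setMethod("show", "ExpressionTable", function(object) {
    cat("ExpressionTable:", nrow(object@values), "genes,",
        ncol(object@values), "samples (",
        paste(levels(object@condition), collapse = " vs "), ")\n")
})

setMethod("show", "SyntheticBundle", function(object) {
    cat("SyntheticBundle:", length(object@annotation@genes), "genes,",
        length(object@methParental@calls), "CpGs,",
        length(object@peaks), "peak sets\n")
})
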