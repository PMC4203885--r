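#' Read a normalized expression table with replicate columns
#'
#' Expects a TSV with a header: a gene id column (first, or named
#' `gene_id`) and one column per sample named `<condition>_<replicate>`
#' (e.g. `parental_rep1`). Values are normalized, linear-scale and
#' non-negative.
#'
#' @param path Input TSV.
#' @param conditionA Optional: which condition label is condition A (the
#'   baseline). Defaults to the first condition seen in the header.
#' @return An [ExpressionTable].
#' @export
readExpression <- function(path, conditionA = NULL) {
    if (!file.exists(path)) .stopf("expression file not found: %s", path)
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             check.names = FALSE,
                             stringsAsFactors = FALSE)
    idCol <- if ("gene_id" %in% names(tab)) "gene_id" else names(tab)[1]
    ids <- as.character(tab[[idCol]])
    val <- as.matrix(tab[setdiff(names(tab), idCol)])
    if (!is.numeric(val)) .stopf("%s: non-numeric expression values", path)
    if (anyNA(val))
        .stopf("%s: missing expression value (gene %s)",
               path, ids[which(rowSums(is.na(val)) > 0)[1]])
    if (any(val < 0)) {
        bad <- which(rowSums(val < 0) > 0)[1]
        .stopf("%s: negative expression value for gene %s", path, ids[bad])
    }
    cond <- sub("_[^_]*$", "", colnames(val))
    if (length(unique(cond)) != 2L)
        .stopf("%s: header must name exactly two conditions, got: %s",
               path, paste(unique(cond), collapse = ", "))
    if (is.null(conditionA)) conditionA <- cond[1]
    if (!conditionA %in% cond)
        .stopf("conditionA '%s' not present in header", conditionA)
    rownames(val) <- ids
    makeExpressionTable(val, cond, conditionA)
}

#' Construct an ExpressionTable from a matrix
#' @param values Non-negative matrix, rownames = gene ids.
#' @param condition Character/factor per column.
#' @param conditionA Baseline condition label (first level).
#' @return An [ExpressionTable].
#' @export
makeExpressionTable <- function(values, condition,
                                conditionA = condition[1]) {
    lev <- c(conditionA, setdiff(unique(as.character(condition)),
                                 conditionA))
    new("ExpressionTable", values = values,
        condition = factor(as.character(condition), levels = lev))
}

#' Write an ExpressionTable in the format readExpression() reads
#' @param expr An [ExpressionTable].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(expr, path) {
    v <- exprValues(expr)
    df <- data.frame(gene_id = rownames(v), check.names = FALSE)
    df <- cbind(df, as.data.frame(signif(v, 7)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Per-condition means of log2(x + pseudocount)
#'
#' @param expr An [ExpressionTable].
#' @param pseudocount Added before the log2, default 1.
#' @return Matrix, genes x 2 conditions, of mean log2 values.
#' @export
log2Means <- function(expr, pseudocount = 1) {
    .condMeans(log2(exprValues(expr) + pseudocount), expr@condition)
}

## per-condition means of linear values
.linearMeans <- function(expr) {
    .condMeans(exprValues(expr), expr@condition)
}

.condMeans <- function(v, condition) {
    lev <- levels(condition)
    out <- matrix(NA_real_, nrow(v), length(lev),
                  dimnames = list(rownames(v), lev))
    for (l in lev)
        out[, l] <- rowMeans(v[, condition == l, drop = FALSE])
    out
}

#' De-repressed genes: silent in A, active in B
#'
#' Genes with mean `log2(x+1)` strictly below `lowCut` in condition A and
#' strictly above `highCut` in condition B (the study used 1.5 and 2.5) —
#' promoters that were methylation-silenced in the parental line and fired
#' up after demethylation.
#'
#' @param expr An [ExpressionTable].
#' @param lowCut,highCut Strict log2 cutoffs, defaults 1.5 and 2.5.
#' @param pseudocount Pseudocount for the log2 transform, default 1.
#' @return Character vector of de-repressed gene ids.
#' @export
classifyDerepressed <- function(expr, lowCut = 1.5, highCut = 2.5,
                                pseudocount = 1) {
    stopifnot(lowCut < highCut)
    lm <- log2Means(expr, pseudocount)
    rownames(lm)[lm[, 1] < lowCut & lm[, 2] > highCut]
}

#' Built-in two-group location test
#'
#' Two-sided Welch (unequal-variance) t-test on `log2(x + pseudocount)`
#' replicate values. This is a documented stand-in for the model-based test
#' used in the original study; externally computed p-values can be supplied
#' to [classifyDifferential()] instead.
#'
#' @param valuesA,valuesB Linear replicate values (length >= 2 each).
#' @param pseudocount Pseudocount, default 1.
#' @return A p-value in (0, 1].
#' @export
builtinDeTest <- function(valuesA, valuesB, pseudocount = 1) {
    if (length(valuesA) < 2L || length(valuesB) < 2L)
        .stopf("builtinDeTest needs >= 2 replicates per group")
    la <- log2(valuesA + pseudocount)
    lb <- log2(valuesB + pseudocount)
    if (stats::var(la) == 0 && stats::var(lb) == 0)
        return(if (mean(la) == mean(lb)) 1 else .Machine$double.xmin)
    p <- tryCatch(stats::t.test(la, lb)$p.value, error = function(e) 1)
    max(p, .Machine$double.xmin)
}

#' Up/down/unchanged classification by p-value and fold change
#'
#' A gene is `up` when `p < pCut` and the linear fold change B/A strictly
#' exceeds `fcCut`, `down` when `p < pCut` and A/B exceeds `fcCut`, and
#' `unchanged` otherwise (the study used raw P < 0.05 and fold change >
#' 1.2). Fold change is the ratio of per-condition means of the linear
#' normalized values; genes with both means 0 are `unchanged`. Genes listed
#' in `exclude` (e.g. already classed de-repressed) are dropped first.
#'
#' @param expr An [ExpressionTable].
#' @param pValues Optional named per-gene p-values; when absent,
#'   [builtinDeTest()] is run per gene (requires >= 2 replicates per
#'   condition).
#' @param pCut,fcCut Thresholds, defaults 0.05 and 1.2.
#' @param exclude Gene ids to leave out of the classification.
#' @param pseudocount Pseudocount for the built-in test.
#' @return Named character vector (`up`/`down`/`unchanged`) over the
#'   non-excluded genes.
#' @export
classifyDifferential <- function(expr, pValues = NULL, pCut = 0.05,
                                 fcCut = 1.2, exclude = character(),
                                 pseudocount = 1) {
    v <- exprValues(expr)
    keep <- setdiff(rownames(v), exclude)
    lin <- .linearMeans(expr)[keep, , drop = FALSE]
    if (is.null(pValues)) {
        if (min(table(expr@condition)) < 2L)
            .stopf("built-in test needs >= 2 replicates per condition")
        a <- v[keep, expr@condition == levels(expr@condition)[1],
               drop = FALSE]
        b <- v[keep, expr@condition == levels(expr@condition)[2],
               drop = FALSE]
        p <- vapply(seq_along(keep), function(i)
            builtinDeTest(a[i, ], b[i, ], pseudocount), numeric(1))
    } else {
        p <- unname(pValues[keep])
        if (anyNA(p)) .stopf("pValues missing for some genes")
    }
    mA <- lin[, 1]; mB <- lin[, 2]
    fcUp <- ifelse(mA == 0, ifelse(mB > 0, Inf, NA), mB / mA)
    fcDown <- ifelse(mB == 0, ifelse(mA > 0, Inf, NA), mA / mB)
    cls <- rep("unchanged", length(keep))
    cls[!is.na(fcUp) & p < pCut & fcUp > fcCut] <- "up"
    cls[!is.na(fcDown) & p < pCut & fcDown > fcCut] <- "down"
    stats::setNames(cls, keep)
}

#' Full gene classing: de-repressed, up, down, unchanged, not expressed
#'
#' Applies the class rules in order of precedence: genes with zero mean
#' expression in both conditions are `not_expressed`; then de-repressed
#' genes are taken out (silent-to-active promoters are reported separately
#' from ordinary up-regulation); the remainder are classed
#' `up`/`down`/`unchanged` by [classifyDifferential()].
#'
#' @param expr An [ExpressionTable].
#' @param lowCut,highCut De-repression cutoffs, defaults 1.5/2.5.
#' @param pCut,fcCut Differential thresholds, defaults 0.05/1.2.
#' @param pValues Optional named per-gene p-values.
#' @param pseudocount Pseudocount, default 1.
#' @return A [S4Vectors::DataFrame] with one row per gene: `gene_id`,
#'   `class`, `log2_a`, `log2_b`, `fold_change` (B/A of linear means; NA
#'   when both are 0) and `p_value` (NA where no test was run).
#' @export
classifyGenes <- function(expr, lowCut = 1.5, highCut = 2.5, pCut = 0.05,
                          fcCut = 1.2, pValues = NULL, pseudocount = 1) {
    lm <- log2Means(expr, pseudocount)
    lin <- .linearMeans(expr)
    ids <- rownames(lm)
    cls <- rep(NA_character_, length(ids))
    names(cls) <- ids
    notExpr <- lin[, 1] == 0 & lin[, 2] == 0
    cls[notExpr] <- "not_expressed"
    dr <- setdiff(classifyDerepressed(expr, lowCut, highCut, pseudocount),
                  ids[notExpr])
    cls[dr] <- "de_repressed"
    rest <- ids[is.na(cls)]
    diffCls <- classifyDifferential(expr, pValues, pCut, fcCut,
                                    exclude = ids[!is.na(cls)],
                                    pseudocount = pseudocount)
    cls[names(diffCls)] <- diffCls
    pv <- rep(NA_real_, length(ids)); names(pv) <- ids
    if (is.null(pValues)) {
        ## re-derive the p-values used, for the report
        if (min(table(expr@condition)) >= 2L && length(rest)) {
            v <- exprValues(expr)
            a <- v[rest, expr@condition == levels(expr@condition)[1],
                   drop = FALSE]
            b <- v[rest, expr@condition == levels(expr@condition)[2],
                   drop = FALSE]
            pv[rest] <- vapply(seq_along(rest), function(i)
                builtinDeTest(a[i, ], b[i, ], pseudocount), numeric(1))
        }
    } else pv[names(pValues)[names(pValues) %in% ids]] <-
        pValues[names(pValues) %in% ids]
    fc <- ifelse(lin[, 1] == 0,
                 ifelse(lin[, 2] > 0, Inf, NA), lin[, 2] / lin[, 1])
    DataFrame(gene_id = ids,
              class = factor(cls, levels = c("de_repressed", "up", "down",
                                             "unchanged",
                                             "not_expressed")),
              log2_a = lm[, 1], log2_b = lm[, 2],
              fold_change = fc, p_value = pv)
}

#' Intersect a gene set with a tumor-suppressor gene list
#'
#' Case-insensitive name intersection with a supplied TSG list (emulating a
#' lookup against the TSGene database export).
#'
#' @param genes Character vector of gene names.
#' @param tsgList Character vector of TSG names, or a path to a 1-column
#'   TSV.
#' @return The subset of `genes` present in the list (original spelling).
#' @export
annotateTsg <- function(genes, tsgList) {
    if (is.character(tsgList) && length(tsgList) == 1L &&
        file.exists(tsgList))
        tsgList <- utils::read.table(tsgList, header = FALSE,
                                     colClasses = "character")[[1]]
    if (!length(tsgList)) {
        warning("empty TSG list; returning no genes")
        return(character())
    }
    genes[tolower(genes) %in% tolower(tsgList)]
}
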