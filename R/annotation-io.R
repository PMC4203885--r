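#' Read a gene annotation (GTF-like or BED12) into a GenomeAnnotation
#'
#' Parses one-transcript-per-gene models. In the GTF dialect, `gene` rows
#' give the span and `exon` rows (grouped by the `gene_id` attribute) give
#' the exon structure; if `gene` rows are absent the span is the range of
#' each gene's exons. In BED12 the blocks are the exons. Coordinates are
#' converted to the 1-based closed convention used throughout the package.
#'
#' @param path Annotation file.
#' @param format `"gtf"` or `"bed12"`; defaults from the file extension.
#' @param chromSizes Optional path to a 2-column TSV (`chrom`, `length`) or a
#'   named vector of chromosome lengths. Needed to validate that genes fit
#'   their chromosome and to clip windows later.
#' @return A [GenomeAnnotation].
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(c(
#'   'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; gene_name "G1";',
#'   'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "g1"; gene_name "G1";'),
#'   gtf)
#' ann <- readAnnotation(gtf, chromSizes = c(chr1 = 10000))
#' geneRanges(ann)
#' @export
readAnnotation <- function(path, format = c("auto", "gtf", "bed12"),
                           chromSizes = NULL) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.bed[0-9]*$", path, ignore.case = TRUE))
            "bed12" else "gtf"
    if (!file.exists(path)) .stopf("annotation file not found: %s", path)
    sl <- .resolveChromSizes(chromSizes)
    nonEmpty <- any(!grepl("^(#|\\s*$)", readLines(path, warn = FALSE)))
    if (!nonEmpty)
        return(.makeAnnotation(GRanges(), list(), sl))
    gr <- tryCatch(
        rtracklayer::import(path, format = if (format == "gtf") "gtf"
                            else "bed"),
        error = function(e) .stopf("failed to parse %s (%s): %s",
                                   path, format, conditionMessage(e)))
    if (format == "gtf") .annotationFromGtf(gr, path, sl)
    else .annotationFromBed12(gr, path, sl)
}

.resolveChromSizes <- function(chromSizes) {
    if (is.null(chromSizes)) return(NULL)
    if (is.character(chromSizes) && length(chromSizes) == 1L &&
        file.exists(chromSizes)) {
        tab <- utils::read.table(chromSizes, sep = "\t", header = FALSE,
                                 col.names = c("chrom", "length"),
                                 colClasses = c("character", "integer"))
        return(stats::setNames(tab$length, tab$chrom))
    }
    if (is.numeric(chromSizes) && !is.null(names(chromSizes)))
        return(chromSizes)
    .stopf("chromSizes must be a 2-column TSV path or a named vector")
}

.annotationFromGtf <- function(gr, path, sl) {
    if (is.null(mcols(gr)$gene_id))
        .stopf("%s: GTF attributes must include gene_id", path)
    type <- as.character(mcols(gr)$type)
    ex <- gr[type == "exon"]
    if (!length(ex)) .stopf("%s: no exon rows found", path)
    ids <- as.character(mcols(ex)$gene_id)
    exl <- S4Vectors::split(granges(ex), factor(ids, unique(ids)))
    exl <- endoapply(exl, function(x) x[order(start(x))])
    geneRows <- gr[type %in% c("gene", "transcript")]
    nm <- mcols(ex)$gene_name
    nameOf <- if (is.null(nm)) stats::setNames(unique(ids), unique(ids))
        else stats::setNames(as.character(nm), ids)[unique(ids)]
    if (length(geneRows)) {
        gid <- as.character(mcols(geneRows)$gene_id)
        geneRows <- geneRows[!duplicated(gid)]
        gid <- gid[!duplicated(gid)]
        span <- granges(geneRows)
        names(span) <- gid
        span <- span[names(exl)]
    } else {
        span <- unlist(range(exl))
    }
    ## exons outside the declared span are a validation error
    es <- unlist(BiocGenerics::start(exl))
    .makeAnnotationChecked(span, exl, nameOf, sl, path)
}

.annotationFromBed12 <- function(gr, path, sl) {
    if (is.null(mcols(gr)$blocks))
        .stopf("%s: BED12 blocks column required", path)
    ids <- mcols(gr)$name
    if (is.null(ids) || anyDuplicated(ids))
        .stopf("%s: BED12 name column must carry unique gene ids", path)
    blocks <- mcols(gr)$blocks   # IRangesList, gene-relative
    exl <- GRangesList(lapply(seq_along(gr), function(i) {
        GRanges(seqnames(gr)[i],
                IRanges::shift(blocks[[i]], start(gr)[i] - 1L),
                strand = strand(gr)[i])
    }))
    names(exl) <- ids
    span <- granges(gr)
    names(span) <- ids
    .makeAnnotationChecked(span, exl, stats::setNames(ids, ids), sl, path)
}

.makeAnnotationChecked <- function(span, exl, nameOf, sl, path) {
    bad <- which(min(BiocGenerics::start(exl)) < start(span) |
                 max(BiocGenerics::end(exl)) > end(span))
    if (length(bad))
        .stopf("%s: exons outside gene span for gene(s): %s", path,
               paste(head(names(exl)[bad], 5), collapse = ", "))
    st <- as.character(strand(span))
    if (any(st == "*")) {
        exSt <- as.character(unlist(runValue(strand(exl))))
        st <- vapply(seq_along(exl), function(i)
            as.character(runValue(strand(exl[[i]]))[1]), character(1))
        strand(span) <- st
    }
    .makeAnnotation(span, exl, sl, nameOf)
}

.makeAnnotation <- function(span, exl, sl, nameOf = character()) {
    if (!length(span)) {
        si <- if (is.null(sl)) Seqinfo() else
            Seqinfo(names(sl), unname(sl))
        g <- GRanges(seqinfo = si)
        mcols(g) <- DataFrame(gene_id = character(), name = character(),
                              tss = integer())
        return(new("GenomeAnnotation", genes = g,
                   exons = GRangesList()))
    }
    ids <- names(span)
    st <- as.character(strand(span))
    tss <- ifelse(st == "+", start(span), end(span))
    if (!is.null(sl)) {
        lv <- union(seqlevels(span), names(sl))
        seqlevels(span) <- lv
        seqlengths(span)[names(sl)] <- unname(sl)
        exl <- GRangesList(lapply(exl, function(x) {
            seqlevels(x) <- lv
            seqlengths(x)[names(sl)] <- unname(sl)
            x
        }))
    }
    mcols(span) <- DataFrame(gene_id = ids,
                             name = unname(nameOf[ids]),
                             tss = as.integer(tss))
    names(span) <- ids
    new("GenomeAnnotation", genes = span, exons = exl)
}

#' Construct a GenomeAnnotation from ranges
#'
#' Programmatic constructor used by the synthetic generator and by tests.
#'
#' @param span Named `GRanges` of gene spans with `+`/`-` strands.
#' @param exons `GRangesList` parallel to `span` (same names).
#' @param names Optional human-readable gene names (defaults to the ids).
#' @return A [GenomeAnnotation].
#' @export
makeGenomeAnnotation <- function(span, exons, names = NULL) {
    ids <- names(span)
    if (is.null(ids)) .stopf("gene spans must be named by gene_id")
    nameOf <- stats::setNames(if (is.null(names)) ids else names, ids)
    .makeAnnotation(span, exons[ids], NULL, nameOf)
}

#' Write a GenomeAnnotation as GTF
#'
#' Emits `gene` and `exon` rows with `gene_id`/`gene_name` attributes, the
#' dialect [readAnnotation()] reads back.
#'
#' @param ann A [GenomeAnnotation].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeAnnotationGtf <- function(ann, path) {
    g <- geneRanges(ann)
    attr1 <- sprintf('gene_id "%s"; gene_name "%s";',
                     mcols(g)$gene_id, mcols(g)$name)
    geneLines <- sprintf("%s\tdemethylscope\tgene\t%d\t%d\t.\t%s\t.\t%s",
                         as.character(seqnames(g)), start(g), end(g),
                         as.character(strand(g)), attr1)
    ex <- unlist(exonRanges(ann))
    ids <- rep(mcols(g)$gene_id, lengths(exonRanges(ann)))
    nms <- rep(mcols(g)$name, lengths(exonRanges(ann)))
    exLines <- sprintf(
        "%s\tdemethylscope\texon\t%d\t%d\t.\t%s\t.\t%s",
        as.character(seqnames(ex)), start(ex), end(ex),
        as.character(strand(ex)),
        sprintf('gene_id "%s"; gene_name "%s";', ids, nms))
    writeLines(c(geneLines, exLines), path)
    invisible(path)
}

#' Write chromosome sizes as a 2-column TSV
#' @param sizes Named vector of chromosome lengths.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeChromSizes <- function(sizes, path) {
    utils::write.table(
        data.frame(chrom = names(sizes), length = as.integer(sizes)),
        path, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
    invisible(path)
}
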