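#' Write a synthetic bundle to disk
#'
#' Emits every file the pipeline readers consume: `annotation.gtf`,
#' `chrom_sizes.tsv`, `meth_<condition>.tsv` (fraction dialect),
#' `peaks_<mark>_<condition>_rep<i>.bed`, `expression.tsv`, `cgi.bed`,
#' `promoters.fasta`, `tsg.tsv`, plus `ground_truth.json` and
#' `config.yaml`.
#'
#' @param bundle A [SyntheticBundle].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fp <- function(...) file.path(dir, ...)
    writeAnnotationGtf(bundle@annotation, fp("annotation.gtf"))
    sizes <- seqlengths(geneRanges(bundle@annotation))
    writeChromSizes(sizes, fp("chrom_sizes.tsv"))
    writeMethylation(bundle@methParental,
                     fp(sprintf("meth_%s.tsv",
                                conditionLabel(bundle@methParental))))
    writeMethylation(bundle@methDerived,
                     fp(sprintf("meth_%s.tsv",
                                conditionLabel(bundle@methDerived))))
    for (nm in names(bundle@peaks))
        writePeaks(bundle@peaks[[nm]], fp(sprintf("peaks_%s.bed", nm)))
    writeExpression(bundle@expression, fp("expression.tsv"))
    writePeaks(bundle@cgi, fp("cgi.bed"))
    Biostrings::writeXStringSet(bundle@promoterSeq, fp("promoters.fasta"))
    writeLines(bundle@tsg, fp("tsg.tsv"))
    jsonlite::write_json(bundle@truth, fp("ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    yaml::write_yaml(bundle@config, fp("config.yaml"))
    invisible(dir)
}

#' Read a bundle directory back into memory
#'
#' Re-reads the files written by [writeBundle()] through the package's
#' format readers (so a round trip also validates the files).
#'
#' @param dir Bundle directory.
#' @return A list with elements `annotation`, `methParental`,
#'   `methDerived`, `peaks`, `expression`, `cgi`, `promoterSeq`, `tsg`,
#'   `truth`, `config`.
#' @export
readBundle <- function(dir) {
    fp <- function(...) file.path(dir, ...)
    if (!dir.exists(dir)) .stopf("no such bundle directory: %s", dir)
    if (!file.exists(fp("config.yaml")))
        .stopf("%s is not a bundle directory (config.yaml missing)", dir)
    cfg <- yaml::read_yaml(fp("config.yaml"))
    ann <- readAnnotation(fp("annotation.gtf"), "gtf",
                          chromSizes = fp("chrom_sizes.tsv"))
    cond <- unlist(cfg$conditions)
    methP <- readMethylation(fp(sprintf("meth_%s.tsv", cond[1])), cond[1])
    methD <- readMethylation(fp(sprintf("meth_%s.tsv", cond[2])), cond[2])
    peakFiles <- list.files(dir, "^peaks_.*\\.bed$")
    peaks <- lapply(peakFiles, function(f) {
        parts <- strsplit(sub("^peaks_(.*)\\.bed$", "\\1", f), "_")[[1]]
        readPeaks(fp(f), mark = parts[1], condition = parts[2],
                  replicate = sub("rep", "", parts[3]))
    })
    names(peaks) <- sub("^peaks_(.*)\\.bed$", "\\1", peakFiles)
    expr <- readExpression(fp("expression.tsv"), conditionA = cond[1])
    cgi <- rtracklayer::import(fp("cgi.bed"), format = "bed")
    strand(cgi) <- "*"
    promSeq <- Biostrings::readDNAStringSet(fp("promoters.fasta"))
    tsg <- readLines(fp("tsg.tsv"))
    truth <- jsonlite::read_json(fp("ground_truth.json"),
                                 simplifyVector = TRUE)
    list(annotation = ann, methParental = methP, methDerived = methD,
         peaks = peaks, expression = expr, cgi = cgi,
         promoterSeq = promSeq, tsg = tsg, truth = truth, config = cfg)
}
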