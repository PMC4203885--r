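Package: DemethylScope
Title: Integrative Comparison of a Parental and a Globally Demethylated
    Epigenome
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Region-level summarization of whole-genome bisulfite
    sequencing methylation calls, replicate-consensus ChIP-seq peak
    handling, promoter-distal enhancer definition and two-condition
    enhancer comparison, expression-based gene classing (de-repressed,
    up- and down-regulated), and the integrative promoter/enhancer
    analyses used to contrast a parental colon cancer methylome
    (HCT116-like) with a DNMT1/DNMT3b double-knockout derivative
    (DKO1-like). Includes a seedable synthetic epigenome generator that
    reproduces the study's statistical structure with ground-truth
    labels for every downstream operation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Epigenetics, DNAMethylation, ChIPSeq, GeneExpression,
    GeneRegulation, Software
RoxygenNote: 7.3.3
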