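Package: nomefoot
Title: Single-Molecule Nucleosome and Footprint Analysis for NOMe-seq Amplicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-molecule chromatin accessibility analysis of
    GpC-methyltransferase footprinting (NOMe-seq) amplicon data. Includes a
    ground-truth simulator of phased nucleosomes, sub-nucleosomal protein
    footprints, enzymatic GpC/CpG labelling and bisulfite conversion;
    context-aware (GCH/HCG/GCG) methylation state calling from bisulfite
    reads; run-length classification of protected spans into nucleosomes and
    footprints; anchored percent-accessibility metaplots with
    nucleosome-depleted-region and nucleosome-center detection; condition
    comparison for salt-wash experiments; and ChIP-based promoter activity
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
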