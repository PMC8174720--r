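Package: indelbarcode
Title: InDel Marker Panels and Black-and-White Genotype Barcodes for
    Cultivar Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Selects PCR-typeable co-dominant insertion/deletion (InDel)
    markers from multi-accession variant calls against a reference
    variety, predicts allele-specific amplicon sizes by in-silico PCR,
    encodes each accession's marker profile as a 1D or 2D black-and-white
    barcode relative to the reference, and quantifies panel quality:
    pattern frequencies, polymorphism information content (simple and
    Botstein forms), profile homology, discrimination power, simple
    matching distances with neighbor-joining trees, and principal
    component coordinates. Includes a synthetic-data generator that
    emulates a crop germplasm resequencing study so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    graphics,
    grDevices,
    jsonlite,
    methods,
    png,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
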