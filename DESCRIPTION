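Package: circosviz
Title: Circos File Generation for Structural Variant Visualization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts structural-variation evidence from paired-end and
    mate-pair sequencing (SV link calls, half-mapped read pairs, binned
    read coverage, copy-number segments and gene annotations) into the
    complete set of data and configuration files consumed by the Circos
    circular-ideogram renderer. Implements a fixed three-ring image
    architecture (annotations, coverage histogram, CNV heatmap) around a
    central link field, zoomable views on a chromosome of interest, a
    "No Match" pseudo-chromosome anchoring half-mapped read-pair clusters,
    and significance gradients that darken link colors with supporting
    read count. Includes adapters for SVDetect, Pindel and Control-FREEC
    output dialects, native SAM/BAM coverage and half-mapped pair
    extraction, and a deterministic synthetic-data simulator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rsamtools,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
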