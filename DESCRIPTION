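Package: tagdge
Title: Digital Gene Expression Tag Profiling: Simulation, Filtering,
    Annotation and Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for NlaIII-anchored digital gene expression (DGE) tag
    profiling of two unreplicated libraries: a synthetic tag-library
    generator with planted fold changes, the raw-to-clean tag filtering
    ladder, virtual-digest tag-to-gene annotation with one-mismatch
    tolerance and multi-gene exclusion, sequencing saturation curves, the
    Audic-Claverie two-library exact test with Benjamini-Hochberg FDR,
    hypergeometric pathway enrichment, and 2^-ddCt qPCR validation, plus
    an end-to-end pipeline and command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
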