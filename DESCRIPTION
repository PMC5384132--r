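Package: pgltools
Title: Genomic Arithmetic for Paired-Genomic-Loci Chromatin Interaction Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A file standard and tool suite for paired-genomic-loci (PGL)
    data from chromatin-interaction assays such as Hi-C and ChIA-PET.  A PGL
    entry records two interacting genomic intervals (anchors) plus free-form
    annotations.  The package provides pair-aware genomic arithmetic
    (intersect, merge, subtract, window, coverage, closest, expand), mixed
    PGL-by-BED operations (intersect1D, closest1D, subtract1D), converters
    from bedpe, triplet-sparse contact matrices and SAM read pairs, exporters
    for the UCSC Genome Browser, Juicebox and bedpe-consuming R packages, a
    sorted-sweep overlap engine that handles non-sequential anchor overlaps,
    and a composable UNIX command-line front end that reads standard input
    and writes standard output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
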