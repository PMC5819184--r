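Package: dioecyTE
Title: Sex-Biased Transposable Element Proliferation from Male and Female
    Genome Skimming Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies transposable-element (TE) subfamily abundance and
    copy number from low-coverage whole-genome shotgun reads of male and
    female individuals of a dioecious plant, and derives sex-comparison
    statistics: male-female genome-size differences, X-chromosome TE
    density from female-minus-male copy numbers, abundance versus
    genome-size correlations across ecotypes, and male/female copy-number
    variability. Includes a synthetic dioecious genome and paired-end read
    generator with machine-readable ground truth, and a transgenerational
    chromosome-transmission simulator that provides the closed-form
    X:autosome insertion-density expectations (4/3 for a strictly
    female-proliferating element) against which the read pipeline is
    validated.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    graphics,
    grDevices,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
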