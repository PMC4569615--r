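Package: paneltriage
Title: Somatic Variant Triage and Mutation Burden Analysis for Matched
    Tumor-Normal Cancer Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Triage and classification of variant calls from targeted
    amplicon cancer panels sequenced as tumor/matched-normal pairs.
    Implements a quality-region-consequence filtering cascade with
    per-stage accounting, somatic versus germline classification by set
    comparison against a pooled matched control, stratification of calls
    against dbSNP-like and COSMIC-like membership tables, a driver-variant
    rule (COSMIC-annotated, or novel and predicted damaging by
    SIFT/PolyPhen2), per-gene mutation burden shares, and Ti/Tv and
    dbSNP-rate quality statistics.  Ships a deterministic synthetic
    tumor/control cohort generator with per-variant truth labels so the
    whole pipeline is testable without access to patient data, and a
    transcribed driver-variant table from a head-and-neck squamous cell
    carcinoma amplicon panel study as a packaged fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    rtracklayer,
    GenomicRanges,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
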