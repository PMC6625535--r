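Package: jjdq
Title: Data Quality Auditing for Juvenile Justice Case-Management Extracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Audits tabular case-level extracts from juvenile justice case
    management systems along three data-quality dimensions: conformance of
    raw tokens to the yes/no/missing vocabulary, completeness (percent
    missing) at each of seven juvenile-court decision points, and
    plausibility via five within-case logical-inconsistency rules with
    first-error chronological accounting. Applies rule-specific resolution
    strategies to flagged cases, producing a corrected extract, an
    exclusion list and an action log, and renders pre/post-cleaning
    quality reports with small-cell suppression. Includes a synthetic
    extract generator with ground-truth error injection for validating
    detectors and cleaning policies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
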