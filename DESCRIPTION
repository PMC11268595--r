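Package: fairmhc
Title: Group-Fairness Auditing and Post-Training Mitigation for Clinical Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to audit the demographic composition of small clinical
    cohorts and to evaluate and mitigate group unfairness in binary
    mental-health classifiers. Implements selection rates, overall and
    privilege-referenced demographic parity ratios, delta-smoothed equalized
    odds ratios, per-group macro-averaged F1, a repeated stratified
    cross-validation harness with majority-vote and probability-weighted late
    fusion, and post-training equalized-odds threshold optimization via
    randomized per-group thresholds on the ROC convex hull. A synthetic
    cohort generator with configurable group structure, base rates and
    class separability supports end-to-end testing without access to
    protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    glmnet,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
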