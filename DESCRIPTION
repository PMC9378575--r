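Package: headachedx
Title: Adaptive Rule-Based Headache Diagnosis and Diagnostic Accuracy Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An adaptive, rule-based diagnostic engine for primary headache
    disorders. ICHD-3 diagnostic criteria are represented as operator trees
    over symptom atoms and evaluated under partial answer sets with
    three-valued (strong Kleene) logic, so that an interview session asks a
    question only while its answer can still change the diagnostic
    impression. Includes a synthetic-cohort simulator with a latent headache
    class mixture and per-symptom response discordance, and a complete
    diagnostic test accuracy toolkit: sensitivity, specificity, predictive
    values with prevalence transport, likelihood ratios with log-method
    confidence intervals, unweighted Cohen's kappa, exact Clopper-Pearson
    intervals, Fagan post-test probabilities, and exact-interval sample-size
    search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
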