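Package: linkadjust
Title: Assessing and Correcting Outcome Misclassification from Imperfect
    Record Linkage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form tools for quantifying and correcting the bias that
    imperfect record linkage introduces into event counts, incidence,
    standardised mortality ratios (SMR) and relative risks (RR). Provides a
    forward misclassification model predicting observed event counts from true
    counts given linkage sensitivity and specificity, the inverse adjustment
    recovering estimated true counts (and adjusted SMR/RR) from observed
    counts, estimation of linkage accuracy from gold-standard validation 2x2
    tables with exact confidence intervals, sensitivity-by-specificity bias
    surfaces, a Monte-Carlo simulation oracle, and a parametric bootstrap
    propagating accuracy uncertainty into adjusted estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
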