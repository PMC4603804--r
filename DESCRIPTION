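Package: survDsize
Title: Discrimination-Based Sample Size Calculations for Prognostic
    Survival Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sample size determination for studies that develop or validate
    multivariable prognostic models of time-to-event data, based on the
    Royston-Sauerbrei D measure of discrimination rather than on events per
    variable.  Implements significance-based (non-inferiority and
    superiority) and precision-based (confidence-interval half-width)
    event-count calculations built on the structural constant lambda =
    events x var(D), estimated either from a prior study or from an
    empirical model in the target D and censoring proportion; a composite
    absolute/relative precision design; estimation of D and its bootstrap
    standard error from survival data via the rankit construction;
    conversion between Harrell's c-index, D and the explained variation
    R^2_D; an exact-event-count exponential survival simulator; and a
    Monte-Carlo harness validating the power, type I error and coverage of
    the calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
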