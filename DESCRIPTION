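Package: adaptRMST
Title: Adaptive Two-Stage Group Sequential Trials with the Restricted
    Mean Survival Time
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Planning, monitoring and analysis of two-stage adaptive group
    sequential clinical trials whose primary endpoint is the difference in
    restricted mean survival time (RMST), targeted at delayed treatment
    effects and other non-proportional-hazards settings. Provides
    Kaplan-Meier and RMST estimation for right-censored and left-truncated
    data, stage-wise inverse normal combination tests with O'Brien-Fleming
    alpha spending, conditional-power-based second-stage sample size
    recalculation with constrained interim nuisance re-estimation,
    simulation-based design planning (asymptotic standard deviations,
    maximum information, combination weights), and a seeded Monte-Carlo
    engine for operating characteristics of full adaptive designs,
    including log-rank and tau-year survival comparator tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    survival,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
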