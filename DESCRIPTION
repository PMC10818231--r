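Package: surveysieve
Title: Multilayer Fraud Detection for Web-Based Survey Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Rule-based detection of fraudulent responses in web-based survey
    exports. Implements a multilayer classifier combining seven real-time
    exclusion rules (address and neighborhood verification against a
    gazetteer, rapid-submission clusters, duplicate emails, nonstandard zip
    codes, address overuse, recruitment-URL validation) with a post hoc
    k-strike ensemble over duplicate free text, VPN/data-center/offshore IP
    origin, and screener-main inconsistency; an adapter reproducing
    platform-side classification from exported reCAPTCHA v3 and RelevantID
    scores; agreement analytics (confusion matrices, Cohen's kappa with
    confidence intervals and qualitative interpretation bands, group
    comparison tests, subgroup mean intervals, and fraud-proportion time
    series); and a seeded synthetic respondent-cohort generator with
    ground-truth labels for end-to-end evaluation of classifier sensitivity
    and specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
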