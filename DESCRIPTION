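Package: brightonaefi
Title: Brighton Anaphylaxis Case Classification and Screening for AEFI Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies coded reports of adverse events following immunization
    (AEFI) against the Brighton Collaboration case definition of anaphylaxis,
    encoded as declarative criteria catalogs evaluated under three-valued
    (Kleene) logic with optional closed-world completion. Ships three guideline
    variants (the original encoding, the original with closed-world negation,
    and an updated negation-free encoding) and assigns each report one of six
    outcome categories: levels 1-3 of diagnostic certainty, reported
    anaphylaxis with insufficient evidence, not a case, or no evidence.
    Also provides a complementary high-sensitivity screening pipeline that
    expands a base Standardized MedDRA Query (SMQ) style term list by
    chi-square feature selection and scores reports by tf-idf cosine
    similarity, plus ROC/sensitivity/specificity evaluation with confidence
    intervals and a synthetic VAERS-like report generator so the whole
    pipeline runs without licensed terminologies or restricted data.
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
    Matrix,
    optparse,
    pROC,
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
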