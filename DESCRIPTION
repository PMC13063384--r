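Package: nhrdea
Title: Delphi Consensus Statistics and Data Envelopment Analysis for
    Nursing Human Resource Efficiency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and applying an efficiency evaluation
    system for nursing human resources in integrated medical-nursing
    elderly care institutions.  Implements Delphi expert-consultation
    statistics (response rates, authority coefficients, coefficients of
    variation, Kendall's coefficient of concordance with tie correction)
    and threshold-based item screening; correlation-based indicator
    selection under DEA dimensionality rules of thumb; input-oriented
    CCR and BCC data envelopment analysis with two-phase slack
    maximization, scale-efficiency decomposition, returns-to-scale
    classification and slack-based projection targets; seeded synthetic
    generators for rating matrices, input-output panels and correlated
    indicator tables; and CSV/JSON readers, report writers and a small
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    vegan
VignetteBuilder: knitr
Config/testthat/edition: 3
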