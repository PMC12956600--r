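Package: cpetr
Title: Breath-by-Breath Cardiopulmonary Exercise Test Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for processing breath-by-breath gas-exchange data from
    ramp-incremental cardiopulmonary exercise tests (CPET): a canonical
    breath CSV format, 30-s moving-average smoothing, quality screening,
    oxygen uptake efficiency slope (OUES) and plateau (OUEP), automated
    ventilatory threshold detection by two-segment piecewise-linear
    regression, ramp-aware VO2-plateau and exhaustion classification, and
    cohort-level comparison with linear models and Cohen's d effect sizes.
    Includes a synthetic ramp-test generator with planted ground truth for
    children, moderately trained, and well-trained adult cohorts, so the
    whole pipeline is testable end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
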