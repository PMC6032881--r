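Package: theatreflow
Title: List-Order Effects on Operation Duration from Theatre Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the composition of a surgeon's operating
    list relates to operation duration. Codes theatre lists with absolute and
    procedure-specific list numbers and switch flags, estimates warm-up and
    task-switching effects on log duration with a linear mixed-effects model
    (REML, random intercepts per procedure-by-age-by-ASA cell), implements a
    randomized exact-matched paired analysis of adjacent procedure-specific
    positions, and ships a synthetic electronic-theatre-record generator so the
    whole pipeline can be exercised and validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
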