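Package: rhythmlink
Title: Multi-Component Cosinor Rhythms and Their Link to Productivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models biobehavioral rhythms in hourly mobile-sensing feature
    streams with multi-component cosinor regression (MESOR, amplitude,
    acrophase, percent rhythm and zero-amplitude significance tests for
    8/12/24-hour components, plus curve-level magnitude, orthophase and
    bathyphase), and relates the fitted rhythm parameters to weekly
    self-reported productivity through min-max normalized Pearson
    correlations combined across features, parameters and weeks with
    Fisher's method. Includes preprocessing for block-missing hourly data
    (linear interpolation, discard rules), productivity labeling, a
    seed-reproducible synthetic-cohort generator with planted
    rhythm-stability effects, and an end-to-end pipeline runner.
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
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
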