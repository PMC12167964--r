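Package: reefcarb
Title: Coral Reef Calcification Decline and the Ocean Carbon Sink
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the negative climate feedback arising from declining
    coral reef net ecosystem calcification. Fits exponential decay curves to
    projected areal calcification under RCP scenarios, converts the relative
    anomalies into global alkalinity and dissolved inorganic carbon sources
    (2:1 molar ratio), and injects them into a reduced-complexity multi-box
    transient ocean carbon cycle with a full seawater carbonate-system solver
    to estimate the enhancement of anthropogenic CO2 uptake from 2005 to 2300.
    Includes synthetic forcing generators (RCP atmospheric CO2 pathways, reef
    location masks, AR(1) alkalinity variability) and time-of-emergence
    diagnostics for detecting the feedback against natural variability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
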