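Package: histbioclim
Title: Historical Bioclimatology of Early Instrumental Weather Registers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rescuing and analysing early instrumental weather
    registers from a human-biometeorology perspective. Standardizes
    twice-daily historical observations (Fahrenheit temperatures, ordinal
    wind-force codes) and contemporary station series into canonical units,
    computes the wind chill temperature (WCT) and insulation predicted
    (Iclp) indices, classifies frostbite risk, clothing demand and
    interdiurnal thermal stimuli, and compares historical against
    contemporary bioclimate through monthly and seasonal statistics,
    anomalies and standard-deviation envelopes. Includes a synthetic
    register generator (seasonal cycle with AR(1) daily anomalies, monthly
    Weibull winds discretized to ordinal force scales) so the full pipeline
    is testable without archival data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
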