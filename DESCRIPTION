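Package: airtrace
Title: Activity-Based Air Pollution Exposure Assessment from Travel Diaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates daily exposure to traffic-related oxides of nitrogen
    (NOx) from 24-hour travel diaries. Person-day activity records are routed
    over a road network by shortest travel time, discretized into space-time
    traces, and matched in space and hour-of-day to a gridded diurnal
    concentration field to give time-weighted activity-based exposure
    concentrations. These are compared with conventional residence-based
    estimates to quantify exposure error and attenuation bias, and analysed
    for disparities between sociodemographic and urbanicity groups with
    Games-Howell post hoc tests and a hierarchical stepwise regression. A
    synthetic-city generator (road network, urbanicity zones, diurnal
    concentration field, and diary population with residential sorting)
    provides fully reproducible inputs.
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
    utils,
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
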