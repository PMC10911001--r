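Package: epeagree
Title: Agreement Among Precipitation Data Sources in Extreme Event Exposure Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how well point weather stations, fine
    interpolated climate grids, and coarse assimilation grids agree in
    identifying extreme precipitation events (EPEs) over polygonal exposure
    units such as census tracts. Implements nearest-station exposure
    assignment with quality-control filtering and completeness screening,
    area-weighted grid-to-polygon aggregation, local percentile and absolute
    EPE thresholds, pooled, annual and stratified Cohen's kappa with
    Landis-Koch interpretation, sociodemographic stratification and
    covariate-matched comparisons, station-proximity regressions, and a
    seeded synthetic study-region generator (spatially correlated wet/dry
    occurrence, gamma wet-day amounts, demographically biased station
    siting, derived interpolated and assimilation products) so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
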