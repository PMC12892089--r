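Package: heatmort
Title: Heat-Related Mortality Attribution from Daily Temperature and Death Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates heat-related deaths (HRD) from regional daily mean
    temperature and all-cause mortality series using a common exposure
    framework: an optimal-temperature (minimum-mortality-temperature)
    climatology, a summer-mean-temperature parameterized relative-risk curve,
    and a minimum-mortality-temperature death rate (MMTD) baseline with
    linear extrapolation. Three complementary attribution estimators are
    provided: the Optimal Temperature Method (OTM, all days warmer than the
    optimal temperature), the Extreme Heat Method (XHM, days at or above the
    95th percentile), and the Excess Death Method (EDM, OTM relative to the
    climate of a historical baseline period). Includes a synthetic-data
    generator with analytically known ground truth for end-to-end validation,
    ingestion and validation of long-format daily series, nearest-grid-point
    assignment of gridded temperatures to regions, and reporting utilities
    for method-versus-official-count comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    geosphere,
    yaml,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
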