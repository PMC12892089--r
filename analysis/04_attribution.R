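#!/usr/bin/env Rscript

# Stage 4: heat-related deaths by the three estimators.
#
# Computes daily attributable deaths (RR(T) - 1) * MMTD(y) on summer days,
# aggregates them into annual OTM (all days above OT) and XHM (days at or
# above the 95th percentile), and derives EDM against the counterfactual
# mid-century baseline climate: the mean annual OTM that climate would have
# produced under the current thresholds, risk curve and a fixed reference
# MMTD, subtracted from each study year.

suppressPackageStartupMessages({
  library(heatmort)
  library(dplyr)
})

temps <- read_daily_series("results/synthetic/temperature_daily.csv", "temperature")
baseline_temps <- read_daily_series("results/synthetic/baseline_temperature_daily.csv",
                                    "temperature")
clim <- readr::read_csv("results/climatology.csv", show_col_types = FALSE)
mmtd <- readr::read_csv("results/mmtd.csv", show_col_types = FALSE)
official <- read_official_counts("results/synthetic/official_counts.csv")
cfg <- run_config()

daily <- daily_hrd(temps, clim, mmtd, cfg)
otm <- aggregate_otm(daily)
xhm <- aggregate_xhm(daily)

reference_mmtd <- mmtd |>
  group_by(region_id) |>
  summarise(mmtd = mean(mmtd), .groups = "drop")
otm_b <- compute_baseline_otm(baseline_temps, clim, reference_mmtd, cfg)
edm <- compute_edm(otm, otm_b)

table <- build_hrd_table(otm, xhm, edm, official)
write_hrd_table(table, "results/hrd_table.csv")
readr::write_csv(otm_b, "results/otm_baseline.csv")

state <- filter(table, scope == "statewide")
cat(sprintf("statewide annual OTM %d-%d, XHM %d-%d deaths\n",
            round(min(state$otm)), round(max(state$otm)),
            round(min(state$xhm)), round(max(state$xhm))))
cat(sprintf("baseline-climate constant OTM_B = %.0f deaths/yr; EDM %d-%d\n",
            otm_b$otm_b[otm_b$scope == "statewide"],
            round(min(state$edm)), round(max(state$edm))))
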