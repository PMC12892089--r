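#!/usr/bin/env Rscript

# Stage 3: baseline mortality at the optimal temperature.
#
# Estimates the minimum-mortality-temperature death rate per region-year by
# averaging deaths on days within 2 degC of the OT over the 2013-2019 fit
# window, fits the per-region linear trend, and extrapolates to the rest of
# 2010-2023 (keeping pandemic-era years out of the direct estimates).

suppressPackageStartupMessages(library(heatmort))

temps <- read_daily_series("results/synthetic/temperature_daily.csv", "temperature")
deaths <- read_daily_series("results/synthetic/deaths_daily.csv", "deaths")
clim <- readr::read_csv("results/climatology.csv", show_col_types = FALSE)
cfg <- run_config()

observed <- estimate_mmtd(deaths, temps, clim, cfg)
model <- fit_mmtd_model(observed, fit_window = cfg$mmtd_fit_years)
pred <- predict_mmtd(model, 2010:2023)

merged <- dplyr::left_join(
  pred, observed[c("region_id", "year", "qualifying_days")],
  by = c("region_id", "year")
)
readr::write_csv(merged, "results/mmtd.csv")

cat(sprintf("MMTD observed for %d region-years (median %.0f qualifying days)\n",
            nrow(observed), median(observed$qualifying_days)))
cat(sprintf("fitted slopes: %.3f to %.3f deaths/day per year\n",
            min(model$fits$slope), max(model$fits$slope)))
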