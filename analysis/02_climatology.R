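#!/usr/bin/env Rscript

# Stage 2: per-region temperature climatology.
#
# Reads the simulated study-period temperatures back through the validated
# ingest path and computes each region's optimal temperature (84th
# percentile of daily means over 2010-2023), summer mean temperature
# (June-September average) and extreme-heat threshold (95th percentile).

suppressPackageStartupMessages(library(heatmort))

temps <- read_daily_series("results/synthetic/temperature_daily.csv", "temperature")
cfg <- run_config()
clim <- build_climatology(temps, cfg)

readr::write_csv(clim, "results/climatology.csv")
cat(sprintf("climatology for %d regions: OT %.1f-%.1f degC, SMT %.1f-%.1f degC\n",
            nrow(clim), min(clim$ot), max(clim$ot), min(clim$smt), max(clim$smt)))
rr95 <- relative_risk(clim$p95, clim$ot, clim$smt, cfg$coefficients)
cat(sprintf("relative risk at the extreme threshold: %.2f-%.2f\n",
            min(rr95), max(rr95)))
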