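#!/usr/bin/env Rscript

# Stage 1: build the synthetic study.
#
# Emulates a Texas-like multi-county study: 10 regions whose mean climates
# span 4 degC, daily mean temperature as seasonal cycle + AR(1) weather noise
# + 0.3 degC/decade warming over 2010-2023, and daily deaths drawn from a
# Poisson whose mean is the true baseline rate times the true relative risk.
# A counterfactual mid-20th-century climate (same weather statistics, 0.8 degC
# cooler, no trend) provides the excess-death baseline, and an official-counts
# emulator reports 30% of the true heat-related deaths.
#
# Writes long-format CSVs under results/synthetic/ that the later stages
# read back through the package's ingest layer.

suppressPackageStartupMessages({
  library(heatmort)
  library(dplyr)
})

dir.create("results/synthetic", recursive = TRUE, showWarnings = FALSE)

cfg <- scenario_config(seed = 42)
baseline_cfg <- scenario_config(
  years = 1950:1963, climate_mean = cfg$climate_mean - 0.8,
  warming_per_decade = 0, seed = 43,
  true_ot = scenario_truth(cfg)$regions$true_ot,
  true_smt = scenario_truth(cfg)$regions$true_smt,
  true_p95 = scenario_truth(cfg)$regions$true_p95
)

temps <- generate_temperature(cfg)
deaths <- generate_mortality(temps, cfg)
baseline_temps <- generate_temperature(baseline_cfg)

truth <- scenario_truth(cfg)
expected <- analytic_expected_hrd(temps, cfg)
state_truth <- expected |>
  group_by(year) |>
  summarise(hrd = sum(expected_otm), .groups = "drop")
official <- generate_official_counts(state_truth, cfg$reporting_fraction)

write_daily_series(temps, "results/synthetic/temperature_daily.csv")
write_daily_series(deaths, "results/synthetic/deaths_daily.csv")
write_daily_series(baseline_temps, "results/synthetic/baseline_temperature_daily.csv")
readr::write_csv(official, "results/synthetic/official_counts.csv")
readr::write_csv(truth$regions, "results/synthetic/truth_regions.csv")
readr::write_csv(truth$mmtd, "results/synthetic/truth_mmtd.csv")
readr::write_csv(expected, "results/synthetic/truth_expected_hrd.csv")

cat(sprintf("simulated %d regions x %d days (study) + %d days (baseline)\n",
            cfg$n_regions, length(unique(temps$date)),
            length(unique(baseline_temps$date))))
cat(sprintf("true OT range: %.1f-%.1f degC; expected statewide OTM %d-%d deaths/yr\n",
            min(truth$regions$true_ot), max(truth$regions$true_ot),
            round(min(state_truth$hrd)), round(max(state_truth$hrd))))
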