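---
title: "Heat-mortality attribution: model, estimators and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heat-mortality attribution: model, estimators and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatmort)
```

## The exposure framework

All three estimators in this package share one exposure model. For a region
$c$ (a county, in the motivating Texas application) with daily mean
temperature $T$:

* **Optimal temperature (OT)** — the temperature at which mortality is
  lowest, operationalized as the 84th percentile of the region's daily mean
  temperature over a reference window (2010–2023 by default). Using a
  modern reference window builds recent acclimatization into the
  thresholds; an older, cooler window would classify more days as
  heat-exposed and raise every estimate.
* **Summer mean temperature (SMT)** — the June–September mean over the same
  window. It indexes how acclimatized a region is: cooler regions respond
  more steeply to a given temperature excess.
* **Relative risk.** Above the OT, mortality risk follows a second-order
  polynomial in the excess $T - OT$ whose coefficients vary linearly with
  SMT:
  $$RR(T) = 1 + A(SMT)\,(T-OT)^2 + B(SMT)\,(T-OT), \qquad
  A = a_s\,SMT + a_i,\quad B = b_s\,SMT + b_i,$$
  with $RR \equiv 1$ at and below the OT (only the heat branch is
  modelled) and the curve floored at 1, since a polynomial dip below 1
  would imply negative attributable deaths, which the attribution identity
  below cannot represent.
* **Baseline mortality (MMTD)** — the minimum-mortality-temperature death
  rate: the average daily all-cause death count on days within ±2 °C of the
  OT, estimated separately per region and year.

Daily heat-related deaths (HRD) on a summer day are then

$$HRD = (RR(T) - 1) \times MMTD(y),$$

and the three estimators are different summations of the same daily series:

* **OTM** (optimal temperature method): sum over all summer days with
  $T > OT$. Strict inequality — a day exactly at the threshold contributes
  nothing anyway, since $RR(OT)=1$.
* **XHM** (extreme heat method): restrict the sum to days with $T \ge$ the
  95th-percentile threshold (inclusive, by convention; the boundary is
  measure-zero for continuous temperatures).
* **EDM** (excess death method): $EDM_y = OTM_y - OTM_B$, where $OTM_B$ is
  the mean annual OTM the *baseline-period climate* would have produced.
  This isolates the contribution of climate change since the baseline
  period; cool years can legitimately go negative and are reported as-is.

Summertime is June–September throughout; widening it changes totals only
marginally because attribution requires $T$ above the (high) OT.

## Parameters and defaults

| parameter | default | units | role |
|---|---|---|---|
| `ot_quantile` | 0.84 | — | OT percentile |
| `extreme_quantile` | 0.95 | — | XHM threshold percentile |
| `climatology_window` | 2010–2023 | years | OT/SMT/threshold reference |
| `summer_months` | 6–9 | months | attribution window |
| `mmtd_fit_years` | 2013–2019 | years | direct MMTD estimation |
| `mmtd_window_halfwidth` | 2 | °C | MMTD temperature window |
| `edm_baseline_window` | 1950–1963 | years | counterfactual climate |
| coefficients | see below | RR/°C, RR/°C² | risk-curve shape |

The MMTD fit window deliberately stops before 2020 so that pandemic-era
mortality does not contaminate the baseline; years outside the window use a
per-region ordinary-least-squares line through the observed values
(capturing population growth and long-term health trends), floored at zero.

**Risk coefficients.** The four constants $(a_s, a_i, b_s, b_i)$ are
external inputs — they come from published multi-city fits and are not
re-estimated here. The package ships a representative default set
($a_s=-0.0010$, $a_i=0.0400$, $b_s=-0.0003$, $b_i=0.0135$) chosen so the
curve is quadratic-dominant (risk accelerates as heat becomes extreme,
with a shallow slope just above OT), cooler regions are steeper (negative
SMT slopes), and RR at the 95th percentile lands in the 1.10–1.25 range
reported for Texas-like summer climates. Substitute published fits with
`risk_coefficients()` or a one-row CSV via `read_risk_coefficients()`. The
composite terms $A$ and $B$ are the ground truth of the parameterization:
the code never re-derives their signs from a rendered formula.

## Decisions where the design was genuinely open

* **Which days enter the percentile distributions.** OT and the extreme
  threshold use *all* calendar days of the window, not summer-only days: an
  84th percentile of all days lands in the upper tail of the summer
  shoulder (≈28–29 °C in the Texas range), which is consistent with
  reported statewide OT values, whereas a summer-only 84th percentile would
  be several degrees hotter. `quantile_days = "summer"` preserves the
  alternative for sensitivity analysis.
* **Which days may qualify for the MMTD window.** All calendar days, to
  maximize sample size in small regions; `mmtd_window_days = "summer"` is
  the restricted alternative.
* **Sparse region-years.** A region-year with fewer than 5 qualifying days
  first widens the window to ±3 °C, then falls back to the pooled
  multi-year mean over the region's qualifying days. Rural counties with
  under one death per day need this stabilization; the `source` column of
  `estimate_mmtd()` records which rule fired.
* **The MMTD inside $OTM_B$ is a fixed reference** — each region's
  study-period mean of predicted MMTD — rather than year-matched values.
  The published Texas table is only consistent with a year-independent
  baseline constant (the OTM and EDM columns differ by 239–240 deaths in
  every one of the 14 years), and a counterfactual that changes *only* the
  climate should hold the demographic baseline fixed. The structural test
  in the suite checks exactly this constancy.
* **Tie-breaks and conventions.** Quantiles use the closest-ranks linear
  interpolation (`stats::quantile` type 7), stated explicitly because the
  84th percentile of a 5,000-day sample moves by a few hundredths of a
  degree across conventions. Nearest-grid-point assignment uses haversine
  distance on a spherical Earth with lexicographic (lat, lon) tie-breaking.
  HRD values stay real-valued until final display rounding.

## The synthetic-data generator

`scenario_config()` defines a study with known truth. Temperature is a
seasonal sinusoid (peak day 213, early August) plus stationary AR(1) noise
plus an optional linear warming trend; the default scenario uses 10 regions
whose annual means span 4 °C around 21 °C, 8.5 °C seasonal amplitude,
2.5 °C noise with lag-1 autocorrelation 0.7, and 0.3 °C/decade warming —
magnitudes a Texas county series would show. Deaths are Poisson with mean
$MMTD_{true}(y) \times RR_{true}(T)$ (negative binomial behind the
`dispersion` switch), with a default true baseline of 12 deaths/day
drifting +0.1/year. An official-counts emulator reports a configurable
fraction (default 0.3) of the true annual heat deaths.

The generator's truth is defined in closed form: true OT and the true
extreme threshold are the 0.84/0.95 quantiles of the *marginal climate
distribution* (an equal-weight mixture of normals over the seasonal cycle,
inverted numerically), and true SMT is the deterministic summer mean. They
are therefore independent of any realized sample percentile, which makes
the estimation error of the empirical OT itself a testable quantity, and
they remain user-overridable scalars.

`analytic_expected_hrd()` turns a generated temperature series into the
exact expectation of each estimator under the truth, the oracle for the
recovery tests: with 10 regions × 14 years × 20 replicate seeds, the
pipeline's statewide per-year OTM and XHM agree with the oracle within 3
Monte-Carlo standard errors, and a self-baseline EDM (baseline window =
study window, no warming) is statistically indistinguishable from zero.
These problem sizes keep the whole validation suite under a minute while
leaving the Monte-Carlo standard errors at a fraction of a percent of the
annual totals.

One estimator property worth knowing: the MMTD window reaches up to
OT + 2 °C, where true risk is slightly above 1, so the MMTD estimator —
and hence OTM — inherits a small upward bias by construction. With a
quadratic-dominant curve the effect is well under 1% and invisible next to
Monte-Carlo noise, but a strongly linear risk curve would make it visible.

**What the generator does not emulate:** spatial correlation between
regions (county weather is strongly correlated in reality; statewide
Monte-Carlo standard errors on real data would be larger than the
synthetic ones), demographic structure and age-specific risk, cause-of-death
composition, reporting lags in official counts, and harvesting/displacement
dynamics. Passing recovery tests therefore demonstrate that the estimators
are implemented correctly and are unbiased under the model's own
assumptions — not that the model is an adequate description of any real
mortality series. One visible consequence of the synthetic weather: with
2.5 °C day-to-day noise the hottest days carry a large share of the
risk-weighted sum, so the synthetic moderate-heat share (≈20%) is far
below the ≈78% of the Texas reference table, whose weather has a much
wider moderate band.

## Degenerate inputs and numerical edges

Constant temperature series produce OT = threshold = SMT with a warning
(the OT < threshold invariant cannot hold); regions with no window data are
excluded with a warning rather than failing the run; region-years with no
qualifying MMTD days even after fallback are flagged missing and excluded
from attribution; extrapolated MMTD below zero is floored with a warning.
Date gaps become explicit missing rows at ingest, and days with missing
temperature carry zero attribution but are visible in the daily table.

## Reporting conventions

Ratios to official counts are ratios of period sums, not means of yearly
ratios — the two differ materially in small-official-count years, and only
the ratio-of-sums convention reproduces the published Texas values (e.g.
5708/520 = 10.98 for 2010–2013). Display rounding is whole deaths for
totals and averages, two decimals for ratios, whole percent for shares;
the underlying columns stay unrounded. In the shipped reference table the
excess-death column sums to 12,474, seven less than its published total
row — accumulated display rounding in the source; the package reports what
the columns sum to.

## Known limitations

Only the heat branch of the exposure-response function is modelled: cold
mortality, lag structures (distributed-lag responses, harvesting) and
within-region heterogeneity are out of scope. The risk curve is taken as
given; uncertainty in its coefficients is not propagated. Official-count
comparisons inherit whatever reporting practices produced those counts.
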