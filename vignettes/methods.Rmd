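---
title: "Methods: attributable burden of PM2.5 and the choices that drive it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attributable burden of PM2.5 and the choices that drive it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pm25bod)
```

## The procedure

`pm25bod` implements the standard exposure-based comparative-risk pipeline
for ambient PM~2.5~. Three inputs meet in one multiplication:

1. **Exposure**: the fraction `EF_i` of the population whose annual-mean
   exposure falls in each 1 µg/m³ concentration interval `i` (arbitrary
   bin widths are accepted; nothing downstream assumes width 1).
2. **Concentration-response curve**: relative risk `RR(C)` of a mortality
   outcome as a function of concentration, parameterized by a risk per
   10 µg/m³ (`RR10`), a shape (linear, log-linear, log-log, or a tabulated
   non-linear grid) and a counterfactual cut-off `C0` below which `RR = 1`.
3. **Population health data**: the cause-by-measure burden table
   (deaths, YLL, YLD, DALY), GBD/WHO/registry style, with 95% CIs where the
   source publishes them.

The population attributable fraction over the binned distribution is
`PAF = (Σ RR_i EF_i − 1) / (Σ RR_i EF_i)` with `RR_i` evaluated at bin
midpoints, and the attributable burden is `PAF × BoD`. When the exposure is
summarized by its population-weighted mean concentration (PWC) the same
formula degenerates to `PAF = (RR_PWC − 1)/RR_PWC`; `collapse_to_pwc()`
routes that shortcut through the identical engine so the two pathways are
directly comparable.

### Assumptions worth knowing

* **Mortality-based PAFs are applied to YLL, YLD and DALY alike.** The
  disease-specific risk curves are mortality curves; applying them to the
  morbidity component assumes incidence tracks mortality for these causes.
  `daly_decomposition()` makes the resulting additivity explicit
  (attributable DALY = attributable YLL + attributable YLD, same PAF).
* **Bin midpoints, no sub-bin integration.** A bin straddling the cut-off
  is either wholly in or wholly out depending on its midpoint — a
  ±half-bin-width approximation. With 1 µg/m³ bins this is at most a
  0.5 µg/m³ mis-attribution at the cut-off edge.
* **One uncertain input at a time.** Endpoint substitution re-runs the
  pipeline with the 2.5%/97.5% endpoint of exactly one input category;
  categories are never varied jointly and no Monte-Carlo integration is
  attempted. This mirrors the comparative design the package exists to
  support: the question is *which* input's uncertainty dominates, not the
  total uncertainty. Summed per-cause intervals are componentwise sums
  (`Σ lo_i`, `Σ hi_i`), not variance-based combinations.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `rr10` (all-cause reference) | 1.08 | RR per 10 µg/m³ | current WHO-era meta-analytic all-cause value; alternatives in the scenario library: 1.17 (low-exposure subset), 1.14, 1.062 (previous recommendation) |
| `cutoff` | 0 | µg/m³ | reference is no cut-off; 2, 4, 5, 6 span the values used by GBD, EEA and US-EPA; tabulated curves default to their intrinsic 2.4 |
| curve shape | linear | — | the conventional single-risk recommendation; log-log captures the supra-linear rise-then-flatten seen in fitted non-linear curves |
| `endpoint` | central | — | `lo`/`hi` select the 95% CI endpoint of whichever input is being substituted |

On the previous-recommendation risk: the rounded value 1.06 is what gets
quoted, but the percent changes it must reproduce (−22% at PWC 5, −19% at
PWC 30 against the 1.08 reference) only reconcile with the underlying
meta-analytic value **1.062**; the package's tests use 1.062 and flag it as
such. Relatedly, a published claim that the log-log shape gives a "21%
increase" at mean exposure 15 µg/m³ cannot be reproduced from the log-log
formula itself (above `C0 + 10` the log-log curve lies *below* the linear
one, so the closed-form change at PWC 15 is a decrease); the package
reproduces the algebra, not that number.

## The synthetic-data generator

Real inputs for this kind of assessment — dispersion-model or satellite
exposure surfaces, national cause-of-death registries — are not
redistributable, so every stage is exercised on synthetic data with the
statistical structure the analysis assumes.

* **Exposure** (`generate_exposure()`): a gamma population of exposures
  (right-skewed, unimodal, mode below the mean), rescaled to hit the
  target mean exactly before binning at 1 µg/m³. The dispersion parameter
  is the coefficient of variation, default 0.5 — a visibly skewed
  distribution of the kind national exposure models produce for a country
  with a few denser urban areas; it is a modelling choice, exposed rather
  than hard-coded. CI variants scale all concentrations by 0.8/1.2,
  chosen to mirror a 4.0–6.0 µg/m³ interval around a mean of 5.0.
* **Health** (`generate_health_table()`): all-cause, NCD+LRI and six
  specific causes (IHD, stroke, COPD, ALRI, lung cancer, type-2 diabetes)
  × deaths/YLL/YLD/DALY, with DALY = YLL + YLD by construction. The
  default all-cause scale of 37,650 deaths makes reference runs land at
  the same magnitude as a small high-income country (and is the count
  under which the worked examples reproduce the published reference
  estimate); it is a convenience, not registry data. Defaults
  `yll_per_death = 12` and `yld_to_yll = 0.35` put the YLL share of DALYs
  near 74%, the mortality-dominated split typical of these causes. The
  six cause fractions (12% IHD, 7% stroke, 6% COPD, 5.5% lung cancer, 5%
  ALRI, 1.5% diabetes) sum well below 1, so the disease-specific sum is
  forced below the all-cause count. A registry variant carries no CIs,
  because national mortality registries publish none — the uncertainty
  engine must then return an explicit "no interval available", never a
  silent zero.
* **Curves** (`generate_tabulated_curve()`): monotone power-law segments
  through user anchors with RR = 1 at the cut-off (default 2.4 µg/m³).
  The `gemm-like` exponent (0.35) bends up steeply at low concentrations;
  `mrbrt-like` (0.75) is closer to linear there — the qualitative contrast
  between the two published curve families.

**What a green test does and does not establish.** The generator
reproduces shapes and scales, not the real surfaces: passing tests show
the *engine* is correct (formulas, orderings, invariances, determinism)
and that distribution-independent percent changes match published values
exactly. They do not certify the handful of published absolute counts that
depend on unpublished exposure distributions and supplementary curve
tables (the full-distribution cut-off reductions of 70/80/91% at PWC 5,
the +39% between the two exposure models, the GEMM/MR-BRT DALY totals);
for those the test suite demonstrates the same qualitative orderings on
synthetic inputs and stops there.

## Numerical conventions

* Bin fractions are renormalized to sum to 1 on load (tolerance 1e-9;
  deviations beyond 1e-6 warn). Bin edges are snapped to exact contiguity
  so shift-and-compare operations are float-drift-free.
* Tabulated curves: piecewise-linear interpolation, clamped to the last
  grid value beyond the grid; a cut-off override re-clamps RR to 1 below
  the override and leaves the curve unchanged above it.
* Attributable counts are kept unrounded internally; reporting layers
  round counts half-up to whole deaths and percent changes to one decimal
  (ledger) to match how such results are conventionally printed.
* Degenerate cases: a zero reference makes percent change undefined
  (reported missing, not 0); a cut-off at or above every concentration
  gives PAF exactly 0; YLL share is missing when YLL + YLD = 0.
* Protective risks: `RR10 < 1` is rejected at spec validation (no
  supported mortality curve is protective), though the algebra below the
  validation layer would accept it.

## Design choices where the design was open

* **Representative concentration = bin midpoint.** The PAF formula needs
  "the exposure level in the interval"; the midpoint is the symmetric
  choice and makes a [4.5, 5.5) bin represent 5.0.
* **CI variants of the exposure are whole distributions** (`lo95`/`hi95`),
  not per-bin intervals — matching how exposure-model uncertainty is
  actually published (a shifted/scaled curve, not independent bin errors).
* **Configuration is JSON.** The run-configuration contract allows a YAML
  dialect as well, but no YAML parser is available in the supported
  dependency set, so JSON is the single accepted format.
* **The reference DALY configuration is not asserted.** Published DALY
  totals could have come from either of two plausible configurations
  (linear/no-cut-off or log-log/2.4); the scenario library can express
  both, and no test claims either is "the" source configuration.
* Scenario ids are caller-supplied strings and output order follows the
  configuration order, so ledgers are reproducible and diffable;
  re-running a grid is bit-identical (no hidden randomness anywhere in the
  evaluation path — seeds exist only in the generator).

## Known limitations

* No spatial modelling: exposure arrives pre-aggregated into bins; no
  raster/population-weighting machinery.
* No life tables: YLL/YLD arrive precomputed; the package never derives
  years of life lost from age-specific mortality.
* No refitting of non-linear curve families; tabulated curves are consumed
  as given, with interpolation the only inference.
* All-cause, NCD+LRI and disease-specific labels are distinct; the package
  never reconciles one from another.
* The endpoint-substitution design quantifies one input category at a
  time; it is not a full uncertainty analysis and the summed per-cause
  intervals are conservative by construction.
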