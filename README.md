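# pm25bod

Burden of disease attributable to ambient fine particulate matter
(PM<sub>2.5</sub>), with explicit accounting for the methodological choices
that drive such estimates.

## Who this is for

Health-risk assessors and environmental epidemiologists who compute deaths,
years of life lost (YLL), years lived with disability (YLD) or
disability-adjusted life years (DALY) attributable to annual-mean
PM<sub>2.5</sub> exposure — and who need to know how much their answer
depends on the concentration-response curve, the counterfactual cut-off,
the exposure model and the mortality data source they picked. The package
is especially aimed at **low-exposure settings** (population means below
~10 µg/m³), where these choices can swing the estimate by a factor of two
or more.

## The model

The attributable burden for a cause is

```
AB = PAF × BoD
```

where `BoD` is the population burden (deaths, YLL, YLD or DALY) and the
population attributable fraction is computed over the exposure distribution
binned into concentration intervals *i*:

```
PAF = (Σᵢ RRᵢ·EFᵢ − 1) / (Σᵢ RRᵢ·EFᵢ)
```

with `EFᵢ` the fraction of the population exposed in interval *i* and
`RRᵢ` the relative risk at the interval's midpoint concentration. When the
exposure is summarized by its population-weighted mean concentration (PWC),
this collapses to `PAF = (RR_PWC − 1)/RR_PWC`.

Relative risk as a function of concentration `C` above a cut-off `C₀`
(RR = 1 at or below it), given a risk `RR₁₀` per 10 µg/m³:

| shape | formula |
|---|---|
| linear | `RR = 1 + (RR₁₀ − 1)/10 · (C − C₀)` |
| log-linear | `RR = exp(β(C − C₀))`, `β = ln RR₁₀ / 10` |
| log-log | `RR = [(C+1)/(C₀+1)]^β`, `β = ln RR₁₀ / [ln(10+C₀+1) − ln(C₀+1)]` |
| tabulated | piecewise-linear interpolation of a fitted RR grid (GEMM / MR-BRT style), clamped beyond the grid |

All three closed-form shapes satisfy `RR(C₀) = 1` and `RR(C₀+10) = RR₁₀`.
Uncertainty is propagated by **endpoint substitution**: the pipeline is
re-run with the 2.5% / 97.5% endpoint of exactly one input category
(relative risk, exposure distribution, or health data) in place of its
central value. A scenario engine runs grids of such configurations and
reports each scenario's percent change against a declared reference.

## Worked example

A reference configuration — linear curve, RR 1.08 per 10 µg/m³, no
cut-off, a synthetic right-skewed exposure distribution with PWC 5.0 µg/m³
and an all-cause death count of 37,650 — plus four methodological variants:

```r
library(pm25bod)

expo   <- generate_exposure(target_pwc = 5.0, seed = 1)   # central + lo95/hi95
health <- generate_health_table(seed = 1)                 # GBD-style table
ref    <- curve_spec("linear", rr10 = relative_risk10(1.08, 1.06, 1.09))

paf_distribution(expo$central, ref)
#> [1] 0.0384688

sc <- function(id, ...) bod_scenario(id, expo, ..., health = health)
ledger <- run_scenario_grid(list(
  sc("reference",    curve = ref),
  sc("rr-1.17",      curve = curve_spec("linear", rr10 = relative_risk10(1.17, 1.13, 1.21))),
  sc("cutoff-2",     curve = curve_spec("linear", rr10 = relative_risk10(1.08, 1.06, 1.09), cutoff = 2)),
  sc("loglog",       curve = curve_spec("loglog", rr10 = relative_risk10(1.08, 1.06, 1.09))),
  sc("pwc-cutoff-6", curve = curve_spec("linear", rr10 = relative_risk10(1.08, 1.06, 1.09), cutoff = 6),
                     use_pwc = TRUE)
), "reference")
```

which prints (counts rounded, percent to one decimal):

```
   scenario_id measure attributable   lo   hi uncertainty_source pct_change_vs_reference
1    reference  deaths         1448 1097 1622                 rr                     0.0
2      rr-1.17  deaths         2950 2298 3578                 rr                   103.7
3     cutoff-2  deaths          897  677 1006                 rr                   -38.1
4       loglog  deaths         2009 1530 2242                 rr                    38.7
5 pwc-cutoff-6  deaths            0    0    0                 rr                  -100.0
```

Reading it: substituting the low-exposure meta-analytic risk (1.17)
roughly doubles the estimate (+104%); a 2 µg/m³ cut-off removes ~38% of
the burden at this low exposure level; the supra-linear log-log shape adds
~39%; and collapsing the exposure to its mean while using a cut-off above
that mean wipes the estimate out entirely (−100%) even though part of the
population is exposed above the cut-off — the central trap of the PWC
shortcut. The `lo`/`hi` columns are the endpoint-substituted interval for
the relative risk's 95% CI.

The command-line interface mirrors this: see `inst/cli/pm25bod.R`
(`compute`, `scenarios`, `simulate`, `validate` subcommands with
`--config`, `--out`, `--seed`, `--verbose`; exit codes 0/2/3).

## Documentation

`vignettes/methods.Rmd` describes the model, its assumptions, the
synthetic-data generator, numerical conventions and known limitations.
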