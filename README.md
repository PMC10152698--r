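# indiri — indirect reference intervals, benchmarked

`indiri` establishes clinical **reference intervals** (RIs) — the central 95%
range of an analyte in a healthy population, bounded by a lower limit (LL) and
an upper limit (UL) — from *mixed* routine laboratory data, and scores the
result objectively against a gold standard.

It is aimed at laboratory-medicine statisticians who want to use **indirect**
estimation (data mining of real-world results, where some unknown minority of
values come from diseased patients) instead of the costly **direct** approach
(recruiting vetted healthy reference individuals), and who need to know *which*
algorithm to trust for *which* distribution shape.

## What's inside

**Five indirect estimators**, each consuming a numeric vector and returning an
RI with a fitted model:

| function | idea |
|---|---|
| `hoffmann_ri()` | probit plot (ordered values vs normal quantiles); the straight mainstream segment is extrapolated to z = ±1.96 |
| `bhattacharya_ri()` | log histogram-count differences ∆ln Y(x) vs bin centre; a Gaussian component is a straight line with slope −h/σ² |
| `em_ri()` | Gaussian-mixture EM on the Box-Cox scale; the largest-weight component is the healthy population |
| `kosmic_ri()` | power-normal (Box-Cox + Gaussian) fit minimizing the Kolmogorov–Smirnov distance to a truncated empirical CDF |
| `refiner_like_ri()` | simplified inverse modeling: fit (λ, µ, σ, healthy fraction) to the histogram main peak by χ² search |

**A two-step preprocessing pipeline** (`preprocess_table()`): stratified
sex/age balancing by random downsampling, then per-subgroup Box-Cox
transformation and Tukey-fence outlier removal.

**Partitioning analysis** (`partition_analysis()`): standardized regression
plus a variance-component decomposition; a factor triggers sex- or
age-specific RIs when its standard deviation ratio SDR = SD_factor/SD_residual
exceeds 0.4.

**A direct gold standard** (`transformed_parametric_ri()`): Box-Cox (or log)
transform, m ± 1.96 s, back-transform; percentile-bootstrap 90% CIs via
`bootstrap_ci()`.

**Objective scoring** (`bias_ratio()`, `br_matrix()`): the bias ratio

```
BR_LL = |LL − LL₀| / SD_RI,   BR_UL = |UL − UL₀| / SD_RI,   SD_RI = (UL₀ − LL₀)/3.92
```

flags a limit as clinically discrepant when BR > 0.375.

**A synthetic cohort generator** (`thyroid_panel_spec()`, `generate_cohort()`,
`true_ri()`): five thyroid-hormone-like analytes (right-skewed TSH-like,
near-Gaussian FT3/TT3/TT4-like, moderately skewed FT4-like) with 10%
pathological contamination, sex/age effects, and closed-form ground-truth
limits — so every estimator is testable by parameter recovery without any
clinical data.

## Worked example

```r
library(indiri)

spec <- thyroid_panel_spec(20000)$TSH      # right-skewed, 10% contaminated
tab  <- generate_cohort(spec, seed = 42)
true_ri(spec)
#> [1] 0.7789277 4.1281818

kosmic_ri(tab$value)$ri
#> Reference interval [kosmic]: LL = 0.7779, UL = 4.188

em_ri(tab$value, k = 3, seed = 7)$ri
#> Reference interval [em]: LL = 0.7721, UL = 4.018

# score an estimate against a gold standard
bias_ratio(test = c(0.970, 4.276), standard = c(0.801, 4.221))
#> BR_LL = 0.194  BR_UL = 0.063  (SD_RI = 0.87245, threshold 0.375)
```

Both estimators recover the generator's true limits to within a few
percent, the EM upper limit running slightly narrow (its typical behaviour
once the pathological tails overlap the healthy core). In the `bias_ratio()`
call, both BR values sit below 0.375, so neither limit would be flagged as
clinically discrepant.

End-to-end run on a pair of cohorts (standard RI from a vetted reference
table, five indirect RIs from a routine table, BR matrix comparing them):

```r
cfg <- run_config(seed = 1, bootstrap_B = 100)
out <- run_pipeline(cfg, reference_table, test_table, out_dir = "reports")
out$br          # bias-ratio matrix with threshold flags
```

A command-line launcher with subcommands `simulate | preprocess | partition |
direct | estimate | compare | run` is installed at `inst/cli/indiri`.

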