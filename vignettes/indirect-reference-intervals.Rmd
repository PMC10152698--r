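---
title: "Indirect reference intervals: models, choices, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect reference intervals: models, choices, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A reference interval (RI) is the central 95% range of an analyte in a healthy
population, bounded by the 2.5th (LL) and 97.5th (UL) percentiles. The direct
approach estimates it from individuals vetted healthy by strict inclusion and
exclusion criteria; the indirect approach estimates it from routine ("real
world") laboratory data in which an unknown minority of results comes from
diseased patients. Indirect estimation rests on one assumption: the majority
of routine results are non-pathological, so a sufficiently structured model
can separate the healthy distribution from the mixture.

`indiri` implements five mainstream indirect algorithms behind a common
interface, the simplified two-step preprocessing that usually precedes them,
a direct (transformed parametric) gold standard, and an objective scoring
rule — the bias-ratio (BR) matrix — for comparing the two. A synthetic
cohort generator with closed-form ground truth makes the whole chain testable.

## The statistical model

All estimators share one distributional idea: the healthy component is
**power normal** — Gaussian after a Box-Cox transformation

$$y = \begin{cases}(x^\lambda - 1)/\lambda & \lambda \neq 0\\ \ln x & \lambda = 0\end{cases}$$

so an RI is always some version of $BC^{-1}_\lambda(\mu \pm 1.96\sigma)$.
The transform is strictly monotone, so limits computed on the transformed
scale and mapped back are quantiles on the measurement scale. The exponent is
estimated by profile maximum likelihood over $\lambda \in [-2, 2]$ (the
classic definition; the Jacobian term $(\lambda - 1)\sum\log x_i$ makes
exponents comparable). For the *indirect* estimators the exponent is
estimated on the central 90% of the sample: one-sided pathological
contamination otherwise drags it visibly (on the TSH-like panel the
full-sample estimate is ≈ 0.24 where the healthy core has λ = 0).

### The five estimators and their failure modes

* **Hoffmann** regresses sorted values on normal quantiles
  $z_i = \Phi^{-1}((i-0.5)/n)$ and inverts the straight mainstream segment at
  $z = \pm 1.96$. With a healthy fraction $f < 1$ the central slope of the
  probit plot is flattened by roughly $f$, so the method *intrinsically*
  widens the interval by ≈ $1/f$ on the transformed scale; cleaning the tails
  first (see preprocessing) removes most of this bias. On raw right-skewed
  data its extrapolated LL undershoots and can go negative — the classic
  argument for transforming first.
* **Bhattacharya** plots $\Delta\ln Y(x)$, the log-ratio of adjacent
  histogram counts, against the bin centre; a Gaussian component is a line
  with slope $-h/\sigma^2$ and the parameters follow from slope and
  intercept ($\sigma^2 = -h/b - h^2/12$ with the grouping correction,
  $\mu = -a/b + h/2$). Sparse bins make the log-ratio pure noise, so points
  need a minimum count (default 5) on both sides.
* **EM** fits a $k$-component Gaussian mixture on the transformed scale and
  reads the largest-weight component as healthy. It is the only method that
  models the contamination explicitly — and it is therefore fed the *raw*
  mixture. Removing the pathological lobes first leaves EM to carve a clean
  Gaussian into overlapping pieces, and the largest piece is systematically
  narrow; this reproduces a well-known behaviour of EM-derived RIs on
  near-Gaussian analytes.
* **kosmic-style search** minimizes the Kolmogorov–Smirnov distance between
  a truncated power-normal CDF and the empirical CDF restricted to a
  truncation window; λ is searched on a coarse grid with (µ, σ) optimized
  per candidate. A handful of candidate windows (central [0.05, 0.95] plus
  asymmetric retreats from either tail) are compared on the size-normalized
  distance $D\sqrt{n_w}$, and the widest window fitting within a factor of
  two of the best is kept — heavy one-sided contamination can reach inside
  a fixed symmetric window, while on clean data narrow windows always
  overfit slightly.
* **refineR-style inverse modeling** (an intentionally simplified
  reconstruction, not a port) locates the main histogram peak (shortest bin
  span holding 60% of mass, widened by a 75% margin per side), then fits
  (λ, µ, σ) and a healthy-fraction scale factor by χ² between model-implied
  and observed bin counts. The margin matters: fitted only to the narrow
  peak, the exponent is unidentified and extrapolation to ±1.96σ drifts by
  several percent; the shoulders pin it down while staying clear of
  far-shifted pathological lobes.

### Automated region selection

The two graphical methods traditionally rely on a *visually* chosen straight
segment. `select_linear_region()` replaces this with a deterministic
criterion: over all contiguous windows of at least `min_span` points,
maximize $r^2 - c(1 - \text{span fraction})$. The penalty weight is
**c = 0.005**: on a 200-point probit grid the $r^2$ of candidate windows
varies only by a few thousandths, so a larger penalty (say 0.05) swamps the
signal and always selects near-full windows, dragging the fit into the bent
contaminated tails. Windows must have the physically admissible slope sign
(rising probit, falling log-ratio), and the Bhattacharya search is anchored
at the modal bin so a long pathological lobe sharing the plot cannot capture
the fit. A `region = c(start, end)` override preserves the classic manual
mode.

## Preprocessing: who gets cleaned data

The two-step pipeline (1) balances the sex × age-band composition by random
downsampling to the largest feasible equal-cell design, and (2) removes
outliers per subgroup by Tukey fences ($Q_1 - 1.5\,\mathrm{IQR}$,
$Q_3 + 1.5\,\mathrm{IQR}$, type-7 quartiles) on the Box-Cox-transformed
subgroup values. Per-subgroup filtering avoids discarding values that are
extreme only relative to the wrong stratum. On the synthetic panel the fences
remove most of the far pathological mass, which is why the graphical methods
(whose premise is a dominant near-Gaussian bulk) are benchmarked on cleaned
vectors, while EM / kosmic / refineR-style estimators are benchmarked on the
raw mixture they are designed to decompose. The full pipeline
(`run_pipeline()`) applies the same preprocessing to both cohorts and makes
partition decisions on the reference cohort only.

## Partitioning

Whether RIs need sex- or age-specific versions is decided by the standard
deviation ratio SDR = SD_factor / SD_residual with a strict 0.4 cut-off.
SD_residual is the pooled within-cell SD on the sex × age-band grid;
SD_factor is the population SD (divide by the number of groups) of the
unweighted group means, debiased for cell-mean sampling noise and truncated
at zero. The population-SD convention makes a sex shift equal to one residual
SD correspond to SDR = 0.5 — the calibration used by the recovery tests.
Age enters the regression as a continuous covariate but the variance
decomposition through four decade bands (18–29, 30–39, 40–49, 50–59),
mirroring how both framings are used in practice. A REML variant was
deliberately not added: method-of-moments is exact on the balanced designs
the balancing step produces, and keeping the decomposition closed-form keeps
it deterministic.

## Bias-ratio scoring

$$BR_{LL} = \frac{|LL - LL_0|}{SD_{RI}},\qquad BR_{UL} = \frac{|UL - UL_0|}{SD_{RI}},\qquad SD_{RI} = \frac{UL_0 - LL_0}{3.92}$$

with flags at BR > 0.375 (strict). BR is scale-invariant and symmetric in
the deviation's sign; it is computed from unrounded limits by default, with
a `digits` option to reproduce report-scale arithmetic.

## The synthetic world

`thyroid_panel_spec(n)` fixes one stated world: five analytes whose healthy
cores are power normal — TSH-like log-normal (λ = 0, µ = 0.609, σ = 0.424 on
the log scale, i.e. RI ≈ 0.78–4.13 µIU/L), near-Gaussian FT3/TT3/TT4-like,
moderately skewed FT4-like (λ = 0.5) — plus 5% pathological contamination
shifted low and 5% shifted high (10% total; routine physical-examination
data are assumed to carry only small pathological fractions, and the exact
fraction is exposed as `patho_frac`). FT3 and FT4 carry male–female shifts
calibrated to SDR ≈ 0.73 and 0.50 so that exactly these two analytes trigger
sex partitioning at the 0.4 cut-off; TSH carries a small negative male shift
and a mild positive age slope. Ages are drawn uniformly over 18–59 (the
balanced limit of decade-band matching); sexes are 1:1 in expectation. The
`truth_label` column records the generating component but is never visible
to estimators.

Ground truth: on the transformed scale the healthy population marginalized
over sex and age is a finite Gaussian mixture; `true_ri()` inverts its exact
CDF at $\Phi(\mp 1.96)$ and back-transforms. With no covariate effects this
reduces to $BC^{-1}(\mu \pm 1.96\sigma)$.

What the generator does *not* emulate: assay imprecision and drift, repeat
visits, BMI/blood-pressure covariates, antibody positivity, age-dependent
pathological fractions, or multimodal pathology beyond one low and one high
lobe. A green recovery test therefore establishes that an estimator can
separate a dominant power-normal core from moderate two-sided contamination
at realistic sample sizes — not that it is robust to every clinical mixture.

## Numerical choices

* Quartiles/quantiles: linear interpolation of order statistics (type 7)
  throughout; stated once here, used everywhere.
* Bootstrap: percentile CIs over B = 100 resamples at 90% coverage, with the
  observed estimate included in the percentile construction, so a CI always
  brackets its point estimate. Region/parameter selection is re-run on every
  resample. More than 20% estimator failures across resamples aborts with an
  instability error.
* EM: convergence when the relative log-likelihood change drops below 1e-7
  (an absolute rule makes near-degenerate fits on clean data spin until the
  iteration cap; a looser 1e-6 visibly distorts two-component fits on clean
  Gaussian samples), cap 2000 iterations, 3 initializations — one deterministic tail-anchored
  quantile spread (components seeded at the 1st/…/99th percentiles, where
  pathological lobes live) plus seeded random restarts; best converged
  likelihood wins; σ < 1e-8 marks a collapsed restart.
* Degenerate inputs: constant samples are a degenerate-variance error for
  parametric fits; zero IQR makes Tukey fences collapse to the common value
  (nothing removed); a zero residual SD makes the SDR undefined and errors.
* Ties in region selection resolve to the earliest window; all stochastic
  steps take explicit seeds, and equal seeds give byte-identical outputs end
  to end.
* The λ = 1 branch of the inverse Box-Cox is linear ($x = y + 1$) and is
  therefore defined for all reals, unlike other exponents whose domain is
  $\lambda y + 1 > 0$; the generator rejects-and-redraws out-of-domain draws
  and aborts if more than 10% of draws are rejected.

## Known limitations

* Hoffmann/Bhattacharya retain a residual widening bias proportional to the
  contamination that survives cleaning; on raw heavily contaminated data
  they should not be trusted, which is precisely the benchmark's point.
* The EM healthy component is identified by largest weight; with a
  pathological fraction approaching the healthy one this rule breaks down.
* The refineR-style estimator is a simplified reconstruction; fidelity to
  the published tool's estimates is out of scope.
* The kosmic-style truncation window is symmetric in quantiles; strongly
  asymmetric contamination may justify an asymmetric window (exposed as
  `truncation`).
* Bootstrap CIs are percentile, not BCa; with B = 100 their own Monte-Carlo
  error is a few percent of the interval width.
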