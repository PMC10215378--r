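---
title: "Linear-logistic analysis of amino-acid titration studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear-logistic analysis of amino-acid titration studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linlogr)
```

## The model

Classical amino-acid (AA) requirement analysis fits a broken-line or
saturating curve to a growth-type response and declares the breakpoint the
requirement. Across many titration data sets, however, the response is not
monotone: growth rises with AA intake, dips over an intermediate range, and
rises again. `linlogr` models this rise–dip–rise shape as a rising line
minus a logistic drop,

$$y = a + bx - \frac{c}{1 + d\,e^{-fx}},$$

with intercept $a$ (response units), linear slope $b > 0$ (response per
dose), drop amplitude $c \ge 0$ (response units), dimensionless offset
$d > 0$, and rate $f > 0$ (per dose unit). Setting the derivative

$$y' = b - \frac{c\,d\,f\,e^{-fx}}{(1 + d\,e^{-fx})^2}$$

to zero and substituting $u = e^{-fx}$ gives the quadratic
$b(1+du)^2 = cdfu$ with discriminant $\Delta = cf(cf - 4b)$. When
$cf > 4b$ there are two stationary doses,

$$u_\pm = \frac{cf - 2b \pm \sqrt{cf(cf-4b)}}{2bd}, \qquad
R_{max} = -\tfrac{1}{f}\ln u_+, \quad R_{min} = -\tfrac{1}{f}\ln u_-,$$

the dose maximizing the response ($R_{max}$) and the larger dose at the
local minimum ($R_{min}$). Because $u_+u_- = 1/d^2$, the two doses always
satisfy $R_{max} + R_{min} = 2\ln(d)/f$ — an identity the test suite uses
as an exact invariant. When $cf = 4b$ both collapse to a saddle at
$\ln(d)/f$; when $cf < 4b$ (or $c = 0$) the curve is strictly increasing
and neither dose exists. `stationary_points()` reports these three regimes
explicitly rather than returning complex or missing roots silently.

The scientific reading, which motivates everything downstream: growth-type
responses peak at $R_{max}$, while companion physiological responses —
milk yield, litter size, immunoglobulins, survival, plasma AA — tend to
keep improving up to $R_{min}$ and plateau there. The package
operationalises that claim as a measurable comparison (below) rather than
a visual one.

```{r curve, fig.width = 6, fig.height = 4}
p <- linlog_params(a = 0, b = 1, c = 10, d = 100, f = 1)
x <- seq(0, 10, length.out = 300)
plot(x, linlog_eval(p, x), type = "l", lwd = 2,
     xlab = "dose", ylab = "response")
abline(v = unlist(stationary_points(p)[c("rmax", "rmin")]), lty = 2)
```

## Numerical choices

**Overflow-safe evaluation.** On ratio-type dose axes (e.g. 77–127% of
lysine) the product $fx$ easily exceeds the range where $e^{-fx}$ is
representable. All evaluation therefore goes through
`plogis(f*x - log(d))`, which saturates gracefully in both tails, and the
offset is carried as $\log d$ throughout (`linlog_params(..., log_d =)`),
so fits whose back-transformed $d$ exceeds double overflow remain fully
usable; `d` itself is only materialised for display.

**Discriminant tolerance.** $|cf - 4b| \le 10^{-10}\max(cf, 4b)$ is
treated as the degenerate saddle. This avoids manufacturing two spurious
near-identical roots from floating-point noise exactly at the boundary.

**Fitting.** `fit_linlog()` is multi-start Levenberg–Marquardt
(`minpack.lm::nls.lm`) on $(a, \log b, \log c, \log d, \log f)$: the log
parameterisation enforces the sign convention without penalties. Doses are
standardised to $[0,1]$ before optimisation and coefficients
back-transformed, making the fit invariant to the dose unit (tested to
$10^{-6}$ relative). The start grid is deterministic: $b$ and $a$ from an
OLS line through the upper third of doses (the post-dip rise), $c$ from
1–3× the maximum dip of the data below that line, the logistic midpoint
$\ln(d)/f$ at the 0.25/0.4/0.5/0.6/0.75 dose quantiles, and $f \in
\{2, 5, 10\}$ per unit range, plus one near-linear fallback — 46 starts.
Replicates are fitted as individual rows by default (`collapse_reps =
TRUE` fits level means instead; published tables often report only means,
and both conventions are defensible, so both are provided).

**Segmented regression.** The companion model is the continuous
linear-plateau: for a fixed breakpoint it is linear, so the breakpoint is
profiled over 512 grid points plus all midpoints between adjacent observed
doses, then polished by `optimize()` in the winning bracket. The test
suite checks the polished fit beats a 1000-point grid search. Orientation
(`rise-then-plateau` vs `plateau-then-rise`) is auto-detected by RSS
unless forced.

**Model selection.** Published analyses chose "the model with the best
goodness of fit" without naming the criterion or candidate set. Here the
criterion is AICc (small-sample corrected — titration studies have few
points) over a declared five-model set: linear-logistic, linear-plateau,
quadratic-plateau, simple logistic, quadratic. Ties below $10^{-6}$ go to
the model with fewer parameters, then alphabetically, so selection is
deterministic.

## Uncertainty and the Rmin-vs-breakpoint comparison

`bootstrap_ci()` is a case-resampling bootstrap stratified by dose level:
rows are resampled with replacement within each level, preserving the
design's replication — appropriate for titration designs with few levels
and possibly heteroscedastic responses. Intervals are percentile (BCa is
future work). Replicate refits warm-start from the point estimate, which
keeps the default `B = 1000` tractable without changing the estimator;
replicates whose refit is monotone carry no $R_{min}$ and are counted in
`failed_replicates`, with the result flagged unreliable past 50% failures.
One root seed drives per-replicate streams drawn up front, so results are
reproducible regardless of evaluation order.

`compare_rmin_to_breakpoint()` fits the linear-logistic model to the
primary response, the segmented model to the companion, and reports which
stationary dose the companion's breakpoint is nearer to in absolute dose
distance. "Coincides with $R_{min}$" has no quantitative definition in
the literature this models; nearest-inflection distance plus an optional
nearest-treatment mapping (ties toward the larger dose, the conservative
direction when benefits accrue above $R_{max}$) is this package's
operationalisation. When the primary fit is monotone the report states
that no inflection exists — the pattern is undetectable in such data, as
happens in practice when adaptation periods are long.

## The synthetic generator

`generate_primary()` draws Gaussian, homoscedastic noise around a
linear-logistic mean on a declared design — the simplest structure
consistent with least-squares fitting. The default
`synthetic_design()` mirrors the densest published layout the package
targets: 6 uniform levels over a 77–127 digestible Arg:Lys ratio, 8
replicates per level, noise SD 3% of the noiseless response range. The
default truth (`default_truth_params()`: $a=30$, $b=0.1$, $c=4$,
$f=0.2$, $\ln d = 0.2 \cdot 107$) puts $R_{max} \approx 98.2$ and
$R_{min} \approx 115.8$ inside that range, with 117 the nearest treatment
to $R_{min}$. Per-species noise magnitudes are not recoverable from the
source literature; 3% of range is a documented choice, fixed once.

`generate_companion()` produces the paired physiological response: a
continuous linear-plateau (or logistic rise) whose breakpoint (midpoint)
sits exactly at a chosen anchor, typically the primary's true $R_{min}$.
Count-like companions (survival, litter size) are still generated as
Gaussian around the mean curve; binomial noise is out of scope. What
passing tests show, therefore, is that the pipeline recovers the truth
under Gaussian additive noise on a balanced design — not that real data
are homoscedastic, that real companions are exact plateaus, nor anything
about animal-level covariates (sex, genetics, fiber level) or the
age-dependent decay of the pattern.

`recovery_study()` wraps the loop simulate → fit both models → summarise
bias/RMSE (and optionally bootstrap coverage) per design cell.

## Problem sizes used by the checks

The shipped checks run 1000 random parameter draws for the closed-form
oracle comparison, 200 simulated studies for recovery medians, 200
studies × 200 bootstrap replicates for the 90%-interval calibration, and
100 low-noise pairs per anchor for the coincidence classification — sizes
at which the Monte-Carlo error is comfortably below the tolerances being
asserted while a full run stays in the minutes range on one core.

## Limitations

- Weighted, heteroscedastic and mixed-effects titration models are out of
  scope; so are Bayesian fits and formal hypothesis tests of
  breakpoint-equals-$R_{min}$.
- Percentile intervals can undercover near design edges; calibration is
  verified only under the default design's conditions.
- The five-model candidate set is a declared convention, not an exhaustive
  dose-response taxonomy.
- AICc counts the error variance as a parameter; comparisons are only
  meaningful within the candidate set fitted to identical data.
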