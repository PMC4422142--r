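---
title: "Distributional dichotomisation of continuous outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributional dichotomisation of continuous outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dichodist)
```

## The problem

Clinical research routinely reduces a continuous outcome to a binary one at
a cut-point: birthweight under 2500 g is "low birthweight", systolic blood
pressure over 160 mmHg is "high blood pressure", BMI over 30 is "obesity",
gestational age under 37 weeks is "preterm". Comparing two groups on the
dichotomised outcome is easy to communicate but, done by counting, discards
most of the information in the data and with it statistical power.

The distributional approach keeps both presentations coherent: the
proportion beyond the cut-point is computed from the fitted distribution of
the outcome — its mean, standard deviation and, when the data are skewed, a
shape parameter — so the comparison of proportions is a smooth function of
the comparison of means and inherits its precision. `dichodist` implements
this for normally distributed outcomes and generalises it to skewed
outcomes through the skew-normal distribution, together with the monotone
transformations (log, square root, square, inverse, negation, reflected
log) that practitioners use to normalise skewed data, and a simulation
framework for checking when each method can be trusted.

## The model

A skew-normal outcome with shape $\alpha$ has density

$$ f(x) = \frac{2}{w}\,\varphi\!\left(\frac{x-\xi}{w}\right)
  \Phi\!\left(\alpha\,\frac{x-\xi}{w}\right), $$

where $\xi$ is a location and $w$ a scale parameter. $\alpha = 0$ recovers
the normal distribution; positive $\alpha$ skews to the right. Because
analysts report means and SDs, the package works in the *centred*
parameterisation $(\mu, \sigma, \alpha)$ and converts internally using

$$ \mu_z = \sqrt{2/\pi}\,\frac{\alpha}{\sqrt{1+\alpha^2}}, \qquad
   w = \frac{\sigma}{\sqrt{1-\mu_z^2}}, \qquad
   \xi = \mu - w\,\mu_z, $$

which guarantees that the fitted distribution has mean $\mu$ and variance
$\sigma^2$ exactly (`sn_direct()`, `sn_centred()`). The sign of $\mu_z$
follows the sign of $\alpha$; this is forced by requiring $E[X] = \mu$.
Note that $|\mu_z| < \sqrt{2/\pi}$, so $w \ge \sigma$ with equality only at
$\alpha = 0$.

The proportion below a cut-point $x_0$ is
$p = \Phi(z) - 2\,T(z, \alpha)$ with $z = (x_0-\xi)/w$ and $T$ Owen's T
function (`pskewnorm()`, `owens_t()`). Owen's T is evaluated by reducing
the second argument to $|a| \le 1$ with the standard identity and applying
adaptive quadrature to the defining integral; an adaptive-quadrature
evaluation of the density integral is kept as an automatic fallback and as
an internal cross-check. Both factors of the density use the same centred
argument $(x_0 - \xi)/w$; the moment round-trip, the reflection symmetry
$P(X \le x_0;\alpha) = 1 - P(X \le 2\mu - x_0;-\alpha)$ and an empirical
CDF comparison over $10^6$ simulated draws all verify this convention in
the test suite.

## Delta-method standard errors

Seen as a function of the sample mean $\bar X_n$ (with $\sigma$ and
$\alpha$ held at their pooled estimates), the proportion has derivative

$$ p'(\mu) = -\frac{2}{w}\,\varphi\!\left(\frac{x_0-\xi}{w}\right)
   \Phi\!\left(\alpha\,\frac{x_0-\xi}{w}\right) = -f(x_0), $$

minus the density at the cut-point (`skewnorm_dp_dmean()`): raising the
mean moves mass past a fixed cut, at a rate given by the density there. The
delta method then gives

$$ \operatorname{var}(p) = \frac{\sigma^2}{n}\,p'(\mu)^2 . $$

For two groups sharing $\sigma$ and $\alpha$ (the equal-variance,
equal-skewness assumption) with tail proportions $p_1, p_2$, the
comparisons and their variances are

$$ se(d)^2 = v_1 + v_2, \qquad
   se(\log rr)^2 = \frac{v_1}{p_1^2} + \frac{v_2}{p_2^2}, \qquad
   se(\log or)^2 = \frac{v_1}{(p_1(1-p_1))^2} + \frac{v_2}{(p_2(1-p_2))^2}, $$

with $v_i = (\sigma^2/n_i)\,p'(\mu_i)^2$. Distributional confidence
intervals (DCIs) are symmetric normal-quantile intervals, built on the log
scale and exponentiated for the two ratios. The method is a large-sample
approximation, so standard normal quantiles are used with no small-sample
t correction. The test suite validates the SE formulas against the
Monte-Carlo SD of the estimates over 20&nbsp;000 replicates — the same
criterion the simulation study reports as SE bias.

## Parameters that matter

* **`alpha` (shape, dimensionless).** 0 = normal method. The attainable
  moment skewness of a skew-normal is bounded by about $|0.995|$; samples
  beyond the bound (common for strongly lognormal data) are fitted near
  the boundary and flagged (`fit_skew_normal()` diagnostics) rather than
  rejected.
* **`sd_pooled` (outcome units).** Default: df-weighted pooled SD,
  $\sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}$ — the standard
  equal-variance estimator. When a pooled model is built from raw data by
  joint maximum likelihood, the jointly estimated centred SD is used
  instead.
* **Confidence `level`.** Default 0.95.
* **`method_guard()` thresholds.** `alpha_threshold = 1`: at or below this
  the data are a small deviation from normality, where the normal method is
  reliable and the skew-normal fit is erratic unless n is very large.
  `n_min = 50` per group: below this the skew-normal standard errors are
  unreliable even under real skewness, so the normal method is returned
  with a warning. Both defaults mirror where the simulation study places
  the reliability boundaries.

## Fitting

Maximum likelihood runs in the centred parameterisation $(\mu, \log\sigma,
\alpha)$, which avoids the singular information matrix the direct
parameterisation suffers at $\alpha = 0$. Optimisation is multi-start
(BFGS from the method-of-moments shape and from 0, keeping the better
optimum); the moment start inverts
$\gamma_1 = \frac{4-\pi}{2}\mu_z^3/(1-\mu_z^2)^{3/2}$ in closed form, with
$|\gamma_1|$ truncated just inside the attainable bound. The two-group
model (`build_pooled_model()`) estimates one shared $(\sigma, \alpha)$ with
free group means; the model's means, however, are the *sample* means,
since the distributional proportion is a function of the sample mean whose
variability the delta method tracks. A moment-based pooling
(`pool_skewness = "moment"`: shape from the skewness of the pooled centred
residuals, df-pooled SD) is provided as a sensitivity alternative. A
non-convergent fit falls back to the normal method with a warning;
`method = "auto"` delegates the normal/skew-normal choice to
`method_guard()`.

## Transforms and thresholds

A continuous strictly monotone transform leaves the proportion beyond a
threshold unchanged: increasing transforms (log, sqrt, square on positive
values) preserve the tail, decreasing ones (inverse, negation,
$\log(c-x)$) flip it. `map_threshold()` applies the transform to the
cut-point and flips the tail exactly when the transform is decreasing, so
"BMI above 30" becomes "inverse BMI below 1/30" automatically.
Two conventions are fixed here and checked by `preserve_proportion_check()`:

* *Boundary:* "under the threshold" means strictly below ($x < x_0$) for
  empirical counts; for the continuous fitted model $P(X < x_0) =
  P(X \le x_0)$, so distributional estimates are unaffected.
* *Reflection point:* the constant $c$ in $\log(c - x)$ (45 weeks for
  gestational age is the usual domain convention) is user-supplied, never
  inferred from data.

## The simulation framework

`sim_scenario()` / `run_scenario()` emulate the validation design:
data from (1) a lognormal family — genuinely misspecified for both
estimators, skewness indexed by the log-SD over 0.02–1, gauged by the
mean/median ratio $\exp(\sigma_{\log}^2/2)$ — and (2) a skew-normal family
with $\alpha \in [-20, 20]$; per-group sizes 20–500; standardised effect
sizes 0.01–0.5. Choices the design left open, fixed here once:

* **Effect size** is the raw-scale mean difference over the *reference
  group's SD* (an `effect_scale = "se"` switch divides by $\sqrt{n}$
  instead). The lognormal effect is imposed by shifting the exposed
  group's raw-scale mean with a shared log-SD, so both groups remain
  lognormal; their SDs then differ slightly, which is part of the
  misspecification being studied.
* **Cut-point placement** is by the reference group's true tail
  probability (default 0.1, grid 0.05/0.1/0.2 in grid runs), so cut-points
  are comparable across skewness levels.
* **Truth** is always analytic, from the generating CDF — for lognormal
  data scored under either method the lognormal tail probability is the
  estimand, because model misspecification is the point.
* **Aggregation** (`summarize_grid()`): per (n, skewness) cell, 3rd
  quartile of |relative bias| of estimates, 3rd quartile of |relative SE
  bias| (mean SE vs SD of estimates, on the log scale for the ratios,
  mirroring how the DCIs are built), and the interquartile range of
  coverage. Quantiles use linear interpolation (`stats::quantile` type 7)
  by default; the rule is configurable since nearest-order-statistic
  conventions differ.
* **Replicates** default to 20&nbsp;000. The packaged acceptance checks
  run 20&nbsp;000 replicates for the SE-validity comparison and 2&nbsp;000
  for coverage (binomial Monte-Carlo SD ≈ 0.005 at nominal 95%, so the
  [0.93, 0.96] acceptance band leaves headroom), with 300-replicate smoke
  tests elsewhere; these sizes are the package's own trade-off between
  resolution and runtime.
* A replicate whose estimator fails (degenerate tail, non-convergence) is
  counted; a scenario aborts if more than 1% fail, rather than silently
  summarising a selected subset.

What the generators emulate — and what they do not: two-group comparisons
with a shared scale and shape, no covariates, no measurement error, no
truncation or digit preference, and independent observations. Passing
simulations therefore show calibration under clean sampling from the
assumed (or deliberately misspecified) families, not robustness to the
messiness of real cohort data.

Two empirical regularities the framework reproduces are worth knowing
when choosing a method: under strong lognormal skewness the normal
method's coverage for the difference in proportions collapses as n grows
(bias shrinks more slowly than the SE — the acceptance scenario at log-SD
1, n = 500, effect 0.5 sits deep in that regime), while the skew-normal
method is well calibrated on skew-normal data once $|\alpha| \gtrsim 5$
and n ≥ 50 per group. Conversely, near-normal data defeat the skew-normal
method at moderate n — the shape is barely identified and its sampling
distribution is wild — which is precisely what `method_guard()` encodes.

## Numerical choices

* Owen's T: reduction to $|a| \le 1$, then `integrate()` at rel.tol 1e-12;
  closed forms at $h = 0$ or $a \in \{0, \pm\infty\}$.
* CDF fallback quadrature: absolute tolerance 1e-10, integration from
  $\xi - 15w$; failure raises a numerical error naming the offending
  parameter values rather than returning NA.
* Degenerate tails: a cut-point more than 10 pooled SDs from a group mean
  makes the proportion numerically 0 or 1; `distributional_proportion()`
  refuses with an explicit error advising against dichotomising there.
* Probabilities are clipped to [0, 1] only against sub-epsilon quadrature
  noise; no other clipping is applied.
* MLE: BFGS, maxit 500, multi-start as above; determinism is tested (same
  data, same result — no randomness inside the fit).

## Known limitations

* Unadjusted two-group comparisons only; no regression adjustment, mixed
  models, censoring, or Bayesian fitting.
* The equal-variance, equal-skewness assumption is maintained, not tested;
  grossly unequal group SDs will bias both methods.
* Data more skewed than the skew-normal bound are fitted at the boundary —
  the fit is then a projection, and a transform may serve better.
* Exact binomial intervals for observed counts are out of scope; the
  package's intervals are large-sample distributional ones.
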