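---
title: "Marginalized two-part models for longitudinal semicontinuous outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marginalized two-part models for longitudinal semicontinuous outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtplong)
```

## The problem

Many biomarkers measured repeatedly over time are *semicontinuous*: a
substantial share of measurements sits exactly at zero (below detection,
production switched off), while the rest follow a skewed positive
distribution.  Plasma connective tissue growth factor (CTGF) in type 1
diabetes cohorts is the motivating example — roughly 60% of repeated
measurements are negligible/zero — but the same structure arises for
cytokine panels, health-care costs, and usage data.  Treating such an
outcome with a single continuous model biases both estimates and tests;
dropping the zeros throws away the information they carry.

`mtplong` fits four model families to long-format panels of this kind, all
by maximum marginal likelihood:

1. **Marginalized two-part (mTP)** — the package's centerpiece.
2. **Two-part with correlated random intercepts (TP-correlated).**
3. **Two-part with uncorrelated random intercepts (TP-uncorrelated)** —
   the two parts fit separately.
4. **One-part** — a single log-link model for all values, zeros replaced
   by a small constant.

## Model structure

Write $Y_{ij} \ge 0$ for subject $i$ at visit $j$, with covariate vectors
$z_{ij}$ (zero part) and $x_{ij}$ (continuous part).  All two-part
families share a logistic zero part,

$$\mathrm{logit}\,\pi_{ij} = z_{ij}'\alpha + u_{1i}, \qquad
\pi_{ij} = \Pr(Y_{ij} > 0 \mid u_{1i}),$$

and a generalized gamma (GG) continuous part with location $\mu_{ij}$,
scale $\sigma$ and shape $k$.  The random intercepts
$(u_{1i}, u_{2i})$ are bivariate normal with covariance $G$, inducing the
within-subject correlation across visits and the cross-part correlation
between the zero and positive processes.

The GG density in this parameterization (with $\eta = |k|^{-2}$,
$u = \mathrm{sign}(k)(\log y - \mu)/\sigma$) is

$$f(y) = \frac{\eta^{\eta}}{\sigma\, y\, \Gamma(\eta)\sqrt{\eta}}
 \exp\{u\sqrt{\eta} - \eta e^{|k|u}\},$$

with mean $E(Y) = \exp\{\mu + C(\sigma,k)\}$ and offset
$C(\sigma,k) = \sigma\log(k^2)/k + \log\Gamma(\eta + \sigma/k)
- \log\Gamma(\eta)$.  Setting $\sigma = k$ gives the standard gamma
($C = 0$), $k = 1$ the Weibull ($C = \log\Gamma(1+\sigma)$), and
$k \to 0$ the lognormal ($C = \sigma^2/2$).

**Conventional two-part (TP)** models the conditional location,
$\mu_{ij} = x_{ij}'\delta + u_{2i}$: the coefficients $\delta$ describe
the positive values only, *given* that the outcome is non-zero.

**Marginalized two-part (mTP)** instead parameterizes the *overall*
marginal mean $E(Y_{ij} \mid u_{2i}) = \exp(x_{ij}'\beta + u_{2i})$ —
zeros included — and solves for the GG location that enforces it:

$$\mu_{ij} = x_{ij}'\beta + u_{2i} - \log \pi_{ij} - C(\sigma, k).$$

This makes $\exp(\beta_p)$ the multiplicative effect of covariate $p$ on
the population mean of the full semicontinuous outcome, which is usually
the scientifically relevant effect; `mtp_location()` implements the
identity $\pi\exp(\mu + C) = \exp(x'\beta + u_2)$ exactly, and the test
suite checks it to machine precision.

**One-part** applies the GG density with
$\log \mu_{ij} = w_{ij}'\gamma + u_{0i}$ to every record after replacing
zeros by a small constant $c$ (default: half the smallest positive
outcome, configurable via `model_spec(one_part_constant=)`).

## Estimation

The marginal likelihood integrates the per-subject conditional likelihood

$$\prod_j (1-\pi_{ij})^{I(y_{ij}=0)}
 \left[\pi_{ij}\, f(y_{ij};\mu_{ij},\sigma,k)\right]^{I(y_{ij}>0)}$$

against the bivariate normal density of $(u_1, u_2)$.  Numerical choices:

* **Adaptive Gauss–Hermite quadrature**, 7 nodes per dimension by default
  (tensor product, 49 evaluations per subject in 2-D).  Each subject's
  rule is recentered and rescaled at the posterior mode of its random
  effects, found by a damped Newton search with finite-difference
  derivatives (started from the previous evaluation's mode); if the
  search fails the non-adaptive rule centered at the prior is used for
  that subject.  On test fixtures, adaptive 7-node quadrature agrees with
  brute-force grid integration to relative error below $10^{-4}$ and with
  a 15-node rule to below $10^{-5}$; the non-adaptive rule is orders of
  magnitude worse at the same node count.
* **Unconstrained parameterization**: $\log\sigma$ (and $\log k$ where
  the named distribution requires $k > 0$), log random-effect SDs and
  $\mathrm{atanh}$ of their correlation, which keeps $G$ positive
  semidefinite without constrained optimization.  Random-effect SDs below
  $10^{-8}$ drop their dimension from the integral exactly, so a zero
  variance reduces to the conditional likelihood at $u = 0$.
* **Lognormal switch**: shapes with $|k| \le 10^{-4}$ are evaluated in the
  analytic $k \to 0$ limit; the direct formula's departure from the limit
  (of order $k|u|^3/6$ on the log scale) is below $10^{-3}$ at the switch
  point over the central range of the density, and a continuity test
  covers the seam.
* **Optimization**: BFGS on the unconstrained scale (relative objective
  tolerance $10^{-8}$, up to 500 iterations, one polishing restart), with
  stage-wise starting values — a plain logistic GLM for $\alpha$, a
  log-scale least-squares fit on the positives for $\delta$ (a log-link
  moment fit over all records for $\beta$), variances 0.25, correlation 0.
  These warm starts converged in every simulated setting we exercised, so
  the costlier option of warm-starting the mTP from a full TP-correlated
  solution is not the default (supply `control = list(start = ...)` to
  do so).
* **Convergence declaration**: optimizer success *and* a finite-difference
  gradient-norm check with tolerance $\max(10^{-3}, 10^{-4}(1 + |\ell|))$.
  The tolerance scales with the objective because both the
  finite-difference noise floor and the gradient norm reachable at a given
  relative-change tolerance grow with $|\ell|$; at this threshold the
  implied parameter error is about $10^{-4}$, far below any standard
  error.  Non-convergence is always reported, never silent.
* **Standard errors**: inverse of a central finite-difference Hessian of
  the negative log-likelihood at the optimum, mapped to the natural scale
  (coefficients, shape/scale, variances, covariance) by the delta method.
  A singular or indefinite Hessian — typically a variance estimated at the
  boundary — yields `NA` standard errors with an explicit warning.  Wald
  $z$ p-values are reported; variance components get no p-value.
* **Information criteria**: $\mathrm{AIC} = -2\ell + 2p$,
  $\mathrm{BIC} = -2\ell + p\log(\text{number of subjects})$.  BIC uses
  subjects — the independent sampling units — which reproduces the
  published mTP-gamma fit statistics to rounding, whereas the record count
  would not.
* **Empirical Bayes**: predicted random intercepts are the per-subject
  posterior modes at the MLE (the adaptive centering points); they shrink
  to zero as a subject contributes less data.

The likelihood kernel is compiled (Rcpp), with per-observation linear
predictors and the density's constant terms precomputed once per
evaluation; everything else is plain R.

## The simulator and the replicate study

`simulate_panel()` draws from the generative model itself: random
intercepts from $N_2(0, G)$, covariates from a configurable scheme,
a Bernoulli non-zero indicator with probability $\pi_{ij}$, and positive
values from the GG family at the family's location (via the gamma
transform $y = \exp\{\mu + (\sigma/k)\log(k^2 g)\}$, $g \sim
\Gamma(1/k^2, 1)$).

The default study design is fixed once and documents its own truth:
200 subjects with 9 repeated measures and a 30% marginal zero proportion
(the 50% variant uses 12 visits), one subject-level binary covariate
(`group`, Bernoulli(0.5)) and one visit-level standard-normal covariate
(`biom`) shared by both parts, zero-part slopes $(0.4, -0.4)$,
marginal-mean coefficients $(0.5, 0.3, -0.3)$, gamma shape
$k = \sigma = 0.7$, random-intercept variances $0.5$ with correlation
$0.5$.  The zero-part intercept is *calibrated* to the target zero
proportion by solving $E[1 - \mathrm{expit}(\alpha_0 + z'\alpha + u_1)] =
\text{target}$ with Gauss–Hermite quadrature over $u_1$ and a large
fixed covariate draw (`calibrate_zero_intercept()`); simulated designs
hit their target within one percentage point.

`run_replicate_study()` simulates replicates (seeds derived from the
master seed by a counter scheme, so studies are reproducible and
parallelizable), fits any subset of the four families, and summarizes
bias and MSE of the continuous-part coefficients against the generative
truth, per parameter and aggregated.  The headline aggregate is over the
*slope* coefficients, whose generative values are the marginal
multiplicative effects that all four families attempt to estimate; the
conditional intercept of the TP families targets a different quantity and
would dominate any aggregate that included it.  Non-converged replicates
are excluded and counted.

Under this design the mTP fit has the smallest aggregate absolute bias
and MSE of the four families — the package's acceptance suite asserts
this strictly with 100 replicates.  The *relative* ranking of the other
three is not a theorem: the one-part model's slopes also target the
marginal mean (its distortion comes from the zero-replacement constant
and the misspecified density), and under our documented truth it can beat
the conditional-slope TP models.  Published orderings of those
comparators depend on generating parameters that are not stated; the
study driver therefore reports raw per-model cells and leaves secondary
orderings as a warning-level diagnostic rather than a hard assertion.

## What the simulator does and does not emulate

The generator reproduces the structural features that matter for the
estimators: the point mass at zero with logistic covariate dependence,
skewed GG-distributed positives, within-subject correlation through
random intercepts, and cross-part correlation.  It does **not** emulate
detection-limit censoring (zeros are generated by the binary process, not
by thresholding a latent positive), covariate measurement error,
missing-visit mechanisms, serial correlation beyond the random
intercepts, or random slopes.  Passing tests therefore demonstrate
correctness of the estimators under the assumed model class, not
robustness to violations of it.

## Problem sizes used in the test suite

The shipped tests run the recovery check at 500 subjects × 9 visits, the
Wald-coverage check at 120 subjects × 5 visits with 200 replicates
(5-node quadrature), and the comparative study at 200 subjects × 9 visits
with 100 replicates (7-node quadrature); the acceptance script uses 60
study replicates.  These sizes were chosen to make the Monte-Carlo noise
small relative to the assertions being made while keeping a full run in
the tens of minutes on one CPU.

## Known limitations

* Only random intercepts are supported — no random slopes, and the
  random effects are normal by assumption.
* $\sigma$ and $k$ are common to all observations (no covariate-dependent
  dispersion).
* Gradients and Hessians are finite-difference; analytic derivatives
  would speed up and sharpen convergence for large panels.
* The full GG family (`distribution = "gg"`, free $k$ of either sign) is
  supported in the likelihood, but fitting near the $k = 0$ seam relies
  on the lognormal-limit switch and can be slow to converge; the named
  special cases are the recommended workhorses.
* Two-part families require both zeros and positives in the data; fits
  with a variance component on the boundary report `NA` standard errors
  rather than pretending the Wald theory applies.
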