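---
title: "Corrected likelihood-based boosting for linear mixed models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corrected likelihood-based boosting for linear mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbbLMM)
```

## The model and the problem

For clusters $i = 1, \dots, n$ with observations $j = 1, \dots, n_i$ the
package fits the Gaussian linear mixed model

$$y_{ij} = \beta_0 + x_{ij}^\top\beta + z_{ij}^\top\gamma_i + \varepsilon_{ij},
\qquad \varepsilon_{ij} \sim N(0, \sigma^2),\quad \gamma_i \sim N_q(0, Q),$$

or in stacked notation $y = \beta_0\mathbf{1} + X\beta + Z\gamma +
\varepsilon$ with $Z = \mathrm{diag}(Z_1,\dots,Z_n)$ block-diagonal. Two
likelihoods matter:

* the **marginal** log-likelihood, with the random effects integrated out —
  each cluster contributes a Gaussian density with covariance
  $V_i = Z_i Q Z_i^\top + \sigma^2 I$; and
* the **penalized** (Laplace-approximated) log-likelihood
  $\sum_i \log f(y_i \mid \vartheta, \phi) - \tfrac12 \sum_i
  \gamma_i^\top Q^{-1} \gamma_i$, the working objective of the boosting
  updates.

Component-wise boosting is attractive here because it performs variable
selection implicitly and scales to many more candidate covariates than
observations. The catch, and the reason this package exists, is the
interplay between random intercepts and **cluster-constant covariates**
(baseline covariates such as gender or a treatment arm, constant within each
cluster). When fixed effects are built up in small regularized steps while
random intercepts are estimated freely, the per-cluster intercepts can
absorb a baseline covariate's effect wholesale: the covariate is never
selected, its coefficient stays at zero, and the random-intercept estimates
separate by the covariate's levels. The fit's predictions look fine; the
inference is wrong.

## The algorithm

`lbbLMM()` runs, per iteration $m$:

1. **Component-wise fixed-effects update.** For each candidate $r$ the
   Fisher-scoring update of $(\beta_0, \beta_r)$ under the penalized
   likelihood is $u_r = F_r^{-1} s_r$ with
   $s_r = \sigma^{-2}\tilde X_r^\top (y - \eta)$ and
   $F_r = \sigma^{-2}\tilde X_r^\top \tilde X_r$, where
   $\tilde X_r = (\mathbf{1}, X_{\cdot r})$ and $\eta$ is the current fit.
   The error variance cancels, so $u_r$ is simply the least-squares
   regression of the current residual on $(\mathbf{1}, x_r)$ — a property
   the unit tests exploit as an oracle. The candidate minimizing the
   information criterion is applied, scaled by the step length $\nu$; all
   other coordinates are untouched, so after $m$ iterations at most $m$
   coefficients are nonzero and the unselected ones are exactly zero.
2. **Weak corrected random-effects update.**
   $\gamma \leftarrow \gamma + \nu\, C F_{\mathrm{ran}}^{-1}
   s_{\mathrm{ran}}$, where $F_{\mathrm{ran}} =
   \mathrm{diag}(F_1,\dots,F_n)$ with $F_i = \sigma^{-2} Z_i^\top Z_i +
   Q^{-1}$ is block-diagonal (one $q \times q$ solve per cluster) and $C$ is
   the correction operator described below. Updating the random effects
   separately from the fixed effects — and weakly, with the same $\nu$ —
   keeps the candidate comparison in step 1 fair and stops the random
   effects from growing faster than the regularized fixed effects.
3. **Approximate EM variance updates.**
   $Q \leftarrow \frac1n \sum_i (F_i^{-1} + \hat\gamma_i
   \hat\gamma_i^\top)$ using the posterior curvatures $F_i$, then
   $\sigma^2 \leftarrow \widehat{\mathrm{Var}}(y - \hat\eta)$.

The information criterion is recorded after every iteration and the fit is
returned at $m^* = \arg\min_m \mathrm{IC}^{[m]}$. The whole loop is
deterministic: refitting reproduces the path bit for bit.

### The correction operator

For each random effect $s$ collect its cluster-level coefficients
$\tilde\gamma_s = (\gamma_{s1}, \dots, \gamma_{sn})^\top$ and a matrix
$X_{cs}$ of correction covariates with one representative row per cluster.
The operator applies $I_n - C_s$ with the hat matrix
$C_s = X_{cs}(X_{cs}^\top X_{cs})^{-1} X_{cs}^\top$, i.e. it removes the
orthogonal projection of $\tilde\gamma_s$ onto the span of $X_{cs}$. For the
random intercept $X_{cs}$ holds all cluster-constant covariates; for every
random slope it is a single ones column, which centers the slope
coefficients. Because every random-effects increment passes through this
projection and $\gamma$ starts at zero, the estimates stay exactly
uncorrelated with the correction covariates along the whole path — the
mechanism that prevents random intercepts from absorbing baseline effects.

Two design choices were genuinely open:

* **A ones column for the intercept.** We include a ones column in the
  intercept's correction covariates in addition to the cluster-constant
  covariates (switchable via `center_intercept`). Centering the random
  intercepts keeps the global intercept $\beta_0$ identifiable, and
  whenever a constant lies in the span of the cluster-constant covariates
  (e.g. with a full set of group dummies) the projector is identical either
  way.
* **Rank-deficient $X_{cs}$.** Collinear correction covariates are handled
  with a rank-revealing QR: the projector targets the column space actually
  spanned, which is well defined regardless of basis rank; a warning names
  the dropped directions.

### Information criteria, selection and stopping

Both the per-iteration component selection and the stopping rule use
$\mathrm{AIC} = -2\ell + 2\,\mathrm{df}$ or
$\mathrm{BIC} = -2\ell + \log(n)\,\mathrm{df}$ (default), with $n$ the
number of clusters and
$\mathrm{df} = \#\phi + \#\{r \le p : \beta_r \ne 0\}$, where
$\#\phi = 1 + q(q+1)/2$ counts the error variance and the unique elements of
$Q$. Nonzero-ness is exact: boosting only ever touches selected
coordinates, so no tolerance is needed.

$\ell$ is by default the **marginal** log-likelihood. A likelihood
conditional on the current $\gamma$ would reward whatever the random
effects currently explain and thereby bias the comparison between
candidates — the very distortion the correction step is designed to
remove — and criterion-based stopping of this kind is justified by its
asymptotic equivalence to cluster-wise cross-validation through the
marginal criterion. A conditional variant is available via
`boost_control(conditional_ic = TRUE)` for sensitivity analysis; both
variants are covered by the replay tests.

The candidate criterion in step 1 evaluates the fixed-effect update alone,
not the subsequent random-effects and variance updates: the candidates are
compared under identical $(\gamma, \sigma^2, Q)$, which is both the cheapest
and the fairest reading of "best performing component". Ties (possible only
with duplicated covariates) break deterministically to the lowest index.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `nu` | 0.1 | step length in $(0,1]$; the conventional weak-learning value, applied to fixed and random updates alike |
| `mstop` | 1500 | maximum iterations; a warning is raised if the criterion is still decreasing at `mstop` |
| `criterion` | BIC | selection and stopping criterion |
| `start` | simple | `simple`: $\beta_0 = \bar y$, $\sigma^2 = \widehat{\mathrm{Var}}(y)$, $\beta = 0$, $\gamma = 0$, $Q = 0.1 I$; `premodel`: intercept-plus-random-effects EM fit |

Starting the selection parameters at zero is not optional — it is what makes
the selection path meaningful. $Q^{[0]} = 0.1 I$ is deliberately small so
the early random-effects updates are heavily shrunk.

### Numerical choices

* $Q^{-1}$ uses a symmetric (Cholesky) solve; if the condition number
  exceeds $10^{12}$ a ridge $10^{-10}\,\mathrm{tr}(Q)/q$ is added with a
  warning.
* The EM update of $Q$ is PSD in exact arithmetic; after symmetrization,
  negative eigenvalues (floating-point drift) are clipped at zero, with a
  warning if the clip exceeds $10^{-8}$.
* $\widehat{\mathrm{Var}}$ is the sample variance (denominator $N-1$, mean
  subtracted), matching the initialization $\sigma^{2[0]} =
  \widehat{\mathrm{Var}}(y)$.
* Within an iteration the $V_i$ factorizations are computed once and shared
  across all $p$ candidate evaluations; candidate criteria are obtained
  from a quadratic expansion of the Gaussian quadratic form rather than $p$
  refactorizations. The test suite asserts that this fast path reproduces
  the naive step-by-step composition of the exported step functions to
  $10^{-10}$.
* Degenerate inputs: a zero-variance response is a data error; a candidate
  collinear with the intercept is skipped with a warning; more correction
  covariates than clusters is a configuration error; a numeric failure
  mid-path truncates the path with a warning rather than discarding the fit.

## The simulation harness

`sim_scenario()` / `simulate_lmm()` generate two longitudinal designs with
$n = 50$ clusters of $n_i = 5$ observations by default, all covariates
standard normal, $\beta_0 = 1$, $\beta = (2, 4, 3, 5, 0, \dots, 0)$,
$\sigma = 0.4$ and $\tau \in \{0.4, 0.8, 1.6\}$; covariates 1–2 are
cluster-constant (one draw per cluster), all others cluster-varying:

* **intercepts**: a random intercept $\gamma_{0i} \sim N(0, \tau^2)$;
* **slopes**: correlated random effects $(\gamma_{0i}, \gamma_{1i},
  \gamma_{2i}) \sim N_3(0, Q)$ with $\mathrm{diag}(Q) = \tau^2$, all
  off-diagonals $0.6\,\tau^2$, attached to the cluster-constant covariate
  $x_2$ and the cluster-varying covariate $x_4$.

Design matrices and random components are regenerated for every
replication; replication $r$ uses seed `seed + r`, so any subset of
replications is independently reproducible. `evaluate_fit()` computes
squared-error recovery metrics — $\mathrm{mse}_\beta = \lVert \beta -
\hat\beta \rVert^2$ over intercept plus all coefficients,
$\mathrm{mse}_\sigma$ and $\mathrm{mse}_\tau$ on the standard-deviation
scale, $\mathrm{mse}_Q$ as a squared Frobenius distance — and the selection
rates TP, FP and FDR, where a covariate counts as selected iff its final
coefficient is nonzero and FDR is defined as 0 when nothing is selected.
`run_study()` reports medians and interquartile ranges for the error
metrics and means for the selection rates, as is conventional for skewed
squared-error distributions.

A small worked cell:

```{r study, eval = FALSE}
sc <- sim_scenario("intercepts", tau = 0.4, p = 10, seed = 1)
run_study(sc, reps = 20, control = boost_control(criterion = "BIC"))
```

The reproduction scripts and the acceptance tests use 20 replications per
cell at $p = 10$, which keeps a full four-cell study in the
single-digit-minute range on one core while leaving the medians stable
enough to be meaningful; `reps` is a knob, and 100 replications is the
documented long-run setting. With these study conditions the package
obtains median $\mathrm{mse}_\beta$ near 0.014 (intercepts) and 0.030
(slopes) at $\tau = 0.4$, perfect TP/FP selection rates, and median
$\mathrm{mse}_\tau$ below 0.001 — the quantities `scripts/acceptance.R`
recomputes from scratch.

**What the generator does and does not emulate.** It produces balanced
clusters, exactly cluster-constant baseline covariates, uncorrelated
standard-normal covariates, and Gaussian random components — the idealized
conditions under which the identification problem and its correction can be
demonstrated cleanly. It does not produce unbalanced or small clusters,
correlated or heavy-tailed covariates, covariate-dependent cluster sizes,
missing data, or nonlinear effects. Passing the recovery tests therefore
shows the algorithm does what it claims under its stated model; it is not
evidence about misspecified real data, where the usual mixed-model caveats
apply.

## Known limitations

* The random-effects structure must be specified in advance; it is not
  itself subject to selection.
* Gaussian responses only; no generalized (non-Gaussian) extension and no
  smooth/P-spline effects.
* Missing data are handled by row deletion only, and there is no formula
  interface — columns are named explicitly (see `lmm_data()`).
* The `premodel` start uses the same approximate EM variance updates as the
  main loop, so its variance components agree with a full ML fit only to a
  few percent; the default `simple` start is used everywhere in the
  package's own experiments.
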