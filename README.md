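# lbbLMM

Component-wise **likelihood-based boosting for Gaussian linear mixed
models**, with a correction step that keeps random-effect estimates
uncorrelated with cluster-constant covariates.

## Who this is for

Biostatisticians and epidemiologists fitting longitudinal or otherwise
clustered data — repeated measurements per patient, pupils within schools —
who want regularized estimation with built-in variable selection, possibly
with many more candidate covariates than observations. The specific failure
mode this package addresses: when fixed effects are regularized but random
intercepts are not, a **cluster-constant covariate** (a baseline variable
such as gender or treatment arm) can be silently absorbed by the random
intercepts. The covariate is never selected, its effect estimate is zero,
and every cluster's intercept is shifted by the missing effect instead.

## The model and algorithm

For clusters *i* = 1..*n* with observations *j* = 1..*n<sub>i</sub>*:

    y_ij = beta0 + x_ij' beta + z_ij' gamma_i + eps_ij,
    eps_ij ~ N(0, sigma^2),   gamma_i ~ N_q(0, Q)

Each boosting iteration performs three steps:

1. **Fixed effects** — for every candidate covariate *r*, a Fisher-scoring
   update of (beta0, beta_r) on the penalized log-likelihood (equivalently:
   least squares of the current residual on (1, x_r)); only the candidate
   minimizing AIC/BIC is applied, scaled by the step length nu = 0.1.
2. **Random effects** — a weak Fisher step exploiting the block-diagonal
   Fisher matrix F_i = sigma^-2 Z_i'Z_i + Q^-1, passed through the
   correction operator C = P^-1 (I - diag(C_1, ..., C_q)) P, where each
   C_s is the hat matrix of that effect's correction covariates (all
   cluster-constant covariates for the random intercept; a ones column —
   i.e. centering — for every random slope). This keeps
   X_cs' gamma_s = 0 along the entire path.
3. **Variance components** — approximate EM:
   Q <- (1/n) sum_i (F_i^-1 + gamma_i gamma_i'), sigma^2 <- Var(y - eta).

The criterion (marginal likelihood; BIC by default, with
df = #phi + #{nonzero beta}) is tracked per iteration and the fit is
returned at its minimizer m*. See the vignette
(`vignettes/boosting-mixed-models.Rmd`) for the full account.

## Worked example

```r
library(lbbLMM)

## a random-intercepts scenario: 50 clusters x 5 observations, p = 10
## candidates of which x1..x4 are informative (beta = 2, 4, 3, 5) and
## x1, x2 are cluster-constant; tau = sigma = 0.4
sc  <- sim_scenario("intercepts", tau = 0.4, p = 10, seed = 1)
sim <- simulate_lmm(sc, seed = 2)

fit <- lbbLMM(sim$data, boost_control(criterion = "BIC"))
summary(fit)
#> Likelihood-based boosting fit for a linear mixed model
#>   BIC stopping at m* = 913 of 1500 iterations
#>   selected covariates (4 of 10): x1, x2, x3, x4
#>   sigma2 = 0.1283; random effects: (Intercept)
#>
#> Variance components:
#>   sigma2 = 0.1283
#>             (Intercept)
#> (Intercept)      0.1838
#>
#> Nonzero coefficients at m*:
#> (Intercept)          x1          x2          x3          x4
#>      1.0910      1.9565      4.0755      3.0390      4.9738

evaluate_fit(fit, sim$truth, sc)
#>    mse_beta   mse_sigma      mse_tau TP FP FDR m_star
#> 1 0.0180753 0.001747709 0.0008222986  1  0   0    913
```

Reading the output: exactly the four informative covariates were selected
(TP = 1, FP = 0), including the two cluster-constant ones, with
coefficients shrunk only slightly toward zero; the fitted random-intercept
variance 0.1838 is close to the generating tau^2 = 0.16
(mse_tau is on the standard-deviation scale), and the fitted sigma^2 =
0.1283 sits near the generating 0.16. The total squared coefficient error
over all 11 coordinates is 0.018.

Fitting your own data:

```r
d <- lmm_data(my_table, response = "y", cluster = "id",
              fixed = c("age", "treatment", "biomarker"),
              random_slopes = "age")
fit <- lbbLMM(d)
coef(fit); random_effects(fit); variance_components(fit); plot(fit)
```

A command-line wrapper with `fit` and `simulate` subcommands lives at
`inst/cli/lbblmm.R` (`Rscript inst/cli/lbblmm.R fit --help`).

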