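test_that("simple starting values follow the stated scheme", {
  tab <- data.frame(id = 1:3, y = c(1, 2, 3), x1 = c(0, 1, 0))
  d <- lmm_data(tab, "y", "id", fixed = "x1")
  st <- initialize_state(d, boost_control())
  expect_equal(st$beta0, 2)
  expect_equal(st$sigma2, 1)  # sample variance
  expect_equal(st$beta, 0)
  expect_equal(st$gamma, rep(0, 3))
  expect_equal(st$Q, matrix(0.1))

  d3 <- toy_data(n = 4, n_i = 3, p = 2, seed = 31, slopes = c("x1", "x2"))
  expect_equal(initialize_state(d3, boost_control())$Q, diag(0.1, 3))

  tab0 <- data.frame(id = 1:3, y = c(2, 2, 2), x1 = rnorm(3))
  d0 <- lmm_data(tab0, "y", "id", fixed = "x1")
  expect_error(initialize_state(d0, boost_control()), class = "lbb_data_error")
})

test_that("the premodel start matches a maximum-likelihood intercept-plus-random-effects fit", {
  skip_if_not_installed("lme4")
  sc <- sim_scenario("intercepts", n = 40, n_i = 5, p = 5, tau = 0.8, seed = 32)
  sim <- simulate_lmm(sc, seed = 33)
  st <- initialize_state(sim$data, boost_control(start = "premodel"))
  tab <- sim$table
  ml <- lme4::lmer(y ~ 1 + (1 | id), data = tab, REML = FALSE)
  expect_equal(st$beta0, unname(lme4::fixef(ml)[1]), tolerance = 1e-3)
  ## the internal fit uses the same approximate EM variance updates as the
  ## boosting loop, so variances agree with full ML only to a few percent
  expect_equal(st$Q[1, 1], unname(lme4::VarCorr(ml)$id[1, 1]), tolerance = 0.1)
  ## and it is within sampling error of the generating intercept
  expect_lt(abs(st$beta0 - mean(sim$data$y)), 1)
})

test_that("candidate updates solve the residual least-squares problem", {
  d <- toy_data(n = 4, n_i = 3, p = 3, seed = 34)
  ctrl <- boost_control()

  ## zero residual: zero score, zero update
  st_fit <- param_state(0, numeric(d$p), numeric(d$n), 1, matrix(0.1))
  d_exact <- d; d_exact$y <- linear_predictor(st_fit, d)
  cu <- candidate_update(1, st_fit, d_exact, ctrl)
  expect_equal(cu$u, c(0, 0))

  ## centered covariate with residual exactly 2 * x_r: update (0, 2)
  d2 <- d
  d2$X[, 2] <- d2$X[, 2] - mean(d2$X[, 2])
  st0 <- param_state(0, numeric(d$p), numeric(d$n), 1, matrix(0.1))
  d2$y <- 2 * d2$X[, 2]
  expect_equal(candidate_update(2, st0, d2, ctrl)$u, c(0, 2))

  ## random instance against the explicit normal-equation oracle
  st <- random_state(d, seed = 35)
  res <- d$y - linear_predictor(st, d)
  for (r in seq_len(d$p)) {
    Xt <- cbind(1, d$X[, r])
    oracle <- drop(solve(t(Xt) %*% Xt) %*% t(Xt) %*% res)
    expect_equal(candidate_update(r, st, d, ctrl)$u, oracle, tolerance = 1e-10)
  }

  ## the update is invariant to the error variance (it cancels in F^-1 s)
  st_b <- st; st_b$sigma2 <- st$sigma2 * 37.5
  for (r in seq_len(d$p)) {
    expect_equal(candidate_update(r, st, d, ctrl)$u,
                 candidate_update(r, st_b, d, ctrl)$u, tolerance = 1e-10)
  }

  ## candidate IC equals the criterion of the hypothetically updated state
  cu3 <- candidate_update(3, st, d, ctrl)
  expect_equal(cu3$ic$value,
               information_criterion(cu3$state, d, ctrl$criterion)$value)
})

test_that("selection applies only the winning component and breaks ties by lowest index", {
  d <- toy_data(n = 4, n_i = 3, p = 2, seed = 36)
  ctrl <- boost_control()
  st <- initialize_state(d, ctrl)
  sel <- select_and_apply(st, d, ctrl)
  expect_equal(sum(sel$state$beta != 0), 1L)
  expect_equal(which(sel$state$beta != 0), sel$selected)

  ## duplicated covariate: identical criteria, the lower index wins
  tab <- toy_table(n = 4, n_i = 3, p = 1, seed = 37)
  tab$x_dup <- tab$x1
  d_dup <- lmm_data(tab, "y", "id", fixed = c("x1", "x_dup"))
  sel_dup <- select_and_apply(initialize_state(d_dup, ctrl), d_dup, ctrl)
  expect_equal(sel_dup$ic[1], sel_dup$ic[2])
  expect_equal(sel_dup$selected, 1L)

  ## constant covariate collinear with the intercept is skipped with a warning
  tab$flat <- 1
  d_flat <- lmm_data(tab, "y", "id", fixed = c("x1", "flat"))
  expect_warning(sel_flat <- select_and_apply(initialize_state(d_flat, ctrl),
                                              d_flat, ctrl),
                 "collinear")
  expect_equal(sel_flat$selected, 1L)
})

test_that("the corrected random-effects step has the scalar closed form", {
  ## equal residual mean in every cluster, q = 1: the raw per-cluster step is
  ## n_i * rbar / sigma2 / (n_i / sigma2 + 1 / tau2); centering then removes it
  n <- 4; n_i <- 3
  tab <- data.frame(id = rep(1:n, each = n_i), y = 0, x1 = rnorm(n * n_i))
  d <- lmm_data(tab, "y", "id", fixed = "x1")
  rbar <- 0.9; sigma2 <- 0.5; tau2 <- 0.3
  d$y <- rep(rbar, n * n_i)
  st <- param_state(0, 0, numeric(n), sigma2, matrix(tau2))
  op <- build_correction(d)
  raw <- (n_i * rbar / sigma2) / (n_i / sigma2 + 1 / tau2)
  ## uncorrected raw step, then projection: equal values are fully centered out
  st1 <- random_effects_step(st, d, op, nu = 1)
  expect_equal(st1$gamma, rep(0, n), tolerance = 1e-12)
  ## with unequal cluster means the raw step minus its projection remains
  d$y <- rep(c(1, -1, 2, -2) * rbar, each = n_i)
  st2 <- random_effects_step(st, d, op, nu = 1)
  expected_raw <- c(1, -1, 2, -2) * raw
  expect_equal(st2$gamma, expected_raw - mean(expected_raw), tolerance = 1e-12)

  ## zero residual keeps gamma at zero
  d$y <- rep(0, n * n_i)
  expect_equal(random_effects_step(st, d, op, nu = 1)$gamma, rep(0, n))
})

test_that("the random-effects step leaves every effect orthogonal to its correction covariates", {
  d <- toy_data(n = 6, n_i = 4, p = 3, seed = 38, slopes = "x2")
  op <- build_correction(d)
  st <- initialize_state(d, boost_control())
  for (k in 1:5) {
    st <- random_effects_step(st, d, op, nu = 0.3)
    expect_lt(max_correction_violation(op, st$gamma), 1e-8)
  }
})

test_that("variance-component updates follow the approximate EM formulas", {
  ## q = 1, n = 2, gamma = (1, -1): Q_hat = mean(Finv) + mean(gamma^2)
  tab <- data.frame(id = rep(1:2, each = 2), y = rnorm(4), x1 = rnorm(4))
  d <- lmm_data(tab, "y", "id", fixed = "x1")
  sigma2 <- 2; tau2 <- 0.5
  st <- param_state(0, 0, c(1, -1), sigma2, matrix(tau2))
  finv <- 1 / (2 / sigma2 + 1 / tau2)   # n_i = 2 ones rows
  up <- update_variance_components(st, d)
  expect_equal(up$Q[1, 1], finv + 1)
  ## sigma2 becomes the sample variance of the current residuals
  resid <- d$y - linear_predictor(st, d)
  expect_equal(up$sigma2, var(resid))
})

test_that("the fast fit replays the exported step functions exactly", {
  d <- toy_data(n = 8, n_i = 4, p = 4, seed = 39, slopes = "x1")
  ctrl <- boost_control(mstop = 25, nu = 0.2)
  fit <- suppressWarnings(lbbLMM(d, ctrl))
  op <- build_correction(d, classify_covariates(d), ctrl$center_intercept)
  st <- initialize_state(d, ctrl)
  for (m in seq_len(ctrl$mstop)) {
    sel <- select_and_apply(st, d, ctrl)
    st <- sel$state
    st <- random_effects_step(st, d, op, ctrl$nu)
    st <- update_variance_components(st, d)
    expect_equal(fit$paths$selected[m], sel$selected)
    expect_equal(fit$paths$beta0[m], st$beta0, tolerance = 1e-10)
    expect_equal(unname(fit$paths$beta[m, ]), st$beta, tolerance = 1e-10)
    expect_equal(fit$paths$sigma2[m], st$sigma2, tolerance = 1e-10)
    expect_equal(fit$paths$gamma[m, ], st$gamma, tolerance = 1e-10)
    expect_equal(fit$paths$Q[m, ], st$Q[lower.tri(st$Q, diag = TRUE)],
                 tolerance = 1e-10)
    expect_equal(fit$paths$ic[m],
                 information_criterion(st, d, ctrl$criterion)$value,
                 tolerance = 1e-8)
  }
})

test_that("the conditional-criterion variant replays its reference path too", {
  d <- toy_data(n = 5, n_i = 3, p = 3, seed = 40)
  ctrl <- boost_control(mstop = 10, conditional_ic = TRUE)
  fit <- suppressWarnings(lbbLMM(d, ctrl))
  op <- build_correction(d)
  st <- initialize_state(d, ctrl)
  for (m in 1:10) {
    sel <- select_and_apply(st, d, ctrl)
    st <- update_variance_components(
      random_effects_step(sel$state, d, op, ctrl$nu), d)
    expect_equal(fit$paths$selected[m], sel$selected)
    expect_equal(unname(fit$paths$beta[m, ]), st$beta, tolerance = 1e-10)
  }
})

test_that("fit paths satisfy sparsity, positive-definiteness and orthogonality invariants", {
  sc <- sim_scenario("intercepts", n = 25, n_i = 4, p = 6, tau = 0.6, seed = 41)
  sim <- simulate_lmm(sc, seed = 42)
  fit <- suppressWarnings(lbbLMM(sim$data, boost_control(mstop = 120)))
  m_all <- nrow(fit$paths$beta)
  op <- fit$correction
  for (m in seq_len(m_all)) {
    ## at iteration m at most m coordinates are nonzero; others exactly zero
    expect_lte(sum(fit$paths$beta[m, ] != 0), m)
    expect_lte(sum(fit$paths$beta[m, ] != 0),
               length(unique(fit$paths$selected[seq_len(m)])))
    expect_lt(max_correction_violation(op, fit$paths$gamma[m, ]), 1e-8)
  }
  ## Q stays symmetric PSD along the whole path (q = 1: nonnegative)
  expect_true(all(fit$paths$Q[, 1] >= 0))
  expect_true(all(is.finite(fit$paths$ic)))
  ## unselected coordinates are identically zero
  never <- setdiff(seq_len(sim$data$p), unique(fit$paths$selected))
  if (length(never)) expect_true(all(fit$paths$beta[, never] == 0))
})

test_that("Q stays symmetric positive semi-definite along a random-slopes path", {
  sc <- sim_scenario("slopes", n = 20, n_i = 4, p = 5, tau = 0.5, seed = 43)
  sim <- simulate_lmm(sc, seed = 44)
  fit <- suppressWarnings(lbbLMM(sim$data, boost_control(mstop = 60)))
  for (m in seq_len(nrow(fit$paths$Q))) {
    Q <- matrix(0, 3, 3)
    Q[lower.tri(Q, diag = TRUE)] <- fit$paths$Q[m, ]
    Q <- Q + t(Q) - diag(diag(Q))
    ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
})

test_that("refitting reproduces the path bit-for-bit", {
  sc <- sim_scenario("intercepts", n = 20, n_i = 4, p = 5, seed = 45)
  sim <- simulate_lmm(sc, seed = 46)
  f1 <- suppressWarnings(lbbLMM(sim$data, boost_control(mstop = 80)))
  f2 <- suppressWarnings(lbbLMM(sim$data, boost_control(mstop = 80)))
  expect_identical(f1$paths, f2$paths)
  expect_identical(coef(f1), coef(f2))
})

test_that("full-step boosting on a single covariate converges to the GLS solution", {
  set.seed(47)
  n <- 50; n_i <- 5
  cl <- rep(seq_len(n), each = n_i)
  x <- rnorm(n * n_i)
  y <- 1 + 2 * x + rep(rnorm(n, 0, 0.4), each = n_i) + rnorm(n * n_i, 0, 0.4)
  d <- lmm_data(data.frame(id = cl, y = y, x = x), "y", "id", fixed = "x")
  fit <- suppressWarnings(lbbLMM(d, boost_control(mstop = 400, nu = 1)))
  m <- nrow(fit$paths$beta)
  gls <- gls_coef(d, fit$paths$sigma2[m],
                  matrix(fit$paths$Q[m, 1]))
  expect_equal(unname(fit$paths$beta[m, 1]), unname(gls[2]), tolerance = 1e-3)
})

test_that("fit accessors and path exports are consistent", {
  sc <- sim_scenario("intercepts", n = 15, n_i = 3, p = 5, seed = 48)
  sim <- simulate_lmm(sc, seed = 49)
  fit <- suppressWarnings(lbbLMM(sim$data, boost_control(mstop = 60)))
  expect_equal(unname(coef(fit)),
               c(fit$paths$beta0[fit$m_star], unname(fit$paths$beta[fit$m_star, ])))
  expect_equal(fitted(fit) + residuals(fit),
               sim$data$y[order(sim$data$orig_order)])
  cp <- coef_path(fit)
  expect_equal(nrow(cp), nrow(fit$paths$beta))
  expect_equal(cp$BIC, fit$paths$ic)
  re <- random_effects(fit)
  expect_equal(dim(re), c(sim$data$n, sim$data$q))
  tmp <- tempfile(fileext = ".csv")
  write_fit(fit, path_file = tmp)
  expect_equal(nrow(read.csv(tmp, check.names = FALSE)), nrow(cp))
})
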