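#' Define a simulation scenario
#'
#' Two longitudinal designs with standard-normal covariates and Gaussian
#' random components. Both share the fixed effects `beta0 = 1`,
#' `beta = (2, 4, 3, 5, 0, ..., 0)`; covariates 1 and 2 are cluster-constant
#' (one draw per cluster, repeated within), all others cluster-varying.
#' The `"intercepts"` design adds a random intercept `gamma_0i ~ N(0, tau^2)`;
#' the `"slopes"` design adds correlated random slopes on the cluster-constant
#' covariate `x2` and the cluster-varying covariate `x4`, with
#' `(gamma_0i, gamma_1i, gamma_2i) ~ N(0, Q)`, `diag(Q) = tau^2` and all
#' off-diagonals `slope_correlation * tau^2`.
#'
#' @param design `"intercepts"` or `"slopes"`.
#' @param n number of clusters (default 50).
#' @param n_i observations per cluster (default 5).
#' @param p total number of candidate covariates (default 10, must be >= 5).
#' @param tau random-effect standard deviation (default 0.4).
#' @param sigma error standard deviation (default 0.4).
#' @param slope_correlation pairwise correlation of the random effects in the
#'   slopes design (default 0.6).
#' @param seed base seed; replication `r` of [run_study()] uses `seed + r`.
#' @return an object of class `"sim_scenario"`.
#' @export
sim_scenario <- function(design = c("intercepts", "slopes"), n = 50L,
                         n_i = 5L, p = 10L, tau = 0.4, sigma = 0.4,
                         slope_correlation = 0.6, seed = 1L) {
  design <- match.arg(design)
  if (p < 5) lbb_config_error("p must be at least 5 (four informative covariates plus noise)")
  if (tau < 0 || sigma <= 0) lbb_config_error("tau must be >= 0 and sigma > 0")
  beta <- c(2, 4, 3, 5, rep(0, p - 4))
  q <- if (design == "slopes") 3L else 1L
  Q <- if (design == "slopes") {
    tau^2 * ((1 - slope_correlation) * diag(3) + slope_correlation)
  } else {
    matrix(tau^2, 1, 1)
  }
  structure(list(design = design, n = as.integer(n), n_i = as.integer(n_i),
                 p = as.integer(p), tau = tau, sigma = sigma,
                 slope_correlation = slope_correlation, seed = as.integer(seed),
                 beta0 = 1, beta = beta, q = q, Q = Q,
                 informative = 1:4, cluster_constant = 1:2),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("Simulation scenario (%s design)\n", x$design))
  cat(sprintf("  n = %d clusters x n_i = %d, p = %d covariates\n", x$n, x$n_i, x$p))
  cat(sprintf("  tau = %g, sigma = %g%s, seed = %d\n", x$tau, x$sigma,
              if (x$design == "slopes")
                sprintf(", slope correlation = %g", x$slope_correlation) else "",
              x$seed))
  invisible(x)
}

#' Generate one replication of a simulation scenario
#'
#' Covariates and random components are drawn fresh on every call
#' (design matrices are regenerated per replication).
#'
#' @param scenario a [sim_scenario()].
#' @param seed seed for this replication (default: the scenario seed).
#' @return list with `data` (an [lmm_data()] object), `truth` (the generating
#'   [param_state()]), `table` (the long-format table) and `scenario`.
#' @export
simulate_lmm <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(seed)
  n <- scenario$n; n_i <- scenario$n_i; p <- scenario$p
  N <- n * n_i
  X <- matrix(0, N, p)
  X[, 1] <- rep(stats::rnorm(n), each = n_i)   # cluster-constant
  X[, 2] <- rep(stats::rnorm(n), each = n_i)   # cluster-constant
  X[, 3:p] <- stats::rnorm(N * (p - 2))        # cluster-varying
  colnames(X) <- paste0("x", seq_len(p))

  q <- scenario$q
  if (scenario$tau > 0) {
    Gmat <- t(chol(scenario$Q)) %*% matrix(stats::rnorm(q * n), q, n)
  } else {
    Gmat <- matrix(0, q, n)
  }
  Zrows <- if (scenario$design == "slopes") {
    cbind(1, X[, 2], X[, 4])
  } else {
    matrix(1, N, 1)
  }
  cl <- rep(seq_len(n), each = n_i)
  eta_ran <- rowSums(Zrows * t(Gmat)[cl, , drop = FALSE])
  y <- scenario$beta0 + drop(X %*% scenario$beta) + eta_ran +
    stats::rnorm(N, sd = scenario$sigma)

  tab <- data.frame(id = cl, y = y, X, check.names = FALSE)
  slopes <- if (scenario$design == "slopes") c("x2", "x4") else character()
  data <- lmm_data(tab, response = "y", cluster = "id",
                   fixed = colnames(X), random_slopes = slopes,
                   random_intercept = TRUE)
  truth <- param_state(scenario$beta0, scenario$beta, as.vector(Gmat),
                       scenario$sigma^2, scenario$Q)
  list(data = data, truth = truth, table = tab, scenario = scenario)
}

#' Recovery and selection metrics from raw estimates
#'
#' Lower-level companion of [evaluate_fit()] operating on plain estimates;
#' useful for analytic checks (for example, zeroing the two informative
#' cluster-constant coefficients while keeping all other coordinates exact
#' yields the squared-error floor `2^2 + 4^2 = 20`).
#'
#' @param beta0_hat,beta_hat fitted intercept and fixed effects.
#' @param sigma2_hat fitted error variance.
#' @param Q_hat fitted random-effects covariance.
#' @param scenario the generating [sim_scenario()].
#' @return one-row `data.frame` with `mse_beta`, `mse_sigma`,
#'   `mse_tau` (intercepts design) or `mse_Q` (slopes design, squared
#'   Frobenius norm), and the selection rates `TP`, `FP`, `FDR`. A covariate
#'   counts as selected iff its fitted coefficient is nonzero; `FDR = 0` when
#'   nothing is selected. Error-scale metrics are on the standard-deviation
#'   scale (`tau_hat = sqrt(Q_hat)`).
#' @export
metrics_from_estimates <- function(beta0_hat, beta_hat, sigma2_hat, Q_hat,
                                   scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  p <- scenario$p
  mse_beta <- sum((c(scenario$beta0, scenario$beta) - c(beta0_hat, beta_hat))^2)
  mse_sigma <- (scenario$sigma - sqrt(sigma2_hat))^2
  sel <- which(beta_hat != 0)
  tp_sel <- length(intersect(sel, scenario$informative))
  fp_sel <- length(setdiff(sel, scenario$informative))
  out <- data.frame(mse_beta = mse_beta, mse_sigma = mse_sigma)
  if (scenario$design == "intercepts") {
    out$mse_tau <- (scenario$tau - sqrt(Q_hat[1, 1]))^2
  } else {
    out$mse_Q <- sum((scenario$Q - Q_hat)^2)
  }
  out$TP <- tp_sel / length(scenario$informative)
  out$FP <- fp_sel / (p - length(scenario$informative))
  out$FDR <- if (tp_sel + fp_sel == 0) 0 else fp_sel / (tp_sel + fp_sel)
  out
}

#' Evaluate a boosting fit against the generating truth
#'
#' @param fit an [lbbLMM()] fit of data generated by [simulate_lmm()].
#' @param truth the generating [param_state()].
#' @param scenario the generating [sim_scenario()].
#' @return see [metrics_from_estimates()]; `m_star` is appended.
#' @export
evaluate_fit <- function(fit, truth, scenario) {
  stopifnot(inherits(fit, "lbblmm"))
  out <- metrics_from_estimates(fit$state$beta0, fit$state$beta,
                                fit$state$sigma2, fit$state$Q, scenario)
  out$m_star <- fit$m_star
  out
}

#' Run a replicated simulation study
#'
#' Generates `reps` independent replications of the scenario (replication `r`
#' uses seed `scenario$seed + r`, so any subset of replications is
#' reproducible on its own), fits the boosted mixed model to each, and
#' summarizes recovery and selection: medians with interquartile ranges for
#' the squared-error metrics, means for the selection rates. Failed
#' replications are recorded and excluded.
#'
#' @param scenario a [sim_scenario()].
#' @param reps number of replications (default 20).
#' @param control a [boost_control()] used for every fit.
#' @param progress logical; print one line per replication.
#' @return an object of class `"sim_study"`: list with `metrics` (one row per
#'   successful replication), `summary` (one row), `failures` (messages of
#'   failed replications), `scenario` and `control`.
#' @export
run_study <- function(scenario, reps = 20L, control = boost_control(),
                      progress = FALSE) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (reps < 1) lbb_config_error("reps must be >= 1")
  rows <- vector("list", reps)
  failures <- character(0)
  for (r in seq_len(reps)) {
    seed_r <- scenario$seed + r
    res <- tryCatch({
      sim <- simulate_lmm(scenario, seed = seed_r)
      fit <- lbbLMM(sim$data, control)
      cbind(rep = r, seed = seed_r, evaluate_fit(fit, sim$truth, scenario))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("rep %d (seed %d): %s", r, seed_r,
                                      conditionMessage(res)))
    } else {
      rows[[r]] <- res
    }
    if (progress) {
      cat(sprintf("rep %d/%d %s\n", r, reps,
                  if (inherits(res, "error")) "FAILED" else "done"))
    }
  }
  metrics <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(metrics) || nrow(metrics) == 0) {
    lbb_fit_error("all replications failed")
  }
  mse_cols <- grep("^mse_", names(metrics), value = TRUE)
  summ <- data.frame(design = scenario$design, tau = scenario$tau,
                     p = scenario$p, reps = reps,
                     n_failed = length(failures))
  for (cn in mse_cols) {
    summ[[paste0("median_", cn)]] <- stats::median(metrics[[cn]])
    summ[[paste0("iqr_", cn)]] <- stats::IQR(metrics[[cn]])
  }
  for (cn in c("TP", "FP", "FDR")) {
    summ[[paste0("mean_", cn)]] <- mean(metrics[[cn]])
  }
  structure(list(metrics = metrics, summary = summ, failures = failures,
                 scenario = scenario, control = control),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("Simulation study: %s design, tau = %g, p = %d, %d replication(s)\n",
              x$scenario$design, x$scenario$tau, x$scenario$p,
              x$summary$reps))
  if (x$summary$n_failed > 0) {
    cat(sprintf("  %d replication(s) failed and were excluded\n",
                x$summary$n_failed))
  }
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
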