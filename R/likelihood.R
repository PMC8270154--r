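#' Create a parameter state for the boosted linear mixed model
#'
#' Bundles the current values of the intercept, fixed effects, stacked random
#' effects, error variance and random-effects covariance. The random-effect
#' vector is stored cluster-major: `gamma = (gamma_1', ..., gamma_n')'` with
#' one length-`q` block per cluster.
#'
#' @param beta0 intercept.
#' @param beta numeric vector of fixed effects (length `p`).
#' @param gamma stacked random effects (length `n * q`, cluster-major).
#' @param sigma2 error variance, `> 0`.
#' @param Q `q` x `q` symmetric positive semi-definite random-effects
#'   covariance.
#' @return an object of class `"param_state"`.
#' @export
param_state <- function(beta0, beta, gamma, sigma2, Q) {
  Q <- as.matrix(Q)
  if (!is.numeric(sigma2) || length(sigma2) != 1 || sigma2 <= 0) {
    lbb_config_error("sigma2 must be a positive scalar")
  }
  if (nrow(Q) != ncol(Q) || max(abs(Q - t(Q))) > 1e-8 * max(1, max(abs(Q)))) {
    lbb_config_error("Q must be square and symmetric")
  }
  if (length(gamma) %% nrow(Q) != 0) {
    lbb_config_error("length(gamma) must be a multiple of nrow(Q)")
  }
  structure(list(beta0 = as.numeric(beta0), beta = as.numeric(beta),
                 gamma = as.numeric(gamma), sigma2 = as.numeric(sigma2),
                 Q = (Q + t(Q)) / 2),
            class = "param_state")
}

#' @export
print.param_state <- function(x, ...) {
  cat("Mixed-model parameter state\n")
  cat("  beta0 =", format(x$beta0, digits = 4),
      "| nonzero beta:", sum(x$beta != 0), "of", length(x$beta), "\n")
  cat("  sigma2 =", format(x$sigma2, digits = 4),
      "| q =", nrow(x$Q), "\n")
  invisible(x)
}

## gamma as a q x n matrix (columns = clusters)
gamma_matrix <- function(state, data) {
  matrix(state$gamma, nrow = data$q, ncol = data$n)
}

#' Linear predictor of a parameter state
#'
#' `eta = beta0 + X beta + Z gamma`, a pure function of the state and data.
#'
#' @param state a [param_state()].
#' @param data an [lmm_data()] object.
#' @return numeric vector of length `N` (cluster-contiguous order).
#' @export
linear_predictor <- function(state, data) {
  G <- gamma_matrix(state, data)
  eta_ran <- rowSums(data$Zrows * t(G)[data$cluster, , drop = FALSE])
  state$beta0 + drop(data$X %*% state$beta) + eta_ran
}

## Symmetric inverse of Q with a ridge fallback for near-singular Q:
## when the condition number exceeds 1e12, eps = 1e-10 * trace(Q)/q is added
## to the diagonal and a warning is logged.
safe_Q_inverse <- function(Q) {
  q <- nrow(Q)
  ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > 1e12) {
    eps <- 1e-10 * max(sum(diag(Q)) / q, .Machine$double.eps)
    warning("random-effects covariance is near-singular; ridge-regularized inverse used",
            call. = FALSE)
    Q <- Q + diag(eps, q)
  }
  chol2inv(chol(Q))
}

#' Penalized log-likelihood of the linear mixed model
#'
#' The Laplace-approximated objective: the Gaussian log-likelihood of the
#' responses conditional on the random effects, minus the quadratic penalty
#' `0.5 * sum_i gamma_i' Q^{-1} gamma_i`.
#'
#' @inheritParams linear_predictor
#' @return scalar log-likelihood value.
#' @export
penalized_loglik <- function(state, data) {
  eta <- linear_predictor(state, data)
  ll_obs <- stats::dnorm(data$y, mean = eta, sd = sqrt(state$sigma2), log = TRUE)
  Qinv <- safe_Q_inverse(state$Q)
  G <- gamma_matrix(state, data)
  pen_i <- colSums(G * (Qinv %*% G))
  if (!all(is.finite(ll_obs)) || !all(is.finite(pen_i))) {
    bad_ll <- rowsum(as.numeric(!is.finite(ll_obs)), data$cluster)
    bad <- which(bad_ll > 0 | !is.finite(pen_i))[1]
    lbb_numeric_error(paste0("non-finite penalized log-likelihood in cluster ", bad),
                      cluster = bad)
  }
  sum(ll_obs) - 0.5 * sum(pen_i)
}

#' Marginal log-likelihood of the linear mixed model
#'
#' Random effects integrated out: each cluster contributes a Gaussian
#' log-density with mean `beta0 + X_i beta` and covariance
#' `V_i = Z_i Q Z_i' + sigma2 I`. The value does not depend on `gamma`.
#'
#' @inheritParams linear_predictor
#' @return scalar log-likelihood value.
#' @export
marginal_loglik <- function(state, data) {
  mu <- state$beta0 + drop(data$X %*% state$beta)
  r <- data$y - mu
  total <- 0
  for (i in seq_len(data$n)) {
    idx <- cluster_rows(data, i)
    Zi <- data$Zrows[idx, , drop = FALSE]
    Vi <- tcrossprod(Zi %*% state$Q, Zi) + diag(state$sigma2, length(idx))
    L <- tryCatch(chol(Vi), error = function(e) NULL)
    if (is.null(L)) {
      lbb_numeric_error(paste0("singular marginal covariance in cluster ", i),
                        cluster = i)
    }
    w <- backsolve(L, r[idx], transpose = TRUE)
    total <- total - 0.5 * (length(idx) * log(2 * pi) +
                              2 * sum(log(diag(L))) + sum(w^2))
  }
  total
}

## conditional log-likelihood (no penalty): used by the optional conditional
## information-criterion variant
conditional_loglik <- function(state, data) {
  eta <- linear_predictor(state, data)
  sum(stats::dnorm(data$y, mean = eta, sd = sqrt(state$sigma2), log = TRUE))
}

#' Model complexity of a parameter state
#'
#' `df = #phi + #\{i <= p : beta_i != 0\}` where `#phi = 1 + q(q+1)/2` counts
#' the error variance plus the unique elements of the random-effects
#' covariance. The intercept is not counted.
#'
#' @inheritParams linear_predictor
#' @return integer degrees of freedom.
#' @export
model_df <- function(state, data) {
  q <- data$q
  as.integer(1 + q * (q + 1) / 2 + sum(state$beta != 0))
}

#' Information criterion of a parameter state
#'
#' `-2 * loglik + penalty * df` with penalty 2 (AIC) or `log(n)` (BIC), where
#' `n` is the number of clusters. By default the closed-form marginal Gaussian
#' log-likelihood is used, which is free of the random effects and keeps the
#' component comparison of the boosting selection step fair; a conditional
#' variant (Gaussian likelihood given the current random effects) is available
#' for sensitivity analysis.
#'
#' @inheritParams linear_predictor
#' @param kind `"AIC"` or `"BIC"`.
#' @param conditional logical; evaluate the likelihood conditionally on the
#'   current random effects instead of marginally (default `FALSE`).
#' @return an object of class `"ic_value"`: list with `kind`, `value`, `df`
#'   and `loglik`.
#' @export
information_criterion <- function(state, data, kind = c("BIC", "AIC"),
                                  conditional = FALSE) {
  kind <- match.arg(kind)
  ll <- if (conditional) conditional_loglik(state, data) else marginal_loglik(state, data)
  df <- model_df(state, data)
  pen <- if (kind == "AIC") 2 else log(data$n)
  structure(list(kind = kind, value = -2 * ll + pen * df, df = df, loglik = ll),
            class = "ic_value")
}

#' @export
print.ic_value <- function(x, ...) {
  cat(sprintf("%s = %.4f (df = %d, loglik = %.4f)\n",
              x$kind, x$value, x$df, x$loglik))
  invisible(x)
}
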