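#' Control parameters for the boosting fit
#'
#' @param mstop maximum number of boosting iterations (default 1500).
#' @param nu step length in `(0, 1]` applied to every fixed- and
#'   random-effects update (default 0.1). Small values keep each update weak,
#'   which is what gives every candidate covariate a fair chance of selection
#'   and prevents both fixed and random effects from growing too quickly.
#' @param criterion `"BIC"` (default) or `"AIC"`; used both to pick the
#'   updated component within an iteration and to choose the stopping
#'   iteration.
#' @param start `"simple"` (default: intercept = mean response, error
#'   variance = response variance, zero fixed and random effects, small
#'   random-effects covariance `0.1 I`) or `"premodel"` (intercept, random
#'   effects and variance components taken from an internal fit of the
#'   intercept-plus-random-effects model).
#' @param conditional_ic logical; evaluate information criteria with the
#'   likelihood conditional on the current random effects instead of the
#'   marginal likelihood (default `FALSE`; sensitivity analysis only).
#' @param center_intercept logical; see [build_correction()].
#' @param trace logical; print one line per iteration (iteration, selected
#'   covariate, criterion value).
#' @return an object of class `"boost_control"`.
#' @export
boost_control <- function(mstop = 1500L, nu = 0.1,
                          criterion = c("BIC", "AIC"),
                          start = c("simple", "premodel"),
                          conditional_ic = FALSE, center_intercept = TRUE,
                          trace = FALSE) {
  criterion <- match.arg(criterion)
  start <- match.arg(start)
  if (!is.numeric(nu) || length(nu) != 1 || nu <= 0 || nu > 1) {
    lbb_config_error("nu must lie in (0, 1]")
  }
  mstop <- as.integer(mstop)
  if (is.na(mstop) || mstop < 1L) lbb_config_error("mstop must be >= 1")
  structure(list(mstop = mstop, nu = nu, criterion = criterion, start = start,
                 conditional_ic = isTRUE(conditional_ic),
                 center_intercept = isTRUE(center_intercept),
                 trace = isTRUE(trace)),
            class = "boost_control")
}

#' Starting values for the boosting fit
#'
#' The parameters under selection start at zero: `beta = 0`. In `"simple"`
#' mode the intercept starts at the response mean, the error variance at the
#' response variance, the random effects at zero and their covariance at the
#' small matrix `0.1 I`. In `"premodel"` mode the intercept, random effects
#' and variance components are taken from an internal EM fit of the
#' intercept-plus-random-effects model `y = beta0 + Z gamma + eps`.
#'
#' @param data an [lmm_data()] object.
#' @param control a [boost_control()].
#' @return a [param_state()].
#' @export
initialize_state <- function(data, control = boost_control()) {
  v <- stats::var(data$y)
  if (!is.finite(v) || v <= 0) lbb_data_error("zero-variance response")
  st <- param_state(beta0 = mean(data$y), beta = numeric(data$p),
                    gamma = numeric(data$n * data$q), sigma2 = v,
                    Q = diag(0.1, data$q))
  if (control$start == "premodel") st <- premodel_start(data, st)
  st
}

## EM fit of y = beta0 + Z gamma + eps, used only for start = "premodel"
premodel_start <- function(data, st, maxit = 200L, tol = 1e-8) {
  q <- data$q
  ZtZ <- lapply(seq_len(data$n), function(i) crossprod(z_block(data, i)))
  for (it in seq_len(maxit)) {
    old <- c(st$beta0, st$sigma2, st$Q)
    Qinv <- safe_Q_inverse(st$Q)
    G <- matrix(0, q, data$n)
    Finv_sum <- matrix(0, q, q)
    for (i in seq_len(data$n)) {
      idx <- cluster_rows(data, i)
      Fi <- ZtZ[[i]] / st$sigma2 + Qinv
      Fiinv <- chol2inv(chol(Fi))
      G[, i] <- Fiinv %*% (crossprod(z_block(data, i),
                                     data$y[idx] - st$beta0) / st$sigma2)
      Finv_sum <- Finv_sum + Fiinv
    }
    eta_ran <- rowSums(data$Zrows * t(G)[data$cluster, , drop = FALSE])
    beta0 <- mean(data$y - eta_ran)
    Qhat <- make_psd(Finv_sum / data$n + tcrossprod(G) / data$n)
    sigma2 <- stats::var(data$y - beta0 - eta_ran)
    st <- param_state(beta0, st$beta, as.vector(G), sigma2, Qhat)
    if (max(abs(c(st$beta0, st$sigma2, st$Q) - old)) < tol) break
  }
  st
}

## symmetrize and eigen-clip to the PSD cone; the EM update is PSD in exact
## arithmetic, clipping only guards floating-point drift
make_psd <- function(Q, warn_tol = 1e-8) {
  Q <- (Q + t(Q)) / 2
  ev <- eigen(Q, symmetric = TRUE)
  if (min(ev$values) < 0) {
    if (min(ev$values) < -warn_tol) {
      warning("random-effects covariance update clipped to the PSD cone (",
              format(min(ev$values), digits = 3), ")", call. = FALSE)
    }
    Q <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
    Q <- (Q + t(Q)) / 2
  }
  Q
}

#' Fisher-scoring update for one fixed-effect candidate
#'
#' Computes the joint intercept/effect update `u = F_r^{-1} s_r` for the
#' `r`-th covariate from the penalized-likelihood score and Fisher matrix.
#' Because the error variance cancels in `F_r^{-1} s_r`, `u` equals the
#' least-squares regression of the current residual `y - eta` on `(1, x_r)`.
#' The candidate's information criterion is that of the state with
#' `beta0 + nu u_0` and `beta_r + nu u_r` applied.
#'
#' @param r candidate index in `1..p`.
#' @param state the current [param_state()].
#' @param data an [lmm_data()] object.
#' @param control a [boost_control()] (supplies `nu` and the criterion).
#' @return a list of class `"candidate_update"` with elements `r`,
#'   `u` (length 2: intercept and effect update), `ic` (an `"ic_value"`),
#'   `state` (the hypothetically updated state) and `admissible`.
#' @export
candidate_update <- function(r, state, data, control = boost_control()) {
  if (r < 1 || r > data$p) lbb_config_error("candidate index out of range")
  res <- data$y - linear_predictor(state, data)
  Xt <- cbind(1, data$X[, r])
  Gm <- crossprod(Xt)
  if (Gm[1, 1] * Gm[2, 2] - Gm[1, 2]^2 <=
      1e-12 * Gm[1, 1] * max(Gm[2, 2], .Machine$double.eps)) {
    warning("candidate ", data$covariate_names[r],
            " is collinear with the intercept; skipped", call. = FALSE)
    return(structure(list(r = r, u = c(0, 0), ic = NULL, state = state,
                          admissible = FALSE), class = "candidate_update"))
  }
  u <- drop(solve(Gm, crossprod(Xt, res)))
  new_state <- state
  new_state$beta0 <- state$beta0 + control$nu * u[1]
  new_state$beta[r] <- state$beta[r] + control$nu * u[2]
  ic <- information_criterion(new_state, data, control$criterion,
                              conditional = control$conditional_ic)
  structure(list(r = r, u = u, ic = ic, state = new_state, admissible = TRUE),
            class = "candidate_update")
}

#' Select and apply the best fixed-effect update
#'
#' Evaluates all `p` candidate updates and applies the one minimizing the
#' information criterion; only the intercept and the selected coordinate
#' change. Ties are broken deterministically towards the lowest index.
#'
#' @inheritParams candidate_update
#' @return list with `state` (updated) and `selected` (the chosen index).
#' @export
select_and_apply <- function(state, data, control = boost_control()) {
  cands <- lapply(seq_len(data$p), candidate_update,
                  state = state, data = data, control = control)
  ic <- vapply(cands, function(cu) {
    if (cu$admissible) cu$ic$value else Inf
  }, numeric(1))
  if (!any(is.finite(ic))) lbb_fit_error("no admissible candidate update")
  star <- which.min(ic)
  list(state = cands[[star]]$state, selected = star, ic = ic)
}

#' Weak corrected Fisher-scoring update of the random effects
#'
#' One Fisher step on the penalized log-likelihood for the stacked random
#' effects, exploiting the block-diagonal Fisher matrix
#' `F_i = sigma^{-2} Z_i' Z_i + Q^{-1}` (one small solve per cluster), then
#' corrected with [apply_correction()] and scaled by the step length:
#' `gamma <- gamma + nu * C F^{-1} s`.
#'
#' @inheritParams candidate_update
#' @param op a [build_correction()] operator.
#' @param nu step length.
#' @return the updated [param_state()].
#' @export
random_effects_step <- function(state, data, op, nu = 0.1) {
  Qinv <- safe_Q_inverse(state$Q)
  res <- data$y - linear_predictor(state, data)
  G <- gamma_matrix(state, data)
  delta <- matrix(0, data$q, data$n)
  for (i in seq_len(data$n)) {
    idx <- cluster_rows(data, i)
    Zi <- z_block(data, i)
    Fi <- crossprod(Zi) / state$sigma2 + Qinv
    si <- crossprod(Zi, res[idx]) / state$sigma2 - Qinv %*% G[, i]
    di <- tryCatch(solve(Fi, si), error = function(e) NULL)
    if (is.null(di)) {
      lbb_numeric_error(paste0("singular random-effects Fisher block in cluster ", i),
                        cluster = i)
    }
    delta[, i] <- di
  }
  state$gamma <- state$gamma + nu * apply_correction(op, as.vector(delta))
  state
}

#' Approximate EM update of the variance components
#'
#' Refreshes the random-effects covariance with the posterior-curvature EM
#' expression `Q <- (1/n) sum_i (F_i^{-1} + gamma_i gamma_i')` (then
#' symmetrized and projected onto the PSD cone) and the error variance with
#' the sample variance of the current residuals `y - eta`.
#'
#' @inheritParams candidate_update
#' @return the updated [param_state()].
#' @export
update_variance_components <- function(state, data) {
  Qinv <- safe_Q_inverse(state$Q)
  G <- gamma_matrix(state, data)
  Finv_sum <- matrix(0, data$q, data$q)
  for (i in seq_len(data$n)) {
    Fi <- crossprod(z_block(data, i)) / state$sigma2 + Qinv
    Finv_sum <- Finv_sum + chol2inv(chol(Fi))
  }
  state$Q <- make_psd(Finv_sum / data$n + tcrossprod(G) / data$n)
  state$sigma2 <- stats::var(data$y - linear_predictor(state, data))
  state
}

## ---------------------------------------------------------------------------
## Fast fit loop. Mathematically identical to composing the exported step
## functions (a property the test suite asserts); avoids re-factorizing the
## cluster covariances V_i across the p candidate evaluations of an iteration,
## since (sigma2, Q) are constant within the selection step.

## per-iteration V-dependent quantities
vstuff <- function(Q, sigma2, pre, conditional = FALSE) {
  Qinv <- safe_Q_inverse(Q)
  out <- list(Qinv = Qinv, conditional = conditional, sigma2 = sigma2)
  q <- nrow(Q)
  if (conditional) {
    out$logdet <- pre$N * log(sigma2)
  } else if (pre$shared) {
    Zi <- pre$first_block
    Vi <- tcrossprod(Zi %*% Q, Zi) + diag(sigma2, nrow(Zi))
    L <- tryCatch(chol(Vi), error = function(e)
      lbb_numeric_error("singular marginal covariance"))
    out$W <- chol2inv(L)
    out$logdet <- pre$n * 2 * sum(log(diag(L)))
  } else {
    out$W <- vector("list", pre$n)
    logdet <- 0
    for (i in seq_len(pre$n)) {
      Zi <- pre$Zb[[i]]
      Vi <- tcrossprod(Zi %*% Q, Zi) + diag(sigma2, nrow(Zi))
      L <- tryCatch(chol(Vi), error = function(e)
        lbb_numeric_error(paste0("singular marginal covariance in cluster ", i),
                          cluster = i))
      out$W[[i]] <- chol2inv(L)
      logdet <- logdet + 2 * sum(log(diag(L)))
    }
    out$logdet <- logdet
  }
  ## posterior curvature blocks F_i = ZtZ_i / sigma2 + Qinv
  if (q == 1L) {
    out$finv_vec <- 1 / (pre$ZtZ_vec / sigma2 + Qinv[1, 1])
    out$meanFinv <- matrix(mean(out$finv_vec), 1, 1)
  } else if (pre$shared) {
    Fi <- pre$ZtZ[[1]] / sigma2 + Qinv
    out$Finv_shared <- chol2inv(chol(Fi))
    out$meanFinv <- out$Finv_shared
  } else {
    out$Finv <- vector("list", pre$n)
    acc <- matrix(0, q, q)
    for (i in seq_len(pre$n)) {
      Fi <- pre$ZtZ[[i]] / sigma2 + Qinv
      Fiinv <- tryCatch(chol2inv(chol(Fi)), error = function(e)
        lbb_numeric_error(paste0("singular random-effects Fisher block in cluster ", i),
                          cluster = i))
      out$Finv[[i]] <- Fiinv
      acc <- acc + Fiinv
    }
    out$meanFinv <- acc / pre$n
  }
  out
}

## apply V^{-1} blockwise to a matrix/vector with N rows
vinv_apply <- function(vs, pre, A) {
  if (vs$conditional) return(A / vs$sigma2)
  if (pre$shared) {
    A <- as.matrix(A)
    k <- ncol(A)
    M <- vs$W %*% matrix(A, nrow = pre$ni)
    return(matrix(M, nrow = pre$N, ncol = k))
  }
  A <- as.matrix(A)
  M <- A
  for (i in seq_len(pre$n)) {
    idx <- pre$idx[[i]]
    M[idx, ] <- vs$W[[i]] %*% A[idx, , drop = FALSE]
  }
  M
}

lbblmm_engine <- function(data, control, op) {
  y <- data$y; X <- data$X; N <- data$N; n <- data$n
  p <- data$p; q <- data$q; cl <- data$cluster
  nu <- control$nu; mstop <- control$mstop
  pen <- if (control$criterion == "AIC") 2 else log(n)
  conditional <- control$conditional_ic

  ## structural precomputations (iteration-invariant)
  idx <- lapply(seq_len(n), function(i) cluster_rows(data, i))
  Zb <- lapply(seq_len(n), function(i) z_block(data, i))
  ZtZ <- lapply(Zb, crossprod)
  ni <- data$cluster_sizes[1]
  shared <- all(data$cluster_sizes == ni) &&
    all(data$Zrows == Zb[[1]][rep(seq_len(ni), n), , drop = FALSE])
  pre <- list(n = n, N = N, ni = ni, idx = idx, Zb = Zb, ZtZ = ZtZ,
              shared = shared, first_block = Zb[[1]],
              ZtZ_vec = if (q == 1L) vapply(ZtZ, function(m) m[1, 1], numeric(1)))

  ## 2x2 candidate Gram inverses (X is iteration-invariant)
  sx <- colSums(X); sxx <- colSums(X^2)
  det_r <- N * sxx - sx^2
  admissible <- det_r > 1e-12 * N * pmax(sxx, .Machine$double.eps)
  if (!all(admissible)) {
    warning("candidate(s) collinear with the intercept skipped: ",
            paste(data$covariate_names[!admissible], collapse = ", "),
            call. = FALSE)
  }
  if (!any(admissible)) lbb_fit_error("no admissible candidate update")
  dfphi <- 1 + q * (q + 1) / 2
  logdet_const <- N * log(2 * pi)

  st <- initialize_state(data, control)
  beta0 <- st$beta0; beta <- st$beta
  G <- matrix(st$gamma, q, n)
  sigma2 <- st$sigma2; Q <- st$Q
  vs <- vstuff(Q, sigma2, pre, conditional)

  paths <- list(beta0 = numeric(mstop), beta = matrix(0, mstop, p),
                sigma2 = numeric(mstop),
                Q = matrix(0, mstop, q * (q + 1) / 2),
                gamma = matrix(0, mstop, n * q),
                ic = numeric(mstop), df = integer(mstop),
                selected = integer(mstop))
  colnames(paths$beta) <- data$covariate_names
  lt <- lower.tri(Q, diag = TRUE)
  psd_warned <- FALSE
  truncated <- FALSE
  m_done <- 0L

  for (m in seq_len(mstop)) {
    eta_fix <- beta0 + drop(X %*% beta)
    eta_ran <- rowSums(data$Zrows * t(G)[cl, , drop = FALSE])
    res_m <- y - eta_fix          # marginal residual (mean part only)
    res_p <- res_m - eta_ran      # penalized residual (current fit eta)

    ## --- step 1: component-wise fixed-effects update -----------------------
    s0 <- sum(res_p)
    sr <- drop(crossprod(X, res_p))
    u0 <- (sxx * s0 - sx * sr) / det_r
    ur <- (N * sr - sx * s0) / det_r

    res_base <- if (conditional) res_p else res_m
    A <- vinv_apply(vs, pre, cbind(1, X))
    mres <- drop(vinv_apply(vs, pre, res_base))
    Q11 <- sum(A[, 1])
    B1x <- drop(crossprod(X, A[, 1]))
    Qxx <- colSums(X * A[, -1, drop = FALSE])
    q1r <- sum(mres)
    qxr <- drop(crossprod(X, mres))
    Qrr <- sum(res_base * mres)
    quad <- Qrr - 2 * nu * (u0 * q1r + ur * qxr) +
      nu^2 * (u0^2 * Q11 + 2 * u0 * ur * B1x + ur^2 * Qxx)
    df_cand <- dfphi + sum(beta != 0) + (beta == 0 & ur != 0)
    ic_cand <- vs$logdet + logdet_const + quad + pen * df_cand
    ic_cand[!admissible] <- Inf
    star <- which.min(ic_cand)   # ties -> lowest index

    beta0 <- beta0 + nu * u0[star]
    beta[star] <- beta[star] + nu * ur[star]
    shift <- nu * (u0[star] + ur[star] * X[, star])
    res_m <- res_m - shift
    res_p <- res_p - shift

    ## --- step 2: weak corrected random-effects update ----------------------
    ZtR <- rowsum(data$Zrows * res_p, cl)          # n x q
    Sran <- t(ZtR) / sigma2 - vs$Qinv %*% G        # q x n score blocks
    if (q == 1L) {
      delta <- vs$finv_vec * Sran
      dim(delta) <- c(1L, n)
    } else if (shared) {
      delta <- vs$Finv_shared %*% Sran
    } else {
      delta <- matrix(0, q, n)
      for (i in seq_len(n)) delta[, i] <- vs$Finv[[i]] %*% Sran[, i]
    }
    for (s in seq_len(q)) {
      B <- op$effects[[s]]$basis
      if (ncol(B)) delta[s, ] <- delta[s, ] - drop(B %*% crossprod(B, delta[s, ]))
    }
    G <- G + nu * delta
    eta_ran <- rowSums(data$Zrows * t(G)[cl, , drop = FALSE])
    res_p <- res_m - eta_ran

    ## --- step 3: approximate EM variance-component updates ------------------
    Qhat <- vs$meanFinv + tcrossprod(G) / n
    Qhat <- (Qhat + t(Qhat)) / 2
    ev_min <- min(eigen(Qhat, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < 0) {
      if (ev_min < -1e-8 && !psd_warned) {
        warning("random-effects covariance update clipped to the PSD cone",
                call. = FALSE)
        psd_warned <- TRUE
      }
      Qhat <- make_psd(Qhat, warn_tol = Inf)
    }
    Q <- Qhat
    sigma2 <- stats::var(res_p)
    if (!is.finite(sigma2) || sigma2 <= 0 || !all(is.finite(Q))) {
      truncated <- TRUE
      warning("numeric failure at iteration ", m, "; path truncated",
              call. = FALSE)
      break
    }
    vs <- vstuff(Q, sigma2, pre, conditional)

    ## information criterion of the completed iteration (stopping path)
    res_base <- if (conditional) res_p else res_m
    quad_now <- sum(res_base * vinv_apply(vs, pre, res_base))
    ic_now <- vs$logdet + logdet_const + quad_now + pen * (dfphi + sum(beta != 0))

    paths$beta0[m] <- beta0
    paths$beta[m, ] <- beta
    paths$sigma2[m] <- sigma2
    paths$Q[m, ] <- Q[lt]
    paths$gamma[m, ] <- as.vector(G)
    paths$ic[m] <- ic_now
    paths$df[m] <- dfphi + sum(beta != 0)
    paths$selected[m] <- star
    m_done <- m
    if (control$trace) {
      cat(sprintf("iter %4d  selected %-12s  %s = %.4f\n", m,
                  data$covariate_names[star], control$criterion, ic_now))
    }
    if (!is.finite(ic_now)) {
      truncated <- TRUE
      warning("non-finite information criterion at iteration ", m,
              "; path truncated", call. = FALSE)
      break
    }
  }

  if (m_done < mstop) {
    paths <- lapply(paths, function(x) {
      if (is.matrix(x)) x[seq_len(m_done), , drop = FALSE] else x[seq_len(m_done)]
    })
  }
  list(paths = paths, truncated = truncated, m_done = m_done)
}

#' Fit a linear mixed model by corrected likelihood-based boosting
#'
#' Runs the component-wise boosting loop: per iteration (1) a Fisher-scoring
#' update of the single fixed-effect candidate minimizing the information
#' criterion, (2) a weak random-effects update corrected for cluster-constant
#' covariates, and (3) an approximate EM refresh of the variance components.
#' The fit is returned at the criterion-optimal stopping iteration `m*`
#' together with the full coefficient, variance and criterion paths.
#' The algorithm is deterministic: refitting the same data with the same
#' control reproduces the identical path.
#'
#' @param data an [lmm_data()] object.
#' @param control a [boost_control()].
#' @param classification a [classify_covariates()] result; computed when
#'   omitted.
#' @return An object of class `"lbblmm"` with components `paths` (per
#'   iteration: intercept, fixed effects, error variance, vech of the
#'   random-effects covariance, stacked random effects, information
#'   criterion, model df, selected candidate), `m_star`, `state` (the
#'   [param_state()] at `m_star`), `coefficients`, `correction`,
#'   `classification`, `control`, `understopped` and `truncated` flags.
#' @examples
#' sc <- sim_scenario("intercepts", n = 20, n_i = 4, p = 5, seed = 7)
#' sim <- simulate_lmm(sc)
#' fit <- lbbLMM(sim$data, boost_control(mstop = 150))
#' coef(fit)
#' @export
lbbLMM <- function(data, control = boost_control(),
                   classification = classify_covariates(data)) {
  stopifnot(inherits(data, "lmm_data"), inherits(control, "boost_control"))
  op <- build_correction(data, classification, control$center_intercept)
  eng <- lbblmm_engine(data, control, op)
  paths <- eng$paths
  if (eng$m_done < 1L) lbb_fit_error("boosting failed before the first iteration")
  m_star <- which.min(paths$ic)
  understopped <- !eng$truncated && m_star == control$mstop
  if (understopped) {
    warning("criterion still decreasing at mstop; consider raising mstop",
            call. = FALSE)
  }
  q <- data$q
  Qm <- matrix(0, q, q)
  Qm[lower.tri(Qm, diag = TRUE)] <- paths$Q[m_star, ]
  Qm <- Qm + t(Qm) - diag(diag(Qm), q)
  state <- param_state(paths$beta0[m_star], paths$beta[m_star, ],
                       paths$gamma[m_star, ], paths$sigma2[m_star], Qm)
  coefs <- c(paths$beta0[m_star], paths$beta[m_star, ])
  names(coefs) <- c("(Intercept)", data$covariate_names)
  structure(list(data = data, control = control,
                 classification = classification, correction = op,
                 paths = paths, m_star = m_star, state = state,
                 coefficients = coefs, understopped = understopped,
                 truncated = eng$truncated),
            class = "lbblmm")
}
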