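## Shared fixtures and independent oracles for the test suite.
## Oracles are deliberately naive (dense matrices, observation-wise sums)
## and never share code with the implementation paths they check.

## small clustered table with one cluster-constant covariate ("g")
toy_table <- function(n = 4, n_i = 3, p = 3, seed = 1) {
  set.seed(seed)
  cl <- rep(seq_len(n), each = n_i)
  X <- matrix(rnorm(n * n_i * p), n * n_i, p)
  colnames(X) <- paste0("x", seq_len(p))
  g <- rep(sample(rep_len(c(-1, 1), n)), each = n_i)  # both levels guaranteed
  y <- 1 + X[, 1] + 0.5 * g + rep(rnorm(n, 0, 0.5), each = n_i) +
    rnorm(n * n_i, 0, 0.3)
  data.frame(id = cl, y = y, X, g = g, check.names = FALSE)
}

toy_data <- function(n = 4, n_i = 3, p = 3, seed = 1, slopes = character()) {
  tab <- toy_table(n, n_i, p, seed)
  lmm_data(tab, "y", "id", fixed = c(paste0("x", seq_len(p)), "g"),
           random_slopes = slopes, random_intercept = TRUE)
}

## random parameter state for a data set
random_state <- function(data, seed = 1, gamma_scale = 1) {
  set.seed(seed)
  A <- matrix(rnorm(data$q^2), data$q)
  param_state(beta0 = rnorm(1), beta = rnorm(data$p),
              gamma = gamma_scale * rnorm(data$n * data$q),
              sigma2 = runif(1, 0.5, 2),
              Q = crossprod(A) + diag(0.1, data$q))
}

## observation-wise penalized log-likelihood: scalar normal densities summed
## one by one plus the quadratic penalty via an explicit inverse
brute_penalized_loglik <- function(state, data) {
  eta <- state$beta0 + drop(data$X %*% state$beta)
  G <- matrix(state$gamma, data$q, data$n)
  total <- 0
  for (k in seq_len(data$N)) {
    i <- data$cluster[k]
    mu <- eta[k] + sum(data$Zrows[k, ] * G[, i])
    total <- total + dnorm(data$y[k], mu, sqrt(state$sigma2), log = TRUE)
  }
  Qinv <- solve(state$Q)
  for (i in seq_len(data$n)) {
    total <- total - 0.5 * drop(t(G[, i]) %*% Qinv %*% G[, i])
  }
  total
}

## dense multivariate-normal marginal log-likelihood (log-det + solve)
brute_marginal_loglik <- function(state, data) {
  mu <- state$beta0 + drop(data$X %*% state$beta)
  total <- 0
  for (i in seq_len(data$n)) {
    idx <- which(data$cluster == i)
    Zi <- data$Zrows[idx, , drop = FALSE]
    Vi <- Zi %*% state$Q %*% t(Zi) + state$sigma2 * diag(length(idx))
    r <- data$y[idx] - mu[idx]
    total <- total - 0.5 * (length(idx) * log(2 * pi) +
                              as.numeric(determinant(Vi)$modulus) +
                              drop(t(r) %*% solve(Vi) %*% r))
  }
  drop(total)
}

## the full nq x nq correction matrix P^{-1} (I - Ctilde) P built explicitly,
## with hat matrices from the normal equations
dense_correction_matrix <- function(op) {
  n <- op$n; q <- op$q
  P <- matrix(0, n * q, n * q)
  for (i in seq_len(n)) for (s in seq_len(q)) {
    P[(s - 1) * n + i, (i - 1) * q + s] <- 1   # effect-major <- cluster-major
  }
  Ct <- matrix(0, n * q, n * q)
  for (s in seq_len(q)) {
    Xc <- op$effects[[s]]$Xc
    Cs <- if (ncol(Xc)) Xc %*% solve(t(Xc) %*% Xc) %*% t(Xc) else matrix(0, n, n)
    Ct[(s - 1) * n + seq_len(n), (s - 1) * n + seq_len(n)] <- Cs
  }
  t(P) %*% (diag(n * q) - Ct) %*% P
}

## GLS coefficients for design [1 | X] at fixed variance components
gls_coef <- function(data, sigma2, Q) {
  Xt <- cbind(1, data$X)
  A <- matrix(0, ncol(Xt), ncol(Xt))
  b <- numeric(ncol(Xt))
  for (i in seq_len(data$n)) {
    idx <- which(data$cluster == i)
    Zi <- data$Zrows[idx, , drop = FALSE]
    Vinv <- solve(Zi %*% Q %*% t(Zi) + sigma2 * diag(length(idx)))
    A <- A + t(Xt[idx, , drop = FALSE]) %*% Vinv %*% Xt[idx, , drop = FALSE]
    b <- b + t(Xt[idx, , drop = FALSE]) %*% Vinv %*% data$y[idx]
  }
  drop(solve(A, b))
}

## orthogonality of the stacked random effects to every effect's correction
## covariates: max over effects of max |Xcs' gamma_s|
max_correction_violation <- function(op, gamma) {
  G <- matrix(gamma, op$q, op$n)
  worst <- 0
  for (s in seq_len(op$q)) {
    Xc <- op$effects[[s]]$Xc
    if (ncol(Xc)) worst <- max(worst, max(abs(t(Xc) %*% G[s, ])))
  }
  worst
}
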