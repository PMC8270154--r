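#' Build the random-effects correction operator
#'
#' For each random effect `s` the operator holds the orthogonal projector
#' `I_n - C_s` onto the complement of the span of that effect's correction
#' covariates `X_cs` (one representative row per cluster), where
#' `C_s = X_cs (X_cs' X_cs)^{-1} X_cs'` is the hat matrix. For the random
#' intercept `X_cs` contains a column of ones (optional, on by default) and
#' all cluster-constant covariates; for every random slope `X_cs` is a single
#' ones column, i.e. the slope coefficients are centered. Applying the
#' operator to a random-effects update removes exactly the directions that a
#' cluster-constant covariate could otherwise absorb, keeping random-effect
#' estimates empirically uncorrelated with those covariates.
#'
#' @param data an [lmm_data()] object.
#' @param classification a [classify_covariates()] result for `data`;
#'   computed when omitted.
#' @param center_intercept logical; include a ones column in the intercept's
#'   correction covariates in addition to the cluster-constant covariates
#'   (default `TRUE`). Centering the intercept keeps the global intercept
#'   identifiable.
#' @return An object of class `"correction_operator"`: per effect the
#'   correction covariates `Xc`, an orthonormal `basis` of their column space
#'   and the `n` x `n` `projector` `I_n - C_s`; plus the layout (`n`, `q`,
#'   effect names). The cluster-major to effect-major permutation is applied
#'   implicitly by [apply_correction()].
#' @export
build_correction <- function(data, classification = classify_covariates(data),
                             center_intercept = TRUE) {
  stopifnot(inherits(data, "lmm_data"))
  n <- data$n
  if (data$q < 1) lbb_config_error("no random effects to correct")
  effects <- vector("list", data$q)
  names(effects) <- data$random_effect_spec
  for (s in seq_len(data$q)) {
    if (data$random_intercept && s == 1L) {
      Xc <- classification$representatives
      if (center_intercept) Xc <- cbind(`(ones)` = rep(1, n), Xc)
    } else {
      Xc <- matrix(1, n, 1, dimnames = list(NULL, "(ones)"))
    }
    if (ncol(Xc) >= n) {
      lbb_config_error(paste0("more correction covariates than clusters for effect ",
                              data$random_effect_spec[s]))
    }
    if (ncol(Xc) > 0) {
      ## rank-revealing decomposition: project onto the space actually spanned
      qr_xc <- qr(Xc)
      rank <- qr_xc$rank
      if (rank < ncol(Xc)) {
        dropped <- colnames(Xc)[qr_xc$pivot[seq.int(rank + 1L, ncol(Xc))]]
        warning("rank-deficient correction covariates for effect ",
                data$random_effect_spec[s], "; dropped direction(s): ",
                paste(dropped, collapse = ", "), call. = FALSE)
      }
      basis <- qr.Q(qr_xc)[, seq_len(rank), drop = FALSE]
    } else {
      basis <- matrix(0, n, 0)
    }
    effects[[s]] <- list(Xc = Xc, basis = basis,
                         projector = diag(n) - tcrossprod(basis))
  }
  structure(list(effects = effects, n = n, q = data$q,
                 re_names = data$random_effect_spec),
            class = "correction_operator")
}

#' @export
print.correction_operator <- function(x, ...) {
  cat("Random-effects correction operator\n")
  for (s in seq_len(x$q)) {
    cat(sprintf("  %s: %d correction covariate(s), rank %d (n = %d clusters)\n",
                x$re_names[s], ncol(x$effects[[s]]$Xc),
                ncol(x$effects[[s]]$basis), x$n))
  }
  invisible(x)
}

#' Apply the correction operator to a stacked random-effects vector
#'
#' Computes `P^{-1} (I - diag(C_1, ..., C_q)) P delta` where `P` permutes the
#' cluster-major stacking `(gamma_1', ..., gamma_n')'` into the effect-major
#' stacking. Implemented effect-wise with two skinny matrix products per
#' effect; the `nq` x `nq` matrix is never materialized.
#'
#' @param op a [build_correction()] operator.
#' @param delta numeric vector of length `n * q`, cluster-major.
#' @return the corrected vector, same length and stacking.
#' @export
apply_correction <- function(op, delta) {
  if (length(delta) != op$n * op$q) {
    lbb_config_error("delta must have length n * q")
  }
  G <- matrix(delta, nrow = op$q, ncol = op$n)  # row s = effect-major block
  for (s in seq_len(op$q)) {
    B <- op$effects[[s]]$basis
    if (ncol(B)) G[s, ] <- G[s, ] - drop(B %*% crossprod(B, G[s, ]))
  }
  as.vector(G)
}
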