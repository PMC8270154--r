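#' @export
print.lbblmm <- function(x, ...) {
  cat("Likelihood-based boosting fit for a linear mixed model\n")
  cat(sprintf("  %s stopping at m* = %d of %d iterations%s\n",
              x$control$criterion, x$m_star, x$control$mstop,
              if (x$understopped) " (criterion still decreasing)" else ""))
  sel <- names(x$coefficients[-1])[x$coefficients[-1] != 0]
  cat(sprintf("  selected covariates (%d of %d): %s\n", length(sel),
              x$data$p, if (length(sel)) paste(sel, collapse = ", ") else "(none)"))
  cat(sprintf("  sigma2 = %.4f; random effects: %s\n", x$state$sigma2,
              paste(x$data$random_effect_spec, collapse = ", ")))
  invisible(x)
}

#' @export
coef.lbblmm <- function(object, ...) object$coefficients

#' @export
fitted.lbblmm <- function(object, original_order = TRUE, ...) {
  eta <- linear_predictor(object$state, object$data)
  if (original_order) eta[order(object$data$orig_order)] else eta
}

#' @export
residuals.lbblmm <- function(object, original_order = TRUE, ...) {
  r <- object$data$y - linear_predictor(object$state, object$data)
  if (original_order) r[order(object$data$orig_order)] else r
}

#' Random-effect estimates at the stopping iteration
#'
#' @param fit an [lbbLMM()] fit.
#' @return an `n` x `q` matrix (clusters by effects), rows named by the
#'   original cluster identifiers.
#' @export
random_effects <- function(fit) {
  stopifnot(inherits(fit, "lbblmm"))
  G <- t(gamma_matrix(fit$state, fit$data))
  dimnames(G) <- list(fit$data$cluster_ids, fit$data$random_effect_spec)
  G
}

#' Variance-component estimates at the stopping iteration
#'
#' @param fit an [lbbLMM()] fit.
#' @return list with `sigma2`, `Q` and `tau` (square roots of `diag(Q)`).
#' @export
variance_components <- function(fit) {
  stopifnot(inherits(fit, "lbblmm"))
  Q <- fit$state$Q
  dimnames(Q) <- list(fit$data$random_effect_spec, fit$data$random_effect_spec)
  list(sigma2 = fit$state$sigma2, Q = Q, tau = sqrt(diag(Q)))
}

#' @export
summary.lbblmm <- function(object, ...) {
  print(object)
  vc <- variance_components(object)
  cat("\nVariance components:\n")
  cat("  sigma2 =", format(vc$sigma2, digits = 4), "\n")
  print(round(vc$Q, 4))
  cat("\nNonzero coefficients at m*:\n")
  cf <- object$coefficients
  print(round(cf[cf != 0 | names(cf) == "(Intercept)"], 4))
  invisible(object)
}

#' Coefficient path of a boosting fit as a data frame
#'
#' One row per boosting iteration: iteration number, intercept, all fixed
#' effects, error variance, the unique (vech) elements of the random-effects
#' covariance, and the information-criterion value. Suitable for CSV export.
#'
#' @param fit an [lbbLMM()] fit.
#' @return a `data.frame`.
#' @export
coef_path <- function(fit) {
  stopifnot(inherits(fit, "lbblmm"))
  q <- fit$data$q
  vech_names <- outer(seq_len(q), seq_len(q), function(i, j) paste0("Q", i, j))
  vech_names <- vech_names[lower.tri(vech_names, diag = TRUE)]
  out <- data.frame(iteration = seq_along(fit$paths$beta0),
                    `(Intercept)` = fit$paths$beta0, check.names = FALSE)
  out <- cbind(out, as.data.frame(fit$paths$beta),
               sigma2 = fit$paths$sigma2)
  Qp <- fit$paths$Q
  colnames(Qp) <- vech_names
  out <- cbind(out, as.data.frame(Qp))
  out[[fit$control$criterion]] <- fit$paths$ic
  out
}

#' Plot coefficient paths of a boosting fit
#'
#' Draws the progression of every fixed-effect coefficient over the boosting
#' iterations, with the stopping iteration `m*` marked.
#'
#' @param x an [lbbLMM()] fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.lbblmm <- function(x, ...) {
  graphics::matplot(x$paths$beta, type = "l", lty = 1,
                    xlab = "boosting iteration", ylab = "coefficient", ...)
  graphics::abline(v = x$m_star, lty = 2, col = "grey40")
  nz <- which(x$paths$beta[nrow(x$paths$beta), ] != 0)
  if (length(nz)) {
    graphics::axis(4, at = x$paths$beta[nrow(x$paths$beta), nz],
                   labels = colnames(x$paths$beta)[nz], las = 1, cex.axis = 0.7)
  }
  invisible(x)
}

#' Write a fit's coefficient path and summary to files
#'
#' @param fit an [lbbLMM()] fit.
#' @param path_file CSV destination for [coef_path()] (skipped if `NULL`).
#' @param summary_file plain-text destination for the fit summary
#'   (skipped if `NULL`).
#' @return `fit`, invisibly.
#' @export
write_fit <- function(fit, path_file = NULL, summary_file = NULL) {
  if (!is.null(path_file)) {
    utils::write.csv(coef_path(fit), path_file, row.names = FALSE)
  }
  if (!is.null(summary_file)) {
    con <- file(summary_file, "w")
    sink(con)
    on.exit({ sink(); close(con) })
    summary(fit)
  }
  invisible(fit)
}
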