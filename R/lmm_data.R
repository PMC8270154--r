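#' Assemble a clustered data set for mixed-model boosting
#'
#' Builds the container consumed by every fitting routine in the package from
#' a long-format table (one row per observation). Observations are reordered
#' so that clusters are contiguous; the original row order is retained so
#' fitted values and residuals can be mapped back to the input table.
#'
#' @param table a `data.frame` in long format with a header of named columns.
#' @param response name of the response column.
#' @param cluster name of the cluster-identifier column.
#' @param fixed character vector of fixed-effect covariate columns. These form
#'   the candidate set for the boosting selection step; the global intercept is
#'   handled separately and must not be included.
#' @param random_slopes character vector (possibly empty) of covariate columns
#'   carrying random slopes. A slope column need not appear in `fixed`
#'   (a warning is emitted in that case, as the corresponding fixed effect is
#'   then not part of the model).
#' @param random_intercept logical; include a random intercept (default `TRUE`).
#'
#' @return An object of class `"lmm_data"`: a list with elements
#'   `y` (responses, cluster-contiguous), `X` (N x p fixed-effects design,
#'   no intercept column), `Zrows` (N x q random-effects design rows; the
#'   stacked design is block-diagonal across clusters), `cluster` (integer
#'   index 1..n per row), `cluster_ids` (original identifiers),
#'   `cluster_sizes`, `n`, `N`, `p`, `q`, `covariate_names`,
#'   `random_effect_spec` (effect labels, `"(Intercept)"` first when present)
#'   and `orig_order` (permutation such that row k of the container came from
#'   input row `orig_order[k]`).
#'
#' @examples
#' tab <- data.frame(id = rep(1:3, each = 2), y = rnorm(6),
#'                   x1 = rnorm(6), g = rep(c(-1, 1, 1), each = 2))
#' d <- lmm_data(tab, response = "y", cluster = "id",
#'               fixed = c("x1", "g"), random_intercept = TRUE)
#' d$n; d$q
#' @seealso [classify_covariates()], [lbbLMM()]
#' @export
lmm_data <- function(table, response, cluster, fixed,
                     random_slopes = character(), random_intercept = TRUE) {
  if (!is.data.frame(table)) {
    lbb_config_error("`table` must be a data.frame")
  }
  used <- unique(c(response, cluster, fixed, random_slopes))
  missing_cols <- setdiff(used, names(table))
  if (length(missing_cols)) {
    lbb_config_error(paste0("unknown column name(s): ",
                            paste(missing_cols, collapse = ", ")))
  }
  if (length(fixed) == 0) {
    lbb_config_error("at least one fixed-effect covariate is required")
  }
  if (!random_intercept && length(random_slopes) == 0) {
    lbb_config_error("the random-effects structure is empty; request a random intercept and/or random slopes")
  }
  if (anyNA(table[used])) {
    bad <- used[vapply(table[used], anyNA, logical(1))]
    lbb_data_error(paste0("missing values in column(s): ",
                          paste(bad, collapse = ", ")))
  }
  orphan <- setdiff(random_slopes, fixed)
  if (length(orphan)) {
    warning("random slope(s) without a matching fixed effect: ",
            paste(orphan, collapse = ", "), call. = FALSE)
  }

  cl_raw <- table[[cluster]]
  ## contiguous clusters, in order of first appearance; stable sort keeps the
  ## within-cluster observation order of the input
  cl_fac <- factor(cl_raw, levels = unique(cl_raw))
  ord <- order(as.integer(cl_fac))
  cl <- as.integer(cl_fac)[ord]

  y <- as.numeric(table[[response]])[ord]
  X <- as.matrix(as.data.frame(lapply(table[fixed], as.numeric)))[ord, , drop = FALSE]
  colnames(X) <- fixed
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    lbb_data_error("non-finite values in response or covariates")
  }

  q <- length(random_slopes) + as.integer(random_intercept)
  N <- length(y)
  Zrows <- matrix(1, N, 0)
  re_names <- character(0)
  if (random_intercept) {
    Zrows <- cbind(Zrows, 1)
    re_names <- "(Intercept)"
  }
  for (s in random_slopes) {
    Zrows <- cbind(Zrows, as.numeric(table[[s]])[ord])
    re_names <- c(re_names, s)
  }
  colnames(Zrows) <- re_names

  sizes <- tabulate(cl)
  structure(list(
    y = y, X = X, Zrows = Zrows, cluster = cl,
    cluster_ids = levels(cl_fac), cluster_sizes = sizes,
    cluster_starts = cumsum(c(1L, sizes[-length(sizes)])),
    n = length(sizes), N = N, p = ncol(X), q = q,
    covariate_names = fixed, random_effect_spec = re_names,
    random_intercept = random_intercept, orig_order = ord
  ), class = "lmm_data")
}

#' @export
print.lmm_data <- function(x, ...) {
  cat("Clustered data for mixed-model boosting\n")
  cat(sprintf("  %d observations in %d clusters (sizes %s)\n", x$N, x$n,
              paste(range(x$cluster_sizes), collapse = "-")))
  cat(sprintf("  %d fixed-effect candidates; random effects: %s\n",
              x$p, paste(x$random_effect_spec, collapse = ", ")))
  invisible(x)
}

## rows of cluster i (contiguous)
cluster_rows <- function(data, i) {
  s <- data$cluster_starts[i]
  seq.int(s, s + data$cluster_sizes[i] - 1L)
}

#' Extract the random-effects design block of one cluster
#'
#' @param data an [lmm_data()] object.
#' @param i cluster index in `1..n`.
#' @return the `n_i` x `q` matrix `Z_i`; the stacked random-effects design of
#'   the whole model is block-diagonal in these blocks.
#' @export
z_block <- function(data, i) {
  data$Zrows[cluster_rows(data, i), , drop = FALSE]
}

#' Classify fixed-effect covariates as cluster-constant or cluster-varying
#'
#' A covariate is cluster-constant when its value is exactly identical within
#' every cluster (baseline covariates such as gender or a treatment arm).
#' Exact equality is deliberate: numeric covariates meant to be constant must
#' be stored constant. Cluster-constant covariates drive the random-effects
#' correction of [build_correction()].
#'
#' @param data an [lmm_data()] object.
#' @return An object of class `"covariate_classification"`: a list with
#'   `is_cluster_constant` (named logical, one per fixed-effect covariate) and
#'   `representatives` (an `n` x `k` matrix holding, for each of the `k`
#'   cluster-constant covariates, one representative value per cluster — the
#'   first observation of the cluster).
#' @examples
#' tab <- data.frame(id = rep(1:3, each = 2), y = rnorm(6),
#'                   x = rnorm(6), g = rep(c(0, 1, 0), each = 2))
#' d <- lmm_data(tab, "y", "id", fixed = c("x", "g"))
#' classify_covariates(d)$is_cluster_constant
#' @export
classify_covariates <- function(data) {
  stopifnot(inherits(data, "lmm_data"))
  first_idx <- data$cluster_starts[data$cluster]  # first row of own cluster
  is_cc <- vapply(seq_len(data$p), function(k) {
    all(data$X[, k] == data$X[first_idx, k])
  }, logical(1))
  names(is_cc) <- data$covariate_names
  reps <- data$X[data$cluster_starts, which(is_cc), drop = FALSE]
  structure(list(is_cluster_constant = is_cc, representatives = reps),
            class = "covariate_classification")
}

#' @export
print.covariate_classification <- function(x, ...) {
  cc <- names(x$is_cluster_constant)[x$is_cluster_constant]
  cat("Covariate classification:\n")
  cat("  cluster-constant:", if (length(cc)) paste(cc, collapse = ", ") else "(none)", "\n")
  cat("  cluster-varying: ",
      paste(names(x$is_cluster_constant)[!x$is_cluster_constant], collapse = ", "), "\n")
  invisible(x)
}

#' Read a long-format table from a delimited text file
#'
#' Thin reader for the CLI and scripts: header row required, delimiter taken
#' from `sep` or inferred from the file extension / first line (comma or tab).
#'
#' @param path file path of a CSV/TSV file.
#' @param sep field delimiter; `NULL` (default) infers `","` or `"\t"`.
#' @return a `data.frame`.
#' @export
read_long_table <- function(path, sep = NULL) {
  if (!file.exists(path)) lbb_config_error(paste0("file not found: ", path))
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
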