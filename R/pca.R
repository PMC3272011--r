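# Correlation-scale PCA of the assembly-by-feature matrix. Features live on
# wildly different scales (counts vs N50 in bp), so columns are z-scored and
# the decomposition is of the sample correlation matrix; eigenvalue-based
# retention rules (Kaiser, Marchenko-Pastur) only make sense on that scale.

#' Standardize the columns of a feature matrix
#'
#' Centers every numeric column to mean 0 and scales to sample SD 1. A
#' non-numeric `label` column, if present, is carried through untouched.
#' Zero-variance columns carry no information on correlation scale and are
#' dropped with a warning.
#'
#' @param x Tibble (e.g. from [build_feature_matrix()]) with at least 2 rows.
#' @return Tibble of the same shape minus dropped columns, with attribute
#'   `dropped` naming any removed columns.
#' @export
standardize_matrix <- function(x) {
  x <- as_tibble(x)
  if (nrow(x) < 2) abort("need at least 2 rows to standardize")
  num <- names(x)[purrr::map_lgl(x, is.numeric)]
  sds <- purrr::map_dbl(x[num], sd)
  flat <- num[sds == 0 | !is.finite(sds)]
  if (length(flat)) {
    warn(paste0("dropping zero-variance column(s): ", paste(flat, collapse = ", ")))
    x <- x[setdiff(names(x), flat)]
    num <- setdiff(num, flat)
  }
  x[num] <- purrr::map(x[num], function(v) as.numeric(scale(v)))
  attr(x, "dropped") <- flat
  x
}

#' PCA of a (standardized) assembly-by-feature matrix
#'
#' Eigen-decomposition of the sample correlation matrix of the feature
#' columns. Principal components are ordered by decreasing eigenvalue; the
#' sign of each loading vector is fixed so its largest-magnitude coefficient
#' is positive, making loading tables reproducible.
#'
#' @param x Tibble with numeric feature columns (a `label` column is
#'   ignored). Standardized internally when `standardize = TRUE` (default).
#' @param standardize Z-score columns first (recommended; set `FALSE` only
#'   if `x` is already standardized).
#' @return An object of class `assembly_pca` with elements `eigenvalues`
#'   (descending), `loadings` (variables x PCs, orthonormal columns),
#'   `scores` (observations x PCs), `explained`, `cumulative`, `n_obs`,
#'   `n_var`, `columns`.
#' @export
#' @examples
#' m <- tibble::tibble(a = rnorm(20), b = rnorm(20))
#' p <- assembly_pca(m)
#' tidy(p)
assembly_pca <- function(x, standardize = TRUE) {
  x <- as_tibble(x)
  if (standardize) x <- suppressWarnings(standardize_matrix(x))
  num <- names(x)[purrr::map_lgl(x, is.numeric)]
  m <- as.matrix(x[num])
  if (any(!is.finite(m))) abort("non-finite values in matrix")
  n <- nrow(m)
  p <- ncol(m)
  cc <- crossprod(m) / (n - 1) # correlation matrix when m is z-scored
  eg <- eigen(cc, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  load <- eg$vectors
  # sign convention: largest |coefficient| positive
  for (j in seq_len(p)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(num, paste0("PC", seq_len(p)))
  expl <- ev / sum(ev)
  structure(
    list(
      eigenvalues = ev,
      loadings = load,
      scores = m %*% load,
      explained = expl,
      cumulative = cumsum(expl),
      n_obs = n, n_var = p, columns = num
    ),
    class = "assembly_pca"
  )
}

#' @export
print.assembly_pca <- function(x, ...) {
  cat(
    "<assembly_pca> ", x$n_obs, " observations x ", x$n_var, " variables\n",
    "eigenvalues: ", paste(signif(x$eigenvalues, 3), collapse = " "), "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname assembly_pca
#' @param x An `assembly_pca`.
#' @param ... Unused.
#' @export
tidy.assembly_pca <- function(x, ...) {
  tibble(
    PC = seq_len(x$n_var),
    eigenvalue = x$eigenvalues,
    explained = x$explained,
    cumulative = x$cumulative
  )
}

#' @rdname assembly_pca
#' @export
glance.assembly_pca <- function(x, ...) {
  tibble(
    n_obs = x$n_obs, n_var = x$n_var,
    k_variance_80 = retain_by_variance(x, 0.80),
    k_kaiser = retain_by_kaiser(x)
  )
}

#' Number of PCs to reach a variance threshold
#'
#' The smallest k whose cumulative explained-variance fraction reaches the
#' threshold; the 80% heuristic is the common default.
#'
#' @param pca An `assembly_pca`.
#' @param threshold Fraction in (0, 1], default 0.80.
#' @return Integer count of retained components.
#' @export
retain_by_variance <- function(pca, threshold = 0.80) {
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  as.integer(which(pca$cumulative >= threshold - 1e-12)[1])
}

#' Kaiser-style retention count
#'
#' Number of eigenvalues strictly greater than one -- on correlation scale,
#' components explaining more than a single original variable.
#'
#' @param pca An `assembly_pca`.
#' @return Integer count.
#' @export
retain_by_kaiser <- function(pca) {
  sum(pca$eigenvalues > 1)
}
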