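# Independent component analysis of the assembly-by-feature matrix and
# kurtosis-ranked feature selection. The model is X = A S: each feature
# column is a linear mixture of statistically independent, non-Gaussian
# sources observed across the cohort. Sources are estimated by symmetric
# fixed-point FastICA (tanh contrast) after PCA whitening; independent
# components are ranked by |excess kurtosis| of their sources, the
# top-mass prefix retained, and each retained IC contributes the feature
# with the largest-magnitude mixing coefficient.

#' Excess kurtosis (fourth standardized cumulant)
#'
#' Population-moment form: fourth central moment over squared variance,
#' minus 3. Zero for Gaussian samples, ~3 for Laplace, -2 for a symmetric
#' two-point distribution.
#'
#' @param x Numeric vector of at least 4 values.
#' @return A single number.
#' @export
#' @examples
#' excess_kurtosis(rep(c(-1, 1), 50)) # -2
excess_kurtosis <- function(x) {
  if (length(x) < 4) abort("need at least 4 samples")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) abort("zero variance")
  mean((x - m)^4) / m2^2 - 3
}

# symmetric decorrelation: W <- (W W')^{-1/2} W
.sym_decorrelate <- function(W) {
  sv <- eigen(W %*% t(W), symmetric = TRUE)
  sv$vectors %*% diag(1 / sqrt(pmax(sv$values, 1e-12)), nrow(W)) %*%
    t(sv$vectors) %*% W
}

#' FastICA of a standardized feature matrix
#'
#' Whitens via PCA and runs symmetric fixed-point iteration with the
#' `tanh` contrast (tolerance 1e-6, at most 1000 iterations, up to 5
#' restarts from fresh random rotations with seeds derived from `seed`).
#' Source signs are fixed so each estimated source has positive skewness
#' (falling back to a positive largest-|loading| mixing coefficient when
#' skewness is negligible), making results reproducible for a given seed.
#'
#' @param x Tibble or matrix of the cohort (rows = assemblies, columns =
#'   features; a `label` column is ignored). Standardized internally when
#'   `standardize = TRUE`.
#' @param n_components Number of ICs; defaults to
#'   `min(n_obs - 1, n_var)`.
#' @param seed Integer RNG seed recorded in the result.
#' @param standardize Z-score columns first (default `TRUE`).
#' @param tol,max_iter,restarts Fixed-point iteration controls. When no
#'   restart reaches `tol`, the tightest iterate seen is returned with a
#'   warning and `converged = FALSE` -- near-Gaussian directions commonly
#'   cycle below full tolerance while the informative (non-Gaussian)
#'   components are already resolved, so downstream kurtosis ranking is
#'   unaffected.
#' @return An object of class `assembly_ica`: `mixing` (features x ICs,
#'   the A of X = A S read column-wise per IC), `sources` (ICs x
#'   observations), `kurtosis` (per-IC excess kurtosis of the sources),
#'   `seed`, `converged`, `iterations`, `columns`. The slots
#'   `retained_ics` and `selected_features` are filled by [retain_ics()] /
#'   [select_features()] (or use [ica_select_features()]).
#' @export
run_ica <- function(x, n_components = NULL, seed = 1L, standardize = TRUE,
                    tol = 1e-6, max_iter = 1000L, restarts = 5L) {
  x <- as_tibble(as.data.frame(x))
  if (standardize) x <- suppressWarnings(standardize_matrix(x))
  num <- names(x)[purrr::map_lgl(x, is.numeric)]
  m <- as.matrix(x[num])
  n <- nrow(m)
  p <- ncol(m)
  k <- n_components %||% min(n - 1L, p)
  if (k > min(n - 1L, p)) abort("n_components exceeds min(n_obs - 1, n_var)")
  m <- sweep(m, 2, colMeans(m)) # guard: centering is idempotent

  # PCA whitening: Z (n x k) with cov(Z) = I
  sv <- svd(m, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  if (any(d < 1e-10)) abort("rank-deficient matrix: reduce n_components")
  # canonical sign for the whitening basis (largest-|entry| loading positive),
  # so results are invariant to column permutations of the input
  for (j in seq_len(k)) {
    if (sv$v[which.max(abs(sv$v[, j])), j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  Z <- sv$u * sqrt(n)

  converged <- FALSE
  iterations <- NA_integer_
  W <- NULL
  best_delta <- Inf
  for (r in seq_len(restarts)) {
    set.seed(as.integer(seed) + (r - 1L) * 1000003L)
    Wr <- .sym_decorrelate(matrix(rnorm(k * k), k, k))
    for (it in seq_len(max_iter)) {
      U <- Z %*% t(Wr) # n x k projections
      G <- tanh(U)
      Wnew <- crossprod(G, Z) / n - diag(colMeans(1 - G^2), k) %*% Wr
      Wnew <- .sym_decorrelate(Wnew)
      delta <- max(abs(abs(diag(Wnew %*% t(Wr))) - 1))
      Wr <- Wnew
      if (delta < best_delta) {
        # remember the tightest iterate seen: weakly non-Gaussian
        # directions can settle into a limit cycle after the informative
        # ones have converged
        best_delta <- delta
        W <- Wr
      }
      if (delta < tol) break
    }
    if (delta < tol) {
      converged <- TRUE
      iterations <- it
      W <- Wr
      break
    }
  }
  if (!converged) {
    warn(paste0(
      "FastICA did not reach tol ", format(tol), " after ", restarts,
      " restart(s); returning the tightest iterate (delta = ",
      format(best_delta, digits = 3),
      "). Non-Gaussian components are typically well resolved regardless."
    ))
  }

  S <- Z %*% t(W) # n x k estimated sources (unit variance)
  # mixing in original (standardized) feature space:
  # X_k = Z diag(d)/sqrt(n) V' and Z = S W  =>  A (k x p) = W diag(d)/sqrt(n) V'
  A <- W %*% diag(d / sqrt(n), k) %*% t(sv$v)
  mixing <- t(A) # p x k: per-IC column of feature contributions
  dimnames(mixing) <- list(num, paste0("IC", seq_len(k)))

  # sign convention
  for (j in seq_len(k)) {
    s <- S[, j]
    sk <- mean((s - mean(s))^3) / (sd(s)^3)
    flip <- if (abs(sk) > 0.1) sk < 0 else mixing[which.max(abs(mixing[, j])), j] < 0
    if (flip) {
      S[, j] <- -s
      mixing[, j] <- -mixing[, j]
    }
  }
  kurt <- apply(S, 2, excess_kurtosis)

  structure(
    list(
      mixing = mixing,
      sources = t(S),
      kurtosis = unname(kurt),
      retained_ics = NULL,
      selected_features = NULL,
      seed = as.integer(seed),
      converged = converged,
      iterations = iterations,
      columns = num
    ),
    class = "assembly_ica"
  )
}

#' @export
print.assembly_ica <- function(x, ...) {
  cat(
    "<assembly_ica> ", ncol(x$mixing), " ICs over ", nrow(x$mixing),
    " features (seed ", x$seed, ")\n",
    "|excess kurtosis|: ",
    paste(signif(abs(x$kurtosis), 3), collapse = " "), "\n",
    sep = ""
  )
  if (!is.null(x$selected_features)) {
    cat("selected: ", paste(x$selected_features, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname run_ica
#' @param x An `assembly_ica`.
#' @param ... Unused.
#' @export
tidy.assembly_ica <- function(x, ...) {
  k <- ncol(x$mixing)
  tibble(
    IC = seq_len(k),
    kurtosis = x$kurtosis,
    retained = if (is.null(x$retained_ics)) NA else seq_len(k) %in% x$retained_ics,
    top_feature = x$columns[apply(abs(x$mixing), 2, which.max)]
  )
}

#' @rdname run_ica
#' @export
glance.assembly_ica <- function(x, ...) {
  tibble(
    n_ics = ncol(x$mixing),
    n_retained = length(x$retained_ics %||% integer()),
    n_selected = length(x$selected_features %||% character()),
    seed = x$seed,
    converged = x$converged
  )
}

#' Retain the most non-Gaussian independent components
#'
#' ICs are ranked by `|excess kurtosis|` descending (sub-Gaussian sources
#' are just as non-Gaussian as super-Gaussian ones), ties broken by IC
#' index. With `method = "mass"` (default) the shortest prefix whose
#' |kurtosis| sum reaches `fraction` of the total is retained -- the
#' "top 80% of the kurtosis distribution" reading; `method = "percentile"`
#' instead keeps ICs at or above the `fraction` quantile of |kurtosis|.
#'
#' @param ica An `assembly_ica`.
#' @param fraction Retention fraction, default 0.80.
#' @param method `"mass"` (cumulative-mass prefix) or `"percentile"`.
#' @return Integer vector of retained IC indices (empty, with a warning,
#'   if all kurtoses are zero).
#' @export
retain_ics <- function(ica, fraction = 0.80, method = c("mass", "percentile")) {
  method <- match.arg(method)
  ak <- abs(ica$kurtosis)
  if (all(ak == 0)) {
    warn("all ICs have zero kurtosis; nothing retained")
    return(integer())
  }
  if (method == "percentile") {
    thr <- quantile(ak, probs = fraction, names = FALSE, type = 7)
    return(which(ak >= thr))
  }
  ord <- order(-ak, seq_along(ak))
  cum <- cumsum(ak[ord])
  keep <- seq_len(which(cum >= fraction * sum(ak) - 1e-12)[1])
  sort(ord[keep])
}

#' Select one dominant feature per retained IC
#'
#' For each retained IC, the feature with the largest-magnitude mixing
#' coefficient in that IC's column is singled out; duplicates are removed
#' preserving first occurrence, so the result has at most one feature per
#' retained IC.
#'
#' @param ica An `assembly_ica`.
#' @param retained Integer IC indices, e.g. from [retain_ics()].
#' @return Character vector of selected feature names (ordered set).
#' @export
select_features <- function(ica, retained) {
  if (length(retained) == 0) abort("retained must be non-empty")
  picks <- purrr::map_chr(retained, function(j) {
    ica$columns[which.max(abs(ica$mixing[, j]))]
  })
  unique(picks)
}

#' ICA feature-selection pipeline
#'
#' Runs [run_ica()], [retain_ics()] and [select_features()] in sequence on
#' the feature columns of a cohort matrix (the `N50` and `NUM_CONTIG`
#' extras, if present, are excluded: selection operates on the diagnostic
#' features only) and returns the ICA object with `retained_ics` and
#' `selected_features` filled in.
#'
#' @param x Cohort matrix tibble (e.g. [build_feature_matrix()] output).
#' @param fraction Kurtosis retention fraction (default 0.80).
#' @param seed RNG seed.
#' @param n_components Passed to [run_ica()].
#' @param method Passed to [retain_ics()].
#' @return An `assembly_ica` with selection slots filled.
#' @export
#' @examples
#' sim <- simulate_feature_matrix(cohort_spec(seed = 7))
#' ica <- ica_select_features(sim$matrix, seed = 7)
#' ica$selected_features
ica_select_features <- function(x, fraction = 0.80, seed = 1L,
                                n_components = NULL,
                                method = c("mass", "percentile")) {
  x <- as_tibble(x)
  x <- x[setdiff(names(x), c("N50", "NUM_CONTIG"))]
  ica <- run_ica(x, n_components = n_components, seed = seed)
  ret <- retain_ics(ica, fraction = fraction, method = match.arg(method))
  ica$retained_ics <- ret
  ica$selected_features <- if (length(ret)) select_features(ica, ret) else character()
  ica
}
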