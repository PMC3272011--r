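# Marchenko-Pastur calibration of the eigenvalue spectrum. For pure-noise
# data with aspect ratio gamma = p/n and variance sigma2, sample-correlation
# eigenvalues concentrate in the bulk [lambda_minus, lambda_plus] with
# lambda_pm = sigma2 (1 pm sqrt(gamma))^2; eigenvalues above the upper edge
# indicate genuine signal and fix the number of informative PCs.

#' Marchenko-Pastur density
#'
#' Density of the MP law with aspect ratio `gamma` and scale `sigma2`,
#' supported on `[sigma2 (1 - sqrt(gamma))^2, sigma2 (1 + sqrt(gamma))^2]`.
#' For `gamma > 1` the additional point mass `1 - 1/gamma` at zero is not
#' part of the continuous density returned here.
#'
#' @param x Numeric vector of evaluation points.
#' @param gamma Aspect ratio p/n, > 0.
#' @param sigma2 Variance scale, > 0.
#' @return Density values (0 outside the bulk).
#' @export
mp_density <- function(x, gamma, sigma2 = 1) {
  stopifnot(gamma > 0, sigma2 > 0)
  lm <- sigma2 * (1 - sqrt(gamma))^2
  lp <- sigma2 * (1 + sqrt(gamma))^2
  out <- numeric(length(x))
  inside <- x > lm & x < lp
  xi <- x[inside]
  out[inside] <- sqrt((lp - xi) * (xi - lm)) / (2 * pi * sigma2 * gamma * xi)
  out
}

#' Marchenko-Pastur CDF
#'
#' Cumulative distribution of the MP law, by trapezoidal integration of the
#' density on a fine grid (the point mass at 0 for `gamma > 1` included).
#'
#' @inheritParams mp_density
#' @param q Numeric vector of quantiles.
#' @return CDF values in `[0, 1]`.
#' @export
mp_cdf <- function(q, gamma, sigma2 = 1) {
  # scale relation: F_{sigma2}(q) = F_1(q / sigma2)
  q1 <- q / sigma2
  lm <- (1 - sqrt(gamma))^2
  lp <- (1 + sqrt(gamma))^2
  grid <- seq(lm, lp, length.out = 2048)
  dens <- mp_density(grid, gamma, 1)
  step <- grid[2] - grid[1]
  cdf_grid <- cumsum((dens + dplyr::lag(dens, default = 0)) / 2) * step
  cdf_grid <- cdf_grid / cdf_grid[length(cdf_grid)] # normalize quadrature
  bulk_mass <- if (gamma > 1) 1 / gamma else 1
  atom <- if (gamma > 1) 1 - 1 / gamma else 0
  out <- stats::approx(grid, cdf_grid, xout = q1, yleft = 0, yright = 1,
                       rule = 2)$y * bulk_mass
  out[q1 >= 0] <- out[q1 >= 0] + atom
  out[q1 < lm & q1 < 0] <- 0
  pmin(out, 1)
}

#' Fit the Marchenko-Pastur law to an eigenvalue spectrum
#'
#' The aspect ratio `gamma` is fixed by the matrix shape (p/n, never
#' fitted); the scale `sigma2` is chosen by grid search over 0.05 ... 3.0
#' in steps of 0.01, minimizing the Cramer-von Mises distance between the
#' MP CDF and the empirical eigenvalue CDF. The fitted bulk edges
#' `lambda_pm = sigma2 (1 pm sqrt(gamma))^2` separate noise from signal.
#'
#' With `trim_spikes = TRUE`, a single robustness pass is added: after the
#' initial fit to the full spectrum, eigenvalues above the fitted upper
#' edge are set aside and the scale refitted once on the remaining bulk.
#' On a pure-noise spectrum essentially nothing is trimmed; with strong
#' spikes this stops the signal mass from dragging the scale down. The
#' default is the plain whole-spectrum fit.
#'
#' @param eigenvalues Numeric vector (>= 3 values) of sample eigenvalues.
#' @param gamma Aspect ratio p/n, > 0.
#' @param sigma2_grid Candidate scales searched (default `seq(0.05, 3, 0.01)`).
#' @param trim_spikes Exclude above-edge eigenvalues and refit once
#'   (default `FALSE`).
#' @return An object of class `mp_fit`: `gamma`, `sigma2`, `lambda_minus`,
#'   `lambda_plus`, `fit_distance` (the minimized CvM statistic on the
#'   bulk used for the final fit), `n_trimmed`.
#' @export
#' @examples
#' ev <- eigen(crossprod(matrix(rnorm(5000), 100, 50)) / 100)$values
#' fit_mp(ev, gamma = 0.5)
fit_mp <- function(eigenvalues, gamma, sigma2_grid = seq(0.05, 3, by = 0.01),
                   trim_spikes = FALSE) {
  if (length(eigenvalues) < 3) abort("need at least 3 eigenvalues")
  if (gamma <= 0) abort("gamma must be positive")
  ev <- sort(eigenvalues)
  if (diff(range(ev)) < .Machine$double.eps^0.5) {
    abort("degenerate spectrum: all eigenvalues equal")
  }
  fit_once <- function(evs) {
    n <- length(evs)
    emp <- (2 * seq_len(n) - 1) / (2 * n)
    cvm <- vapply(sigma2_grid, function(s2) {
      fx <- mp_cdf(evs, gamma, s2)
      1 / (12 * n) + sum((fx - emp)^2)
    }, numeric(1))
    best <- which.min(cvm)
    list(sigma2 = sigma2_grid[best], cvm = cvm[best])
  }
  cur <- ev
  f <- fit_once(cur)
  if (trim_spikes) {
    edge <- f$sigma2 * (1 + sqrt(gamma))^2
    keep <- ev[ev <= edge]
    if (length(keep) >= 3 && length(keep) < length(cur)) {
      cur <- keep
      f <- fit_once(cur)
    }
  }
  s2 <- f$sigma2
  structure(
    list(
      gamma = gamma, sigma2 = s2,
      lambda_minus = s2 * (1 - sqrt(gamma))^2,
      lambda_plus = s2 * (1 + sqrt(gamma))^2,
      fit_distance = f$cvm,
      n_trimmed = length(ev) - length(cur)
    ),
    class = "mp_fit"
  )
}

#' @export
print.mp_fit <- function(x, ...) {
  cat(
    "<mp_fit> gamma = ", signif(x$gamma, 3),
    ", sigma2 = ", x$sigma2,
    ", bulk [", signif(x$lambda_minus, 4), ", ", signif(x$lambda_plus, 4),
    "], CvM = ", signif(x$fit_distance, 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname fit_mp
#' @param x An `mp_fit`.
#' @param ... Unused.
#' @export
glance.mp_fit <- function(x, ...) {
  tibble(
    gamma = x$gamma, sigma2 = x$sigma2,
    lambda_minus = x$lambda_minus, lambda_plus = x$lambda_plus,
    fit_distance = x$fit_distance
  )
}

#' Marchenko-Pastur retention count
#'
#' Number of eigenvalues strictly above the fitted upper bulk edge
#' `lambda_plus`: components the noise model cannot explain. The fit should
#' come from the same spectrum (`fit_mp(pca$eigenvalues, p/n)`); see
#' [retain_by_kaiser()] for the simpler eigenvalue-greater-than-one rule.
#'
#' @param pca An `assembly_pca` (or a bare numeric vector of eigenvalues).
#' @param fit An `mp_fit`; fitted from `pca` when omitted.
#' @return Integer count of informative components.
#' @export
retain_by_mp <- function(pca, fit = NULL) {
  ev <- if (inherits(pca, "assembly_pca")) pca$eigenvalues else pca
  if (is.null(fit)) {
    if (!inherits(pca, "assembly_pca")) {
      abort("supply a fit when pca is a bare eigenvalue vector")
    }
    fit <- fit_mp(ev, gamma = pca$n_var / pca$n_obs)
  }
  sum(ev > fit$lambda_plus)
}
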