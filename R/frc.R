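# Feature-Response Curve: sort contigs by length (longest first), and for
# each feature threshold phi take the longest prefix of that order whose
# cumulative feature count stays <= phi; the response is the genome fraction
# covered by that prefix. A good assembly reaches high coverage at low phi.

#' Compute the Feature-Response Curve of an assembly
#'
#' Contigs are sorted by length descending (ties broken by contig id
#' ascending, for determinism). For each threshold `phi`, coverage is the
#' summed length of the longest prefix of that order whose cumulative
#' feature count -- restricted to `subset` if given -- is at most `phi`,
#' divided by the genome size. By default one point is produced at every
#' integer `phi` from 0 to the total feature count.
#'
#' A per-contig variant (`cumulative = FALSE`) instead tallies every contig
#' whose own feature count is `<= phi`, irrespective of the others; it is
#' provided for comparison, the cumulative form being the published curve.
#'
#' @param x An [assembly()], or a count table from [count_features()].
#' @param contigs Contig tibble; required when `x` is a count table.
#' @param subset Character vector of analysis feature types to restrict the
#'   count to, or `NULL` for all.
#' @param genome_size Denominator in bp; defaults to the assembly's own
#'   `genome_size` and falls back to total assembly length.
#' @param thresholds Integer vector of `phi` values, or `NULL` for every
#'   integer 0 ... total count.
#' @param config Counting configuration used when `x` is an assembly.
#' @param cumulative Use cumulative-prefix semantics (default `TRUE`).
#' @param label Curve label; defaults to the assembly label.
#' @return A tibble of class `frc_curve` with columns `phi` and `coverage`,
#'   and attributes `genome_size`, `subset`, `label`.
#' @export
#' @examples
#' a <- assembly("toy",
#'   tibble::tibble(contig_id = c("a", "b", "c"), length = c(100, 50, 30)),
#'   tibble::tibble(
#'     contig_id = c("a", "a", "c"), feature = "BREAKPOINT",
#'     start = c(0, 10, 5), end = c(1, 11, 6)
#'   ),
#'   genome_size = 200
#' )
#' compute_frc(a)
compute_frc <- function(x, contigs = NULL, subset = NULL, genome_size = NULL,
                        thresholds = NULL, config = counting_config(),
                        cumulative = TRUE, label = NULL) {
  if (inherits(x, "assembly")) {
    label <- label %||% x$label
    genome_size <- genome_size %||% x$genome_size
    contigs <- x$contigs
    counts <- count_features(x, config = config)
  } else {
    if (is.null(contigs)) abort("contigs required when x is a count table")
    counts <- x
  }
  label <- label %||% "assembly"
  genome_size <- genome_size %||% sum(contigs$length)
  if (genome_size <= 0) abort("genome_size must be positive")

  feat_cols <- setdiff(names(counts), c("contig_id", "total"))
  if (is.null(subset)) {
    subset_cols <- feat_cols
  } else {
    unknown <- setdiff(subset, feat_cols)
    if (length(unknown)) {
      abort(paste0("unknown subset member(s): ", paste(unknown, collapse = ", ")))
    }
    subset_cols <- subset
  }
  per_contig <- rowSums(counts[, subset_cols, drop = FALSE])

  ord <- order(-contigs$length, contigs$contig_id)
  len <- contigs$length[ord]
  cnt <- per_contig[match(contigs$contig_id[ord], counts$contig_id)]
  cum_cnt <- cumsum(cnt)
  cum_len <- cumsum(len)

  total <- sum(cnt)
  if (is.null(thresholds)) thresholds <- 0:total
  if (any(thresholds < 0)) abort("negative threshold")
  thresholds <- sort(unique(thresholds))

  coverage <- if (cumulative) {
    vapply(thresholds, function(phi) {
      k <- findInterval(phi, cum_cnt, left.open = FALSE)
      # findInterval gives #{j : cum_cnt[j] <= phi} since cum_cnt nondecreasing
      if (k == 0) 0 else cum_len[k] / genome_size
    }, numeric(1))
  } else {
    vapply(thresholds, function(phi) {
      sum(len[cnt <= phi]) / genome_size
    }, numeric(1))
  }

  structure(
    tibble(phi = thresholds, coverage = coverage),
    genome_size = genome_size,
    subset = if (is.null(subset)) "ALL" else subset,
    label = label,
    class = c("frc_curve", "tbl_df", "tbl", "data.frame")
  )
}

#' Area under a Feature-Response Curve
#'
#' Normalized trapezoidal area of coverage over `[0, phi_max]`, a scalar in
#' `[0, 1]` for ranking curves: higher means more genome recovered at lower
#' feature burden. Beyond the last curve point the coverage is carried
#' forward flat (the curve is saturated there).
#'
#' @param curve An `frc_curve`.
#' @param phi_max Upper integration limit; defaults to the largest `phi` in
#'   the curve. Must be positive.
#' @return A single number in `[0, 1]`.
#' @export
frc_auc <- function(curve, phi_max = NULL) {
  if (nrow(curve) == 0) abort("empty curve")
  phi <- curve$phi
  cov <- curve$coverage
  phi_max <- phi_max %||% max(phi)
  if (phi_max <= 0) {
    # degenerate single-point curve at phi = 0
    return(cov[length(cov)])
  }
  keep <- phi <= phi_max
  phi <- phi[keep]
  cov <- cov[keep]
  if (length(phi) == 0 || max(phi) < phi_max) {
    phi <- c(phi, phi_max)
    cov <- c(cov, if (length(cov)) cov[length(cov)] else 0)
  }
  if (phi[1] > 0) {
    phi <- c(0, phi)
    cov <- c(cov[1], cov)
  }
  sum(diff(phi) * (head(cov, -1) + cov[-1]) / 2) / phi_max
}

#' Combine Feature-Response Curves for comparison
#'
#' Stacks curves into a long table `(label, phi, coverage)` for plotting or
#' export, and attaches an AUC ranking. Curves must share a genome size:
#' coverage fractions with different denominators are not comparable, so
#' mismatched curves are dropped with a warning rather than merged.
#'
#' @param curves A list of `frc_curve` objects.
#' @param phi_max Upper limit for the AUC ranking; defaults to the largest
#'   `phi` across curves.
#' @return A tibble of class `frc_comparison` with columns `label`, `phi`,
#'   `coverage`, and attribute `ranking` (a tibble `label`, `auc` sorted
#'   best-first).
#' @export
compare_frc <- function(curves, phi_max = NULL) {
  stopifnot(length(curves) >= 1)
  gs <- purrr::map_dbl(curves, attr, "genome_size")
  if (length(unique(gs)) > 1) {
    keep <- gs == gs[1]
    dropped <- purrr::map_chr(curves[!keep], attr, "label")
    warn(paste0(
      "genome sizes differ; dropping curve(s) not matching the first: ",
      paste(dropped, collapse = ", ")
    ))
    curves <- curves[keep]
  }
  labels <- purrr::map_chr(curves, attr, "label")
  if (anyDuplicated(labels)) {
    labels <- make.unique(labels)
  }
  phi_max <- phi_max %||% max(purrr::map_dbl(curves, function(cv) max(cv$phi)))
  pts <- purrr::map2(curves, labels, function(cv, lb) {
    tibble(label = lb, phi = cv$phi, coverage = cv$coverage)
  }) |>
    dplyr::bind_rows()
  ranking <- tibble(
    label = labels,
    auc = purrr::map_dbl(curves, frc_auc, phi_max = phi_max)
  ) |>
    dplyr::arrange(dplyr::desc(.data$auc))
  structure(
    pts,
    ranking = ranking,
    class = c("frc_comparison", "tbl_df", "tbl", "data.frame")
  )
}

#' Write an FRC comparison to TSV
#'
#' Long-format `label phi coverage` table with a `#`-comment header.
#'
#' @param x An `frc_comparison` (or `frc_curve`).
#' @param file Path.
#' @param header Optional extra comment lines.
#' @return `file`, invisibly.
#' @export
write_frc <- function(x, file, header = character()) {
  if (inherits(x, "frc_curve")) x <- compare_frc(list(x))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# ", c("frcurve FRC table", header)), con)
  utils::write.table(
    as.data.frame(x), con,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(file)
}
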