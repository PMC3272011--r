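# Feature counting rules: a point feature (BREAKPOINT, HIGH_SNP) counts as
# one regardless of reported span; an extent feature of length l counts
# proportionally to its length, max(1, ceiling(l / T)) for the tally window
# T, so that e.g. a 25 kbp KMER_COV region with T = 10 kbp counts as 3.

#' Feature counting configuration
#'
#' @param extent_window Tally window T in bp for extent features: a feature
#'   spanning l bp contributes `max(1, ceiling(l / T))` counts. Default
#'   10,000 bp.
#' @param collapse If `TRUE` (default), merge `HIGH_LINKING_CVG` and
#'   `HIGH_SPANNING_CVG` into one analysis column (12 raw types -> 11).
#' @return A list of class `counting_config`.
#' @export
counting_config <- function(extent_window = 10000, collapse = TRUE) {
  if (extent_window < 1) abort("extent_window must be >= 1")
  structure(
    list(extent_window = extent_window, collapse = isTRUE(collapse)),
    class = "counting_config"
  )
}

#' Count contributed by each feature record
#'
#' Vectorized counting rule: point features contribute 1; extent features of
#' length `end - start` contribute `max(1, ceiling(length / extent_window))`.
#'
#' @param features Tibble of feature records (`feature`, `start`, `end`).
#' @param config A [counting_config()].
#' @return Integer vector of per-record counts, aligned with the rows of
#'   `features`.
#' @export
#' @examples
#' fr <- tibble::tibble(
#'   feature = c("HIGH_SNP", "KMER_COV"),
#'   start = c(500, 100), end = c(501, 25100)
#' )
#' feature_count(fr, counting_config())
feature_count <- function(features, config = counting_config()) {
  len <- features$end - features$start
  if (any(len <= 0)) abort("feature with end <= start")
  ifelse(
    is_point_feature(features$feature),
    1L,
    pmax(1, ceiling(len / config$extent_window))
  )
}

#' Per-contig, per-type feature count table
#'
#' Applies the counting rule to every record and sums per contig and
#' feature type. All contigs of the assembly appear, with zero rows for
#' featureless contigs; with `config$collapse` the linking and spanning
#' coverage columns are merged. Column order is `contig_id`, the analysis
#' feature columns in canonical order, then `total`.
#'
#' @param features Tibble of feature records, or an [assembly()] (in which
#'   case `contigs` is taken from it).
#' @param contigs Tibble with `contig_id`, `length`; ignored when
#'   `features` is an assembly.
#' @param config A [counting_config()].
#' @return A wide tibble: one row per contig, one column per (collapsed)
#'   feature type, plus `total`.
#' @export
count_features <- function(features, contigs = NULL, config = counting_config()) {
  if (inherits(features, "assembly")) {
    contigs <- features$contigs
    features <- features$features
  }
  if (is.null(contigs)) abort("contigs required when features is a tibble")
  cols <- analysis_features(collapse = config$collapse)
  unresolved <- setdiff(features$contig_id, contigs$contig_id)
  if (length(unresolved)) {
    abort(paste0("unresolved contig id(s): ", paste(unresolved, collapse = ", ")))
  }
  base <- tidyr::expand_grid(contig_id = contigs$contig_id, feature = cols)
  if (nrow(features)) {
    tallied <- features |>
      dplyr::mutate(
        n = feature_count(features, config),
        feature = .to_analysis_feature(.data$feature, config$collapse)
      ) |>
      dplyr::group_by(.data$contig_id, .data$feature) |>
      dplyr::summarise(n = sum(.data$n), .groups = "drop")
  } else {
    tallied <- tibble(contig_id = character(), feature = character(), n = numeric())
  }
  base |>
    dplyr::left_join(tallied, by = c("contig_id", "feature")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0)) |>
    tidyr::pivot_wider(names_from = "feature", values_from = "n") |>
    dplyr::mutate(total = rowSums(dplyr::across(dplyr::all_of(cols)))) |>
    dplyr::arrange(match(.data$contig_id, contigs$contig_id))
}

#' Assemble the cohort assembly-by-feature matrix
#'
#' One row per assembly: total feature counts per (collapsed) type summed
#' over contigs, optionally augmented with the `N50` and `NUM_CONTIG`
#' columns commonly reported alongside.
#'
#' @param assemblies List of [assembly()] objects (length >= 2).
#' @param config A [counting_config()].
#' @param include_n50,include_num_contig Append the `N50` and `NUM_CONTIG`
#'   columns (default `TRUE`).
#' @return A tibble with a `label` column followed by the feature columns
#'   in canonical order (11 when collapsed) and the optional extras.
#' @export
build_feature_matrix <- function(assemblies, config = counting_config(),
                                 include_n50 = TRUE, include_num_contig = TRUE) {
  if (length(assemblies) < 2) abort("need at least 2 assemblies")
  if (!all(purrr::map_lgl(assemblies, inherits, "assembly"))) {
    abort("assemblies must be a list of assembly objects")
  }
  cols <- analysis_features(collapse = config$collapse)
  rows <- purrr::map(assemblies, function(a) {
    ct <- count_features(a, config = config)
    tot <- purrr::map_dbl(cols, function(f) sum(ct[[f]]))
    row <- tibble(label = a$label)
    row[cols] <- as.list(tot)
    if (include_n50) row$N50 <- n50(a$contigs$length)
    if (include_num_contig) row$NUM_CONTIG <- nrow(a$contigs)
    row
  })
  dplyr::bind_rows(rows)
}

#' Write / read an assembly-by-feature matrix as CSV
#'
#' Plain CSV with a header row; first column is the assembly label.
#'
#' @param x Matrix tibble from [build_feature_matrix()].
#' @param file Path.
#' @return `write_feature_matrix` returns `file` invisibly;
#'   `read_feature_matrix` returns the tibble.
#' @export
write_feature_matrix <- function(x, file) {
  utils::write.csv(x, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(file) {
  as_tibble(utils::read.csv(file, check.names = FALSE, comment.char = "#"))
}
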