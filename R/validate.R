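# Scoring diagnostic features against true mis-assembly intervals obtained
# by aligning contigs to a finished reference (dnadiff-style). A feature is
# "correct" when its interval intersects (>= 1 bp, half-open semantics) a
# filtered true interval on the same contig. Totals use the counting rules:
# an extent feature contributing c counts contributes c to both tallies.

#' Filter true mis-assembly intervals before scoring
#'
#' Mirrors the usual post-processing of alignment differences: small
#' sequence-level differences (SNPs, indels shorter than `min_indel` bp)
#' are not structural mis-assemblies and are dropped, as are
#' breakpoint-kind intervals starting within `edge_margin` bp of either
#' contig end, where partial alignments are expected.
#'
#' @param intervals Tibble from [read_misassemblies()].
#' @param contigs Contig tibble (`contig_id`, `length`).
#' @param edge_margin Breakpoint exclusion zone at contig ends (default
#'   1000 bp).
#' @param min_indel Minimum indel width kept (default 10 bp).
#' @return Filtered interval tibble.
#' @export
filter_misassemblies <- function(intervals, contigs, edge_margin = 1000,
                                 min_indel = 10) {
  intervals <- as_tibble(intervals)
  if (nrow(intervals) == 0) {
    return(intervals)
  }
  len <- contigs$length[match(intervals$contig_id, contigs$contig_id)]
  if (any(is.na(len))) abort("interval on unknown contig")
  width <- intervals$end - intervals$start
  small <- intervals$kind %in% c("snp", "indel") & width < min_indel
  edge <- intervals$kind == "breakpoint" &
    (intervals$start < edge_margin | intervals$start >= len - edge_margin)
  intervals[!(small | edge), , drop = FALSE]
}

# half-open >= 1 bp overlap flag per feature record, via IRanges
.overlaps_truth <- function(features, intervals) {
  if (nrow(features) == 0) {
    return(logical())
  }
  if (nrow(intervals) == 0) {
    return(rep(FALSE, nrow(features)))
  }
  # convert 0-based half-open to 1-based closed
  fr <- IRanges::IRanges(start = features$start + 1, end = features$end)
  tr <- IRanges::IRanges(start = intervals$start + 1, end = intervals$end)
  same <- outer(features$contig_id, intervals$contig_id, "==")
  ov <- as.matrix(IRanges::findOverlaps(fr, tr, minoverlap = 1L))
  flag <- rep(FALSE, nrow(features))
  if (nrow(ov)) {
    ok <- same[cbind(ov[, 1], ov[, 2])]
    flag[unique(ov[ok, 1])] <- TRUE
  }
  flag
}

#' Score features against true mis-assembly intervals
#'
#' Each feature record contributes its counting-rule count `c` (see
#' [feature_count()]) to `n_features`, and to `n_correct` iff its interval
#' intersects at least one filtered true interval on the same contig
#' (half-open: touching intervals do not overlap). If `subset` is given,
#' the same totals restricted to those feature types are reported as
#' `n_features_subset` / `n_correct_subset` (collapsed analysis names are
#' accepted and expand to their raw members).
#'
#' @param features Feature record tibble, or an [assembly()].
#' @param intervals True-interval tibble; filtered with
#'   [filter_misassemblies()] when `filter = TRUE`.
#' @param contigs Contig tibble; taken from the assembly when given.
#' @param subset Optional character vector of feature types.
#' @param config A [counting_config()].
#' @param filter Apply [filter_misassemblies()] first (default `TRUE`).
#' @param edge_margin,min_indel Passed to the filter.
#' @return One-row tibble: `n_features`, `n_correct`, and (when `subset`
#'   is given) `n_features_subset`, `n_correct_subset`.
#' @export
score_features <- function(features, intervals, contigs = NULL, subset = NULL,
                           config = counting_config(), filter = TRUE,
                           edge_margin = 1000, min_indel = 10) {
  if (inherits(features, "assembly")) {
    contigs <- features$contigs
    features <- features$features
  }
  if (is.null(contigs)) abort("contigs required")
  if (filter) {
    intervals <- filter_misassemblies(intervals, contigs,
      edge_margin = edge_margin, min_indel = min_indel
    )
  }
  cnt <- if (nrow(features)) feature_count(features, config) else numeric()
  hit <- .overlaps_truth(features, intervals)
  out <- tibble(
    n_features = sum(cnt),
    n_correct = sum(cnt[hit])
  )
  if (!is.null(subset)) {
    raw <- subset
    if (.collapsed_name %in% raw) {
      raw <- union(setdiff(raw, .collapsed_name), .collapsed_members)
    }
    unknown <- setdiff(raw, .feature_names)
    if (length(unknown)) {
      abort(paste0("unknown subset type(s): ", paste(unknown, collapse = ", ")))
    }
    in_sub <- features$feature %in% raw
    out$n_features_subset <- sum(cnt[in_sub])
    out$n_correct_subset <- sum(cnt[in_sub & hit])
  }
  out
}
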