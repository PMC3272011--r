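#' Bundle contigs and features into an assembly
#'
#' An assembly is one observation in a cohort: a labelled contig set with
#' its diagnostic feature records and an optional genome-size estimate.
#' Every feature must resolve to a contig and lie within its bounds.
#'
#' @param label Assembler/dataset name used in cohort tables and plots.
#' @param contigs Tibble with columns `contig_id`, `length`
#'   (see [read_contigs()]).
#' @param features Tibble of feature records (see [read_features()]);
#'   defaults to none.
#' @param genome_size Estimated genome size in bp, or `NULL`. Must be at
#'   least the longest contig when given.
#' @return An object of class `assembly` (a list with elements `label`,
#'   `contigs`, `features`, `genome_size`).
#' @export
#' @examples
#' ctg <- tibble::tibble(contig_id = c("a", "b"), length = c(100, 50))
#' assembly("demo", ctg)
assembly <- function(label, contigs, features = NULL, genome_size = NULL) {
  stopifnot(is.character(label), length(label) == 1)
  contigs <- as_tibble(contigs)
  if (!all(c("contig_id", "length") %in% names(contigs))) {
    abort("contigs must have columns contig_id and length")
  }
  if (anyDuplicated(contigs$contig_id)) abort("duplicate contig ids")
  if (any(contigs$length < 1)) abort("contig lengths must be >= 1")
  if (is.null(features)) {
    features <- tibble(
      contig_id = character(), feature = character(),
      start = numeric(), end = numeric(), note = character()
    )
  }
  features <- as_tibble(features)
  if (!"note" %in% names(features)) features$note <- ""
  unresolved <- setdiff(features$contig_id, contigs$contig_id)
  if (length(unresolved)) {
    abort(paste0(
      "feature(s) on unknown contig(s): ",
      paste(utils::head(unresolved, 5), collapse = ", ")
    ))
  }
  if (nrow(features)) {
    len <- contigs$length[match(features$contig_id, contigs$contig_id)]
    if (any(features$start < 0) || any(features$end > len)) {
      abort("feature coordinates outside contig bounds")
    }
    if (any(features$end <= features$start)) abort("feature with end <= start")
  }
  if (!is.null(genome_size)) {
    if (genome_size < max(contigs$length)) {
      abort("genome_size smaller than the longest contig")
    }
  }
  structure(
    list(
      label = label, contigs = contigs,
      features = features, genome_size = genome_size
    ),
    class = "assembly"
  )
}

#' @export
print.assembly <- function(x, ...) {
  cat(
    "<assembly> ", x$label, ": ", nrow(x$contigs), " contigs (",
    format(sum(x$contigs$length), big.mark = ","), " bp), ",
    nrow(x$features), " feature records",
    if (!is.null(x$genome_size)) {
      paste0(", genome ~", format(x$genome_size, big.mark = ","), " bp")
    } else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

#' N50 / NG50 contig statistic
#'
#' The smallest contig length L such that contigs of length >= L together
#' cover at least half the denominator. By default the denominator is the
#' assembly total (N50, the universal convention); supplying `genome_size`
#' gives NG50, where the half-point is half the estimated genome size.
#'
#' @param lengths Numeric vector of positive contig lengths.
#' @param genome_size Optional genome size for NG50; `NULL` (default) uses
#'   the assembly total length.
#' @return A single length in bp. For NG50, `NA` if even the whole assembly
#'   does not reach half the genome size.
#' @export
#' @examples
#' n50(c(10, 8, 5, 3)) # half-total 13 -> 8
n50 <- function(lengths, genome_size = NULL) {
  if (length(lengths) == 0) abort("empty length list")
  if (any(lengths <= 0)) abort("lengths must be positive")
  denom <- if (is.null(genome_size)) sum(lengths) else genome_size
  if (denom <= 0) abort("denominator must be positive")
  srt <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(srt)
  i <- which(cum >= denom / 2)
  if (length(i) == 0) {
    return(NA_real_)
  }
  srt[i[1]]
}
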