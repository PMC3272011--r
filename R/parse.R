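# Readers for the two plain-text inputs: amosvalidate-style .feat files
# (contig_id, type, start, end[, note...]) and contig lengths (FASTA or
# two-column TSV). Coordinates are 0-based half-open throughout; point
# features reported with start == end are widened to width-1 intervals.

#' Read an amosvalidate-style feature file
#'
#' Parses whitespace- or tab-separated lines of the form
#' `contig_id feature_type start end [note...]`. Lines beginning with `#`
#' and blank lines are ignored. Feature tokens are canonicalized via
#' [canonical_feature()]; coordinates are interpreted as 0-based half-open,
#' and point records with `start == end` are widened to `end = start + 1`.
#'
#' @param file Path to the feature file, or a connection.
#' @param strict If `TRUE`, unknown feature tokens are an error; otherwise
#'   such records are dropped with a warning (so files from newer
#'   amosvalidate versions still parse).
#' @return A tibble of feature records with columns `contig_id`, `feature`,
#'   `start`, `end`, `note`.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("# demo", "ctg1 HIGH_SNP 500 500", "ctg1 KMER_COV 100 25100"), f)
#' read_features(f)
read_features <- function(file, strict = FALSE) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble(
      contig_id = character(), feature = character(),
      start = numeric(), end = numeric(), note = character()
    ))
  }
  parts <- strsplit(lines, "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 4)) {
    abort(paste0(
      "malformed feature line(s) (need contig_id type start end): ",
      paste(utils::head(lines[nf < 4], 3), collapse = " | ")
    ))
  }
  rec <- tibble(
    contig_id = purrr::map_chr(parts, 1),
    feature = canonical_feature(purrr::map_chr(parts, 2), strict = strict),
    start = as.numeric(purrr::map_chr(parts, 3)),
    end = as.numeric(purrr::map_chr(parts, 4)),
    note = purrr::map_chr(parts, function(p) {
      if (length(p) > 4) paste(p[-(1:4)], collapse = " ") else ""
    })
  )
  rec <- rec[!is.na(rec$feature), , drop = FALSE]
  if (any(!is.finite(rec$start)) || any(!is.finite(rec$end))) {
    abort("non-numeric coordinates in feature file")
  }
  if (any(rec$end < rec$start)) {
    abort("feature with end < start")
  }
  if (any(rec$start < 0)) {
    abort("negative feature coordinate")
  }
  # width-0 point records become width-1 half-open intervals
  zero <- rec$end == rec$start
  rec$end[zero] <- rec$start[zero] + 1
  rec
}

#' Read contig ids and lengths
#'
#' Accepts either a FASTA file (lengths are sequence lengths, line breaks
#' ignored) or a two-column `id<TAB>length` table. With `format = "auto"`
#' the file is sniffed: a first non-blank character of `>` means FASTA.
#'
#' @param file Path to the contig file.
#' @param format One of `"auto"`, `"fasta"`, `"tsv"`.
#' @return A tibble with columns `contig_id` and `length`.
#' @export
read_contigs <- function(file, format = c("auto", "fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(file, n = 1L, warn = FALSE)
    format <- if (length(first) && startsWith(trimws(first), ">")) "fasta" else "tsv"
  }
  if (format == "fasta") {
    len <- Biostrings::fasta.seqlengths(file)
    ids <- sub("\\s.*$", "", names(len))
    out <- tibble(contig_id = ids, length = as.numeric(unname(len)))
  } else {
    lines <- trimws(readLines(file, warn = FALSE))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "[ \t]+")
    if (any(lengths(parts) < 2)) abort("malformed contig line (need id and length)")
    out <- tibble(
      contig_id = purrr::map_chr(parts, 1),
      length = as.numeric(purrr::map_chr(parts, 2))
    )
  }
  if (anyDuplicated(out$contig_id)) abort("duplicate contig ids")
  if (any(!is.finite(out$length)) || any(out$length < 1)) {
    abort("contig lengths must be positive integers")
  }
  out
}

#' Read true mis-assembly intervals
#'
#' BED-like whitespace-separated lines `contig_id start end kind`, 0-based
#' half-open, as produced by post-processing a dnadiff-style comparison of
#' contigs against a finished reference. `kind` is one of `breakpoint`,
#' `relocation`, `inversion`, `indel`, `snp`, `other` (unknown kinds are
#' mapped to `other`).
#'
#' @param file Path or connection.
#' @return A tibble with columns `contig_id`, `start`, `end`, `kind`.
#' @export
read_misassemblies <- function(file) {
  lines <- trimws(readLines(file, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble(
      contig_id = character(), start = numeric(),
      end = numeric(), kind = character()
    ))
  }
  parts <- strsplit(lines, "[ \t]+")
  if (any(lengths(parts) < 3)) abort("malformed interval line (need contig start end)")
  out <- tibble(
    contig_id = purrr::map_chr(parts, 1),
    start = as.numeric(purrr::map_chr(parts, 2)),
    end = as.numeric(purrr::map_chr(parts, 3)),
    kind = tolower(purrr::map_chr(parts, function(p) {
      if (length(p) >= 4) p[4] else "other"
    }))
  )
  known <- c("breakpoint", "relocation", "inversion", "indel", "snp", "other")
  out$kind[!(out$kind %in% known)] <- "other"
  if (any(!is.finite(out$start)) || any(!is.finite(out$end))) {
    abort("non-numeric interval coordinates")
  }
  if (any(out$start >= out$end)) abort("interval with start >= end")
  out
}

#' Convert dnadiff .mcoords-style breakpoints to intervals
#'
#' Best-effort converter: takes the tab/space-separated `show-coords -T`
#' dialect (columns ref start/end, query start/end, ..., ref id, query id)
#' and emits a breakpoint interval at each internal query alignment
#' boundary. Intended as glue for users coming from dnadiff; the package
#' itself consumes the interval tibble.
#'
#' @param file Path to an mcoords-like file.
#' @return A tibble in the [read_misassemblies()] column layout with
#'   `kind = "breakpoint"`.
#' @export
mcoords_breakpoints <- function(file) {
  lines <- trimws(readLines(file, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[ \t]+")
  parts <- parts[lengths(parts) >= 4]
  if (length(parts) == 0) {
    return(tibble(
      contig_id = character(), start = numeric(),
      end = numeric(), kind = character()
    ))
  }
  qs <- purrr::map_dbl(parts, function(p) as.numeric(p[3]))
  qe <- purrr::map_dbl(parts, function(p) as.numeric(p[4]))
  qid <- purrr::map_chr(parts, function(p) p[length(p)])
  aln <- tibble(contig_id = qid, lo = pmin(qs, qe) - 1, hi = pmax(qs, qe)) |>
    dplyr::arrange(.data$contig_id, .data$lo)
  aln |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::reframe(pos = .data$hi[-dplyr::n()]) |>
    dplyr::transmute(
      contig_id = .data$contig_id,
      start = .data$pos, end = .data$pos + 1,
      kind = "breakpoint"
    )
}
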