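# The amosvalidate diagnostic feature taxonomy: 12 raw feature types, of which
# BREAKPOINT and HIGH_SNP are point signals (width-1 loci) and the rest mark
# extended regions of the contig. For cohort analysis HIGH_LINKING_CVG and
# HIGH_SPANNING_CVG (mates in another scaffold / another contig) are collapsed
# into one column, giving the 11 analysis features.

.feature_names <- c(
  "BREAKPOINT", "COMPRESSION", "STRETCH", "LOW_GOOD_CVG", "HIGH_NORMAL_CVG",
  "HIGH_LINKING_CVG", "HIGH_SPANNING_CVG", "HIGH_OUTIE_CVG",
  "HIGH_SINGLEMATE_CVG", "HIGH_READ_COVERAGE", "HIGH_SNP", "KMER_COV"
)

.point_features <- c("BREAKPOINT", "HIGH_SNP")

.collapsed_name <- "HIGH_LINKING_SPANNING_CVG"
.collapsed_members <- c("HIGH_LINKING_CVG", "HIGH_SPANNING_CVG")

# tokens seen in the wild for the same signals
.feature_aliases <- c(
  BREACKPOINT   = "BREAKPOINT",
  CE_COMPRESSION = "COMPRESSION",
  CE_STRETCH    = "STRETCH",
  K_MER_COV     = "KMER_COV",
  HIGH_KMER_COV = "KMER_COV"
)

#' The diagnostic feature taxonomy
#'
#' The twelve amosvalidate-style mis-assembly signals placed on contigs:
#' mate-pair violations (linking/spanning/outie/single-mate coverage),
#' coverage anomalies (low good coverage, high normal/read coverage),
#' compression/expansion signatures (COMPRESSION, STRETCH, KMER_COV),
#' clustered SNPs (HIGH_SNP) and leftover-read breakpoints (BREAKPOINT).
#' `BREAKPOINT` and `HIGH_SNP` are point features; the remaining ten mark
#' extended intervals.
#'
#' @return A tibble with columns `feature` (the canonical token) and `kind`
#'   (`"point"` or `"extent"`), one row per raw feature type.
#' @seealso [analysis_features()] for the collapsed 11-column analysis set.
#' @export
#' @examples
#' feature_types()
feature_types <- function() {
  tibble(
    feature = .feature_names,
    kind = ifelse(.feature_names %in% .point_features, "point", "extent")
  )
}

#' The collapsed analysis feature set
#'
#' Cohort-level analyses merge `HIGH_LINKING_CVG` and `HIGH_SPANNING_CVG`
#' (high coverage of reads whose mates land in another scaffold or another
#' contig -- two flavors of the same inter-sequence linkage signal) into a
#' single column, reducing the 12 raw types to 11 analysis features.
#'
#' @param collapse If `TRUE` (default) return the 11 collapsed names; if
#'   `FALSE` return the 12 raw names.
#' @return Character vector of feature column names, in canonical order.
#' @export
#' @examples
#' analysis_features()
#' analysis_features(collapse = FALSE)
analysis_features <- function(collapse = TRUE) {
  if (!collapse) {
    return(.feature_names)
  }
  out <- .feature_names
  i <- match(.collapsed_members[1], out)
  out[i] <- .collapsed_name
  setdiff(out, .collapsed_members[2])
}

#' Canonicalize feature-type tokens
#'
#' Maps tokens to canonical taxonomy names, accepting case variants and a
#' few historical aliases (e.g. `BREACKPOINT`, `CE_STRETCH`, `K_MER_COV`).
#'
#' @param x Character vector of feature tokens.
#' @param strict If `TRUE`, unknown tokens raise an error; otherwise they
#'   become `NA` with a warning.
#' @return Character vector of canonical names (possibly with `NA`s when
#'   `strict = FALSE`).
#' @export
canonical_feature <- function(x, strict = FALSE) {
  up <- toupper(trimws(x))
  ali <- .feature_aliases[up]
  up[!is.na(ali)] <- ali[!is.na(ali)]
  bad <- !(up %in% .feature_names)
  if (any(bad)) {
    msg <- paste0(
      "unknown feature token(s): ",
      paste(unique(x[bad]), collapse = ", ")
    )
    if (strict) abort(msg) else warn(paste0(msg, " (skipped)"))
    up[bad] <- NA_character_
  }
  up
}

# collapse a vector of raw feature names to analysis names
.to_analysis_feature <- function(x, collapse = TRUE) {
  if (collapse) x[x %in% .collapsed_members] <- .collapsed_name
  x
}

#' Is a feature type a point feature?
#'
#' @param x Character vector of canonical feature names.
#' @return Logical vector; `TRUE` for `BREAKPOINT` and `HIGH_SNP`.
#' @export
is_point_feature <- function(x) x %in% .point_features
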