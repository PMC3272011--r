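# Synthetic study conditions. Two generators:
#  * simulate_feature_matrix(): a cohort matrix X = S A + noise with k
#    non-Gaussian (Laplace by default) latent factors, each dominated by a
#    distinct feature, mapped to counts -- the low-rank structure PCA/ICA
#    assume, with recorded ground truth.
#  * simulate_assembly(): a toy assembly whose planted mis-assemblies emit
#    a truth interval plus co-occurring feature records at the same locus,
#    over a background of uniformly sprinkled features -- the local error
#    signature the diagnostic features are designed to flag.

#' Specification of a synthetic cohort matrix
#'
#' Defaults describe a cohort of 80 assemblies over the 11 analysis
#' features with 3 planted factors: each factor loads strongly (6.0) on
#' one distinct feature and at half the noise-free scale elsewhere (fixed
#' magnitude 0.5, random signs, so the dominant feature is dominant by
#' construction even after standardization, while the dense cross-loadings
#' mimic how mis-assembly signals co-occur and give factor eigenvalues far
#' above the noise bulk), sources are unit-variance Laplace (excess
#' kurtosis 3), residual noise sd 0.35, and counts arise by rounding a
#' softplus of the latent signal around a baseline of 20 (near-linear
#' there, and large enough that integer rounding is small against the
#' planted signal, so the low-rank non-Gaussian structure survives the
#' link).
#'
#' @param n_assemblies Cohort size (rows).
#' @param n_features Number of feature columns (default 11, named after
#'   [analysis_features()]).
#' @param n_factors Number k of planted latent factors (0 for pure noise).
#' @param factor_loadings `"random"` (dominant + fixed-magnitude random-
#'   sign cross-loadings as above) or a k x p numeric matrix.
#' @param source_family `"laplace"`, `"exponential"` or `"uniform"`
#'   (all scaled to unit variance; uniform is sub-Gaussian).
#' @param noise_sd Residual noise standard deviation.
#' @param count_link `"round_softplus"` (default) or `"poisson"`.
#' @param dominant_strength,cross_sd,baseline Loading of each factor on its
#'   dominant feature, magnitude of its other loadings, and the softplus
#'   baseline.
#' @param seed Integer seed; the generator is fully deterministic per seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_assemblies = 80, n_features = 11, n_factors = 3,
                        factor_loadings = "random",
                        source_family = c("laplace", "exponential", "uniform"),
                        noise_sd = 0.35,
                        count_link = c("round_softplus", "poisson"),
                        dominant_strength = 6, cross_sd = 0.5, baseline = 20,
                        seed = 1L) {
  source_family <- match.arg(source_family)
  count_link <- match.arg(count_link)
  if (n_factors > n_features) abort("n_factors must be <= n_features")
  if (noise_sd <= 0) abort("noise_sd must be positive")
  structure(
    list(
      n_assemblies = n_assemblies, n_features = n_features,
      n_factors = n_factors, factor_loadings = factor_loadings,
      source_family = source_family, noise_sd = noise_sd,
      count_link = count_link, dominant_strength = dominant_strength,
      cross_sd = cross_sd, baseline = baseline, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

.rsource <- function(n, family) {
  switch(family,
    laplace = {
      # difference of exponentials, scaled to unit variance
      u <- runif(n) - 0.5
      -sign(u) * log(1 - 2 * abs(u)) / sqrt(2)
    },
    exponential = rexp(n) - 1,
    uniform = runif(n, -sqrt(3), sqrt(3))
  )
}

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Simulate a cohort assembly-by-feature matrix with planted structure
#'
#' Draws sources S (n x k) from the spec's non-Gaussian family, loadings A
#' (k x p) with one dominant feature per factor, forms
#' `X = S A + noise`, and maps latent values to non-negative counts via
#' the chosen link. The ground truth (loadings, dominant feature of each
#' factor, sources) is returned alongside.
#'
#' @param spec A [cohort_spec()].
#' @return A list: `matrix` (tibble, `label` + feature columns), `truth`
#'   (list with `loadings`, `dominant_features`, `sources`), `spec`.
#' @export
#' @examples
#' sim <- simulate_feature_matrix(cohort_spec(seed = 42))
#' sim$truth$dominant_features
simulate_feature_matrix <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_assemblies
  p <- spec$n_features
  k <- spec$n_factors
  feats <- if (p == 11) analysis_features() else sprintf("F%02d", seq_len(p))

  if (is.matrix(spec$factor_loadings)) {
    A <- spec$factor_loadings
    stopifnot(nrow(A) == k, ncol(A) == p)
    dominant <- feats[apply(abs(A), 1, which.max)]
  } else if (k > 0) {
    dom_idx <- sample.int(p, k)
    A <- matrix(spec$cross_sd * sample(c(-1, 1), k * p, replace = TRUE), k, p)
    A[cbind(seq_len(k), dom_idx)] <-
      spec$dominant_strength * sample(c(-1, 1), k, replace = TRUE)
    dominant <- feats[dom_idx]
  } else {
    A <- matrix(0, 0, p)
    dominant <- character()
  }

  S <- if (k > 0) matrix(.rsource(n * k, spec$source_family), n, k) else matrix(0, n, 0)
  latent <- (if (k > 0) S %*% A else matrix(0, n, p)) +
    matrix(rnorm(n * p, sd = spec$noise_sd), n, p)

  counts <- switch(spec$count_link,
    round_softplus = round(.softplus(latent + spec$baseline)),
    poisson = {
      lam <- .softplus(latent + spec$baseline)
      matrix(rpois(n * p, lam), n, p)
    }
  )
  colnames(counts) <- feats
  mat <- dplyr::bind_cols(
    tibble(label = sprintf("asm%03d", seq_len(n))),
    as_tibble(counts)
  )
  list(
    matrix = mat,
    truth = list(loadings = A, dominant_features = dominant, sources = S),
    spec = spec
  )
}

#' Specification of a synthetic toy assembly
#'
#' Contig lengths are log-normal; each contig independently carries a
#' planted mis-assembly with probability `error_rate`. A planted error
#' emits one truth interval plus `1 + Poisson(features_per_error - 1)`
#' co-occurring feature records overlapping that locus (mate-pair and
#' coverage anomalies cluster where the assembly is wrong); background
#' features are sprinkled uniformly at `background_rate` per kb.
#'
#' @param n_contigs Number of contigs.
#' @param length_meanlog,length_sdlog Log-normal contig-length parameters
#'   (defaults: median 20 kb, sdlog 0.7).
#' @param genome_size Genome size in bp used as the FRC denominator.
#' @param error_rate Per-contig probability of a planted mis-assembly.
#' @param features_per_error Mean number of feature records per error
#'   (>= 1).
#' @param background_rate Background feature rate per kb.
#' @param seed Integer seed.
#' @return A list of class `toy_assembly_spec`.
#' @export
toy_assembly_spec <- function(n_contigs = 50,
                              length_meanlog = log(2e4), length_sdlog = 0.7,
                              genome_size = 2e6,
                              error_rate = 0.1, features_per_error = 3,
                              background_rate = 0.05, seed = 1L) {
  if (error_rate < 0 || error_rate > 1) abort("error_rate must be in [0, 1]")
  if (background_rate < 0) abort("background_rate must be >= 0")
  if (features_per_error < 1) abort("features_per_error must be >= 1")
  structure(
    list(
      n_contigs = n_contigs, length_meanlog = length_meanlog,
      length_sdlog = length_sdlog, genome_size = genome_size,
      error_rate = error_rate, features_per_error = features_per_error,
      background_rate = background_rate, seed = as.integer(seed)
    ),
    class = "toy_assembly_spec"
  )
}

# feature types a planted error can emit (error-proximal signals)
.error_feature_pool <- c(
  "COMPRESSION", "STRETCH", "HIGH_OUTIE_CVG", "HIGH_SPANNING_CVG",
  "HIGH_READ_COVERAGE", "KMER_COV", "BREAKPOINT", "HIGH_SNP"
)
.truth_kinds <- c("relocation", "inversion", "indel")

#' Simulate a toy assembly with planted mis-assemblies
#'
#' @param spec A [toy_assembly_spec()].
#' @return A list: `assembly` (an [assembly()]), `features` (its feature
#'   tibble), `truth` (interval tibble in [read_misassemblies()] layout),
#'   `spec`.
#' @export
#' @examples
#' sim <- simulate_assembly(toy_assembly_spec(seed = 3))
#' sim$assembly
simulate_assembly <- function(spec) {
  stopifnot(inherits(spec, "toy_assembly_spec"))
  set.seed(spec$seed)
  n <- spec$n_contigs
  len <- pmax(1000, round(stats::rlnorm(n, spec$length_meanlog, spec$length_sdlog)))
  contigs <- tibble(contig_id = sprintf("ctg%04d", seq_len(n)), length = len)

  feats <- list()
  truths <- list()
  for (i in seq_len(n)) {
    L <- len[i]
    id <- contigs$contig_id[i]
    if (runif(1) < spec$error_rate) {
      w <- round(runif(1, 500, 2000))
      s <- floor(runif(1, 0, max(1, L - w)))
      e <- min(L, s + w)
      truths[[length(truths) + 1]] <- tibble(
        contig_id = id, start = s, end = e,
        kind = sample(.truth_kinds, 1)
      )
      nf <- 1 + rpois(1, spec$features_per_error - 1)
      for (f in seq_len(nf)) {
        ft <- sample(.error_feature_pool, 1)
        if (is_point_feature(ft)) {
          ps <- floor(runif(1, s, e))
          fs <- ps
          fe <- ps + 1
        } else {
          fw <- round(runif(1, 200, 3000))
          fs <- max(0, floor(runif(1, s - fw / 2, e - fw / 2)))
          fe <- min(L, fs + fw)
          # keep the record anchored on the error locus
          if (fe <= s) fe <- min(L, s + 1)
          if (fs >= e) fs <- max(0, e - 1)
          if (fe <= fs) fe <- fs + 1
        }
        feats[[length(feats) + 1]] <- tibble(
          contig_id = id, feature = ft, start = fs, end = fe, note = "planted"
        )
      }
    }
    nb <- rpois(1, spec$background_rate * L / 1000)
    if (nb > 0) {
      for (f in seq_len(nb)) {
        ft <- sample(.feature_names, 1)
        if (is_point_feature(ft)) {
          fs <- floor(runif(1, 0, L - 1))
          fe <- fs + 1
        } else {
          fw <- round(runif(1, 200, 3000))
          fs <- floor(runif(1, 0, max(1, L - fw)))
          fe <- min(L, fs + fw)
          if (fe <= fs) fe <- fs + 1
        }
        feats[[length(feats) + 1]] <- tibble(
          contig_id = id, feature = ft, start = fs, end = fe, note = "background"
        )
      }
    }
  }
  features <- if (length(feats)) dplyr::bind_rows(feats) else tibble(
    contig_id = character(), feature = character(),
    start = numeric(), end = numeric(), note = character()
  )
  truth <- if (length(truths)) dplyr::bind_rows(truths) else tibble(
    contig_id = character(), start = numeric(),
    end = numeric(), kind = character()
  )
  asm <- assembly(
    label = sprintf("sim_seed%d", spec$seed),
    contigs = contigs, features = features,
    genome_size = max(spec$genome_size, max(len))
  )
  list(assembly = asm, features = features, truth = truth, spec = spec)
}

#' Write simulated outputs to plain-text files
#'
#' Emits the three file formats the parsers consume: a feature TSV, a
#' contig `id<TAB>length` TSV, and a BED-like truth file, each with a
#' `#`-comment header recording the seed.
#'
#' @param sim Result of [simulate_assembly()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_simulated_assembly <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- paste0("# frcurve simulated assembly, seed ", sim$spec$seed)
  paths <- c(
    features = file.path(dir, "features.feat"),
    contigs = file.path(dir, "contigs.tsv"),
    truth = file.path(dir, "truth.bed")
  )
  f <- sim$features
  writeLines(c(hdr, sprintf(
    "%s\t%s\t%d\t%d\t%s", f$contig_id, f$feature, as.integer(f$start),
    as.integer(f$end), f$note
  )), paths["features"])
  ctg <- sim$assembly$contigs
  writeLines(c(hdr, sprintf("%s\t%d", ctg$contig_id, as.integer(ctg$length))),
    paths["contigs"])
  tr <- sim$truth
  writeLines(c(hdr, sprintf(
    "%s\t%d\t%d\t%s", tr$contig_id, as.integer(tr$start),
    as.integer(tr$end), tr$kind
  )), paths["truth"])
  invisible(paths)
}
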