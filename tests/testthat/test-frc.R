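toy_frc_assembly <- function() {
  # contigs (100, 2 feats), (50, 0), (30, 1), genome 200
  assembly("toy",
    tibble::tibble(contig_id = c("a", "b", "c"), length = c(100, 50, 30)),
    tibble::tibble(
      contig_id = c("a", "a", "c"), feature = "BREAKPOINT",
      start = c(0, 10, 5), end = c(1, 11, 6)
    ),
    genome_size = 200
  )
}

test_that("FRC cumulative-prefix semantics on the worked toy example", {
  cv <- compute_frc(toy_frc_assembly())
  expect_equal(cv$phi, 0:3)
  expect_equal(cv$coverage, c(0, 0, 0.75, 0.90))
})

test_that("FRC equals exhaustive prefix enumeration on random assemblies", {
  for (s in 1:60) {
    cc <- random_counted_assembly(s)
    g <- sum(cc$length) + sample(0:1000, 1)
    thr <- 0:sum(cc$count)
    cv <- compute_frc(
      counts_from_totals(cc),
      contigs = cc[, c("contig_id", "length")],
      genome_size = g, thresholds = thr
    )
    expect_equal(cv$coverage, frc_oracle(cc, g, thr))
  }
})

test_that("coverage is monotone in phi and saturates at total length", {
  for (s in 101:130) {
    cc <- random_counted_assembly(s)
    g <- sum(cc$length)
    cv <- compute_frc(counts_from_totals(cc), contigs = cc[, 1:2], genome_size = g)
    expect_true(all(diff(cv$coverage) >= 0))
    expect_equal(cv$coverage[nrow(cv)], sum(cc$length) / g)
  }
})

test_that("restricting the feature subset never lowers coverage", {
  set.seed(77)
  for (s in 1:30) {
    sim <- simulate_assembly(toy_assembly_spec(
      n_contigs = 12, error_rate = 0.5, background_rate = 0.2, seed = 700 + s
    ))
    counts <- count_features(sim$assembly)
    sub <- sample(analysis_features(), 4)
    full <- compute_frc(sim$assembly)
    restricted <- compute_frc(counts,
      contigs = sim$assembly$contigs,
      subset = sub, genome_size = attr(full, "genome_size"),
      thresholds = full$phi
    )
    expect_true(all(restricted$coverage >= full$coverage - 1e-12))
  }
})

test_that("scaling genome size rescales coverage inversely", {
  cc <- random_counted_assembly(5)
  g <- sum(cc$length)
  a <- compute_frc(counts_from_totals(cc), contigs = cc[, 1:2], genome_size = g)
  b <- compute_frc(counts_from_totals(cc), contigs = cc[, 1:2], genome_size = 2 * g)
  expect_equal(b$coverage, a$coverage / 2)
})

test_that("per-contig threshold variant tallies each contig independently", {
  cc <- tibble::tibble(
    contig_id = c("a", "b", "c"), length = c(100, 50, 30), count = c(5, 0, 1)
  )
  cv <- compute_frc(counts_from_totals(cc),
    contigs = cc[, 1:2], genome_size = 180,
    cumulative = FALSE, thresholds = 0:5
  )
  # phi=0: only b; phi=1: b+c; phi=5: all
  expect_equal(cv$coverage, c(50, 80, 80, 80, 80, 180) / 180)
})

test_that("AUC is the normalized trapezoid, flat curves map to their level", {
  flat <- structure(
    tibble::tibble(phi = 0:4, coverage = rep(0.6, 5)),
    genome_size = 100, subset = "ALL", label = "flat",
    class = c("frc_curve", "tbl_df", "tbl", "data.frame")
  )
  expect_equal(frc_auc(flat), 0.6)
  cv <- compute_frc(toy_frc_assembly())
  # hand trapezoid over (0,0),(1,0),(2,.75),(3,.9)
  expect_equal(frc_auc(cv, 3), (0 + 0.375 + 0.825) / 3)
  # extending past the last point carries coverage forward
  expect_equal(frc_auc(cv, 6), (0 + 0.375 + 0.825 + 3 * 0.9) / 6)
  expect_error(frc_auc(cv[0, ]), "empty")
})

test_that("comparison table stacks curves and ranks by AUC", {
  a <- toy_frc_assembly()
  good <- compute_frc(a, label = "good")
  sub <- compute_frc(a, subset = "KMER_COV", label = "restricted")
  cmp <- compare_frc(list(good, sub))
  expect_setequal(unique(cmp$label), c("good", "restricted"))
  rk <- attr(cmp, "ranking")
  expect_equal(rk$label[1], "restricted") # no KMER_COV features: saturated curve
  expect_true(all(diff(rk$auc) <= 0))

  # mismatched genome sizes: warn and drop, never merge
  other <- compute_frc(a, genome_size = 400, label = "other")
  expect_warning(cmp2 <- compare_frc(list(good, other)), "genome sizes differ")
  expect_equal(unique(cmp2$label), "good")
})

test_that("curve TSV export carries label, phi, coverage", {
  f <- tempfile(fileext = ".tsv")
  write_frc(compute_frc(toy_frc_assembly()), f, header = "seed 1")
  lines <- readLines(f)
  expect_true(any(startsWith(lines, "#")))
  body <- utils::read.delim(text = lines[!startsWith(lines, "#")])
  expect_equal(names(body), c("label", "phi", "coverage"))
  expect_equal(nrow(body), 4)
})
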