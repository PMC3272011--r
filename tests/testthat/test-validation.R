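test_that("interval files parse and validate", {
  f <- write_tmp(c("# truth", "ctg1 150 160 relocation", "ctg2\t5\t500\tweird_kind"))
  iv <- read_misassemblies(f)
  expect_equal(nrow(iv), 2)
  expect_equal(iv$kind, c("relocation", "other"))
  expect_error(read_misassemblies(write_tmp("ctg1 160 150 x")), "start >= end")
  expect_equal(nrow(read_misassemblies(write_tmp("# nothing"))), 0)
})

test_that("filtering drops small differences and edge breakpoints", {
  contigs <- tibble::tibble(contig_id = "c", length = 10000)
  iv <- tibble::tibble(
    contig_id = "c",
    start = c(100, 5000, 50, 5000, 9500, 4000),
    end = c(101, 5004, 51, 5600, 9501, 4500),
    kind = c("snp", "indel", "breakpoint", "relocation", "breakpoint", "indel")
  )
  kept <- filter_misassemblies(iv, contigs)
  # snp dropped; 4 bp indel dropped; breakpoints at 50 and 9500 inside the
  # 1 kb margins dropped; mid-contig relocation and 500 bp indel kept
  expect_equal(kept$kind, c("relocation", "indel"))
  expect_equal(kept$start, c(5000, 4000))
  # margin is configurable
  kept2 <- filter_misassemblies(iv, contigs, edge_margin = 10)
  expect_true(50 %in% kept2$start)
})

test_that("half-open overlap: touching intervals do not count", {
  contigs <- tibble::tibble(contig_id = "c", length = 1000)
  feats <- tibble::tibble(
    contig_id = "c", feature = "COMPRESSION",
    start = c(100, 100), end = c(200, 200)
  )
  hit <- score_features(
    feats[1, ],
    tibble::tibble(contig_id = "c", start = 150, end = 160, kind = "relocation"),
    contigs = contigs
  )
  expect_equal(hit$n_correct, 1)
  miss <- score_features(
    feats[1, ],
    tibble::tibble(contig_id = "c", start = 200, end = 210, kind = "relocation"),
    contigs = contigs
  )
  expect_equal(miss$n_correct, 0)
  # same span on another contig never overlaps
  other <- score_features(
    feats[1, ],
    tibble::tibble(contig_id = "d", start = 150, end = 160, kind = "relocation"),
    contigs = tibble::tibble(contig_id = c("c", "d"), length = c(1000, 1000))
  )
  expect_equal(other$n_correct, 0)
})

test_that("scoring equals the brute-force all-pairs oracle on random instances", {
  for (s in 1:60) {
    set.seed(3000 + s)
    contigs <- tibble::tibble(
      contig_id = c("a", "b", "c"), length = c(20000, 15000, 8000)
    )
    nf <- sample(1:25, 1)
    feats <- tibble::tibble(
      contig_id = sample(contigs$contig_id, nf, replace = TRUE),
      feature = sample(analysis_features(collapse = FALSE), nf, replace = TRUE)
    )
    len <- contigs$length[match(feats$contig_id, contigs$contig_id)]
    feats$start <- floor(runif(nf, 0, len - 1))
    width <- ifelse(is_point_feature(feats$feature), 1, sample(1:3000, nf, replace = TRUE))
    feats$end <- pmin(len, feats$start + width)
    ni <- sample(0:10, 1)
    ivs <- tibble::tibble(
      contig_id = sample(contigs$contig_id, ni, replace = TRUE),
      kind = "relocation"
    )
    il <- contigs$length[match(ivs$contig_id, contigs$contig_id)]
    ivs$start <- floor(runif(ni, 0, il - 1))
    ivs$end <- pmin(il, ivs$start + sample(1:2000, max(ni, 1), replace = TRUE)[seq_len(ni)])

    cfg <- counting_config()
    got <- score_features(feats, ivs, contigs = contigs, filter = FALSE, config = cfg)
    cnt <- feature_count(feats, cfg)
    hit <- if (ni > 0) overlap_oracle(feats, ivs) else rep(FALSE, nf)
    expect_equal(got$n_features, sum(cnt))
    expect_equal(got$n_correct, sum(cnt[hit]))
  }
})

test_that("interval coverage of every base makes every feature correct", {
  sim <- simulate_assembly(toy_assembly_spec(seed = 8, error_rate = 0.3))
  all_iv <- tibble::tibble(
    contig_id = sim$assembly$contigs$contig_id,
    start = 0, end = sim$assembly$contigs$length, kind = "relocation"
  )
  sc <- score_features(sim$assembly, all_iv, filter = FALSE)
  expect_equal(sc$n_correct, sc$n_features)
})

test_that("n_correct is monotone as intervals are added; subset totals nest", {
  sim <- simulate_assembly(toy_assembly_spec(seed = 14, error_rate = 0.6))
  iv <- sim$truth
  prev <- 0
  for (k in seq_len(nrow(iv))) {
    sc <- score_features(sim$assembly, iv[seq_len(k), ], filter = FALSE)
    expect_gte(sc$n_correct, prev)
    prev <- sc$n_correct
  }
  sub <- c("KMER_COV", "COMPRESSION")
  sc <- score_features(sim$assembly, iv, filter = FALSE, subset = sub)
  expect_lte(sc$n_features_subset, sc$n_features)
  expect_lte(sc$n_correct_subset, sc$n_correct)
  expect_error(
    score_features(sim$assembly, iv, subset = "NOT_A_FEATURE"),
    "unknown subset"
  )
})
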