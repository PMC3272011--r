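test_that("taxonomy has the 12 raw types with the right point/extent split", {
  tt <- feature_types()
  expect_equal(nrow(tt), 12)
  expect_setequal(tt$kind, c("point", "extent"))
  expect_equal(sort(tt$feature[tt$kind == "point"]), c("BREAKPOINT", "HIGH_SNP"))
  expect_equal(sum(tt$kind == "extent"), 10)
})

test_that("analysis collapse merges linking and spanning into one column", {
  a <- analysis_features()
  expect_equal(length(a), 11)
  expect_true("HIGH_LINKING_SPANNING_CVG" %in% a)
  expect_false(any(c("HIGH_LINKING_CVG", "HIGH_SPANNING_CVG") %in% a))
  expect_equal(length(analysis_features(collapse = FALSE)), 12)
})

test_that("feature file parsing canonicalizes, widens points, rejects bad input", {
  f <- write_tmp(feature_file_lines)
  rec <- read_features(f)
  expect_equal(nrow(rec), 3)
  # point record widened to a width-1 half-open interval
  expect_equal(rec$start[1], 500)
  expect_equal(rec$end[1], 501)
  # extent passes through
  expect_equal(rec$end[2] - rec$start[2], 25000)
  expect_equal(rec$note[3], "low coverage stretch")

  expect_error(read_features(write_tmp("ctg1 BOGUS 1 2"), strict = TRUE), "unknown")
  expect_warning(out <- read_features(write_tmp(c("ctg1 BOGUS 1 2", "ctg1 HIGH_SNP 5 5"))), "unknown")
  expect_equal(nrow(out), 1)
  expect_error(read_features(write_tmp("ctg1 HIGH_SNP 10 5")), "end < start")
  # historical aliases map to canonical names
  expect_equal(canonical_feature(c("breackpoint", "CE_STRETCH")), c("BREAKPOINT", "STRETCH"))
})

test_that("contig parsing handles FASTA and TSV with validation", {
  fa <- write_tmp(c(">a extra words", "ACGT", "AC", ">b", "GGGG"))
  ctg <- read_contigs(fa)
  expect_equal(ctg$contig_id, c("a", "b"))
  expect_equal(ctg$length, c(6, 4))

  tsv <- write_tmp(c("a\t100", "b 42"))
  expect_equal(read_contigs(tsv)$length, c(100, 42))
  expect_error(read_contigs(write_tmp("a\t0")), "positive")
  expect_error(read_contigs(write_tmp(c("a\t10", "a\t20"))), "duplicate")
})

test_that("counting rule: points count once, extents proportionally with floor one", {
  cfg <- counting_config(extent_window = 10000)
  fr <- tibble::tibble(
    feature = c("HIGH_SNP", "KMER_COV", "KMER_COV", "BREAKPOINT"),
    start = c(500, 100, 0, 7),
    end = c(501, 25100, 4000, 8)
  )
  expect_equal(feature_count(fr, cfg), c(1, 3, 1, 1))
  # window monotonicity: doubling T never increases a count
  set.seed(11)
  for (i in 1:50) {
    len <- sample(1:50000, 1)
    f1 <- tibble::tibble(feature = "KMER_COV", start = 0, end = len)
    t1 <- sample(1000:20000, 1)
    expect_lte(
      feature_count(f1, counting_config(extent_window = 2 * t1)),
      feature_count(f1, counting_config(extent_window = t1))
    )
  }
})

test_that("per-contig count table matches brute-force summation and collapses losslessly", {
  set.seed(42)
  contigs <- tibble::tibble(contig_id = c("a", "b", "c"), length = rep(50000, 3))
  nf <- 40
  feats <- tibble::tibble(
    contig_id = sample(contigs$contig_id, nf, replace = TRUE),
    feature = sample(analysis_features(collapse = FALSE), nf, replace = TRUE),
    start = sample(0:20000, nf)
  )
  feats$end <- feats$start + ifelse(is_point_feature(feats$feature), 1, sample(1:25000, nf))
  cfg <- counting_config()

  tab <- count_features(feats, contigs, cfg)
  # brute force: per-record loop
  brute <- setNames(numeric(3), contigs$contig_id)
  for (i in seq_len(nf)) {
    brute[feats$contig_id[i]] <- brute[feats$contig_id[i]] +
      feature_count(feats[i, ], cfg)
  }
  expect_equal(tab$total[match(names(brute), tab$contig_id)], unname(brute))

  # collapsed total equals uncollapsed total
  tab12 <- count_features(feats, contigs, counting_config(collapse = FALSE))
  expect_equal(sum(tab$total), sum(tab12$total))
  # linking + spanning merged
  expect_equal(
    tab$HIGH_LINKING_SPANNING_CVG,
    tab12$HIGH_LINKING_CVG + tab12$HIGH_SPANNING_CVG
  )

  # invariance under permutation of feature rows
  perm <- feats[sample(nf), ]
  expect_equal(count_features(perm, contigs, cfg), tab)

  # unresolved contig errors
  bad <- feats
  bad$contig_id[1] <- "nope"
  expect_error(count_features(bad, contigs, cfg), "unresolved")
})

test_that("n50 follows the cumulative-sum definition and stays in the length set", {
  expect_equal(n50(c(10, 8, 5, 3)), 8)
  expect_equal(n50(7), 7)
  expect_equal(n50(c(5, 5)), 5)
  expect_error(n50(numeric()), "empty")
  # NG50 uses the genome-size denominator
  expect_equal(n50(c(10, 8, 5, 3), genome_size = 40), 5)
  expect_true(is.na(n50(c(10, 8), genome_size = 1000)))
  set.seed(9)
  for (i in 1:25) {
    len <- sample(1:1000, sample(1:30, 1), replace = TRUE)
    v <- n50(len)
    expect_true(v %in% len)
    srt <- sort(len, decreasing = TRUE)
    expect_gte(sum(srt[srt >= v]), sum(len) / 2)
  }
})

test_that("cohort matrix has one row per assembly with optional extras", {
  ctg <- tibble::tibble(contig_id = c("x", "y"), length = c(100, 60))
  a1 <- assembly("a1", ctg)
  a2 <- assembly("a2", ctg, tibble::tibble(
    contig_id = "x", feature = c("HIGH_LINKING_CVG", "HIGH_SPANNING_CVG", "HIGH_SPANNING_CVG"),
    start = c(0, 10, 20), end = c(5, 15, 25)
  ))
  m <- build_feature_matrix(list(a1, a2))
  expect_equal(dim(m), c(2, 1 + 11 + 2))
  expect_equal(m$NUM_CONTIG, c(2, 2))
  expect_equal(m$N50, c(100, 100))
  expect_equal(m$HIGH_LINKING_SPANNING_CVG, c(0, 3))
  m11 <- build_feature_matrix(list(a1, a2), include_n50 = FALSE, include_num_contig = FALSE)
  expect_equal(ncol(m11), 12) # label + 11
  expect_error(build_feature_matrix(list(a1)), "at least 2")

  # CSV round trip
  f <- tempfile(fileext = ".csv")
  write_feature_matrix(m, f)
  expect_equal(as.data.frame(read_feature_matrix(f)), as.data.frame(m))
})

test_that("assembly constructor enforces its invariants", {
  ctg <- tibble::tibble(contig_id = "a", length = 100)
  expect_error(
    assembly("x", ctg, tibble::tibble(
      contig_id = "b", feature = "HIGH_SNP", start = 1, end = 2
    )),
    "unknown contig"
  )
  expect_error(
    assembly("x", ctg, tibble::tibble(
      contig_id = "a", feature = "HIGH_SNP", start = 90, end = 120
    )),
    "outside contig bounds"
  )
  expect_error(assembly("x", ctg, genome_size = 50), "genome_size")
})
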