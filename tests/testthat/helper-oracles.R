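# Independent brute-force oracles and tiny fixture builders used across the
# suite. These deliberately re-derive results by enumeration, not by calling
# the implementation paths they check.

# random toy assembly: <= max_contigs contigs, per-contig feature totals
# already tallied (we bypass records and give counts directly)
random_counted_assembly <- function(seed, max_contigs = 20, max_count = 5) {
  set.seed(seed)
  n <- sample(2:max_contigs, 1)
  tibble::tibble(
    contig_id = sprintf("c%02d", seq_len(n)),
    length = sample(50:5000, n, replace = TRUE),
    count = sample(0:max_count, n, replace = TRUE)
  )
}

# exhaustive FRC: for each phi walk the length-sorted order and accumulate
frc_oracle <- function(contigs_counts, genome_size, thresholds) {
  ord <- order(-contigs_counts$length, contigs_counts$contig_id)
  len <- contigs_counts$length[ord]
  cnt <- contigs_counts$count[ord]
  vapply(thresholds, function(phi) {
    tot <- 0
    covered <- 0
    for (i in seq_along(len)) {
      tot <- tot + cnt[i]
      if (tot > phi) break
      covered <- covered + len[i]
    }
    covered / genome_size
  }, numeric(1))
}

# count table with a single per-contig total column driving compute_frc
counts_from_totals <- function(contigs_counts) {
  tibble::tibble(
    contig_id = contigs_counts$contig_id,
    BREAKPOINT = contigs_counts$count,
    total = contigs_counts$count
  )
}

# quadratic all-pairs interval intersection (0-based half-open)
overlap_oracle <- function(features, intervals) {
  vapply(seq_len(nrow(features)), function(i) {
    any(vapply(seq_len(nrow(intervals)), function(j) {
      features$contig_id[i] == intervals$contig_id[j] &&
        max(features$start[i], intervals$start[j]) <
          min(features$end[i], intervals$end[j])
    }, logical(1)))
  }, logical(1))
}

# Laplace sampler (unit variance) for planted-source tests
rlaplace <- function(n) {
  u <- runif(n) - 0.5
  -sign(u) * log(1 - 2 * abs(u)) / sqrt(2)
}

feature_file_lines <- c(
  "# demo feature file",
  "ctg1 HIGH_SNP 500 500",
  "ctg1\tKMER_COV\t100\t25100",
  "ctg2 LOW_GOOD_CVG 0 1500 low coverage stretch"
)

write_tmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}
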