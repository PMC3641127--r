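# Fixture builders and independent oracles used across the suite.

# random annotation on two chromosomes, 0-based half-open
rand_annotation <- function(n_tx, max_pos = 10000L) {
  start <- sample.int(max_pos, n_tx, replace = TRUE) - 1L
  len <- sample(20:500, n_tx, replace = TRUE)
  data.frame(
    gene_id = sprintf("g%03d", ceiling(seq_len(n_tx) / 2)),
    transcript_id = sprintf("t%03d", seq_len(n_tx)),
    chrom = sample(c("chr1", "chr2"), n_tx, replace = TRUE),
    strand = sample(c("+", "-"), n_tx, replace = TRUE),
    start = start, end = start + len,
    stringsAsFactors = FALSE
  ) |> transform(tss = ifelse(strand == "+", start, end - 1L),
                 length = end - start)
}

rand_reads <- function(n, max_pos = 10000L, chroms = c("chr1", "chr2")) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + sample(20:50, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# exhaustive all-pairs interval-overlap oracle for gene-body counting
brute_count <- function(reads, ann) {
  vapply(seq_len(nrow(ann)), function(i) {
    sum(reads$chrom == ann$chrom[i] &
          reads$start < ann$end[i] &
          reads$end > ann$start[i])
  }, integer(1))
}

# literal O(n^2) dominance-count definition
brute_dominance <- function(e, m) {
  n <- length(e)
  out <- integer(n)
  for (i in seq_len(n)) {
    c_i <- 0L
    for (j in seq_len(n)) {
      if (j != i && e[j] > e[i] && m[j] < m[i]) c_i <- c_i + 1L
    }
    out[i] <- c_i
  }
  stats::setNames(out, names(e))
}

# one-sided KS statistic from the ECDF definition ("greater": a larger)
ecdf_ks_stat <- function(a, b, alternative) {
  grid <- sort(unique(c(a, b)))
  fa <- stats::ecdf(a)(grid)
  fb <- stats::ecdf(b)(grid)
  if (alternative == "greater") max(fb - fa) else max(fa - fb)
}

# permutation-based one-sided KS p-value (independent of stats::ks.test)
perm_ks_pvalue <- function(a, b, alternative, n_perm = 10000L) {
  obs <- ecdf_ks_stat(a, b, alternative)
  pooled <- c(a, b)
  na <- length(a)
  hits <- 0L
  for (k in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), na)
    if (ecdf_ks_stat(pooled[idx], pooled[-idx], alternative) >= obs - 1e-12)
      hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# tiny simulation config for fast structural tests
small_config <- function(seed = 1L, ...) {
  simulation_config(n_genes = 80L, n_tfs = 30L, n_planted = 5L,
                    mean_depth = 25, seed = seed, ...)
}
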