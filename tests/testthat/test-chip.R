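test_that("gene-body counting follows half-open overlap semantics", {
  ann <- data.frame(gene_id = "gA", transcript_id = "t1", chrom = "chr1",
                    strand = "+", start = 100L, end = 200L, tss = 100L,
                    length = 100L)
  reads <- data.frame(chrom = "chr1",
                      start = c(150L, 190L, 300L),
                      end = c(186L, 210L, 320L))
  cnt <- count_gene_body_reads(reads, ann)
  expect_equal(cnt$count, 2L)

  # half-open abutment is zero overlap
  abut <- data.frame(chrom = "chr1", start = 200L, end = 236L)
  expect_equal(count_gene_body_reads(abut, ann)$count, 0L)

  # no reads at all
  none <- data.frame(chrom = character(), start = integer(),
                     end = integer())
  expect_equal(count_gene_body_reads(none, ann)$count, 0L)

  # unknown chromosome: skipped, tallied
  expect_message(
    cnt2 <- count_gene_body_reads(
      data.frame(chrom = c("chrX", "chr1"), start = c(100L, 100L),
                 end = c(150L, 150L)), ann),
    "1 read")
  expect_equal(cnt2$count, 1L)
  expect_equal(attr(cnt2, "n_skipped"), 1L)
})

test_that("counting equals the exhaustive pairwise-overlap oracle", {
  set.seed(101)
  for (i in 1:30) {
    ann <- rand_annotation(sample(5:50, 1))
    reads <- rand_reads(sample(10:500, 1))
    fast <- count_gene_body_reads(reads, ann)$count
    expect_identical(fast, brute_count(reads, ann))
  }
})

test_that("length normalization adds a pseudo-read and Z-scores the log", {
  counts <- data.frame(transcript_id = c("t1", "t2"),
                       count = c(10L, 20L), length = c(1000L, 2000L))
  prof <- chip_zscore_profile(counts, cell_type = "cellA")
  # normalized values are (10+1)/1 = 11 and (20+1)/2 = 10.5 reads/kb
  expect_equal(unname(prof$values), unname(zscore(log(c(11, 10.5)))))
  expect_false(prof$input_corrected)

  flat <- data.frame(transcript_id = c("t1", "t2"),
                     count = c(5L, 5L), length = c(100L, 100L))
  expect_error(chip_zscore_profile(flat, cell_type = "x"), "constant")
  expect_error(chip_zscore_profile(
    data.frame(transcript_id = "t", count = 1L, length = 0L),
    cell_type = "x"), "length")
})

test_that("Z-scores are invariant to depth scaling in the large-count limit", {
  set.seed(5)
  counts <- data.frame(transcript_id = sprintf("t%02d", 1:40),
                       count = rpois(40, 5000), length = 1000L)
  doubled <- transform(counts, count = count * 2L)
  z1 <- chip_zscore_profile(counts, cell_type = "x")$values
  z2 <- chip_zscore_profile(doubled, cell_type = "x")$values
  expect_equal(z1, z2, tolerance = 1e-3)
})

test_that("input correction subtracts the input Z-score per transcript", {
  set.seed(2)
  v <- stats::setNames(rnorm(50), sprintf("t%02d", 1:50))
  chip <- zscore_profile(v, "H3K27me3", "cellA")
  same <- input_correct(chip, chip)
  expect_true(all(same$values == 0))
  expect_true(same$input_corrected)

  inp <- zscore_profile(v + rnorm(50), "H3K27me3", "cellA")
  corr <- input_correct(chip, inp)
  expect_equal(corr$values, chip$values - inp$values)
  expect_error(input_correct(corr, inp), "already")
})

test_that("input correction and differencing commute", {
  set.seed(3)
  ids <- sprintf("t%02d", 1:60)
  mk <- function() zscore_profile(stats::setNames(rnorm(60), ids),
                                  "H3K27me3", "c")
  chip_a <- mk(); chip_b <- mk(); in_a <- mk(); in_b <- mk()
  d_corrected <- differential_profile(input_correct(chip_b, in_b),
                                      input_correct(chip_a, in_a))$values
  d_raw <- differential_profile(chip_b, chip_a)$values -
    differential_profile(in_b, in_a)$values
  expect_equal(d_corrected, d_raw, tolerance = 1e-12)
})

test_that("isoform collapse keeps the largest-magnitude dZ with deterministic ties", {
  gm <- data.frame(transcript_id = c("t1", "t2", "t3", "t4", "t5"),
                   gene_id = c("gA", "gA", "gB", "gC", "gC"))
  diff <- structure(list(feature = "H3K27me3", source_cell = "a",
                         target_cell = "b",
                         values = c(t1 = -2.5, t2 = 1.0, t3 = 0.7,
                                    t4 = 1.0, t5 = 1.0),
                         level = "entity"),
                    class = "differential_profile")
  g <- collapse_isoforms(diff, gm)
  expect_equal(g$values, c(gA = -2.5, gB = 0.7, gC = 1.0))
  expect_equal(attr(g, "chosen_transcript")[["gC"]], "t4")
  expect_equal(g$level, "gene")
})

test_that("gene-level differential is antisymmetric under cell-type swap", {
  set.seed(8)
  ids <- sprintf("t%02d", 1:40)
  gm <- data.frame(transcript_id = ids,
                   gene_id = rep(sprintf("g%02d", 1:20), each = 2))
  pa <- zscore_profile(stats::setNames(rnorm(40), ids), "H3K27me3", "a")
  pb <- zscore_profile(stats::setNames(rnorm(40), ids), "H3K27me3", "b")
  fwd <- collapse_isoforms(differential_profile(pb, pa), gm)$values
  rev <- collapse_isoforms(differential_profile(pa, pb), gm)$values
  expect_identical(fwd, -rev[names(fwd)])
})
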