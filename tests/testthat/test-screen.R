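test_that("dominance counts follow the strict two-criteria definition", {
  expect_equal(dominance_count(c(A = 1), c(A = -1)), c(A = 0L))

  cnt <- dominance_count(c(A = 2, B = 1, C = 0),
                         c(A = -3, B = -1, C = 0))
  expect_equal(cnt, c(A = 0L, B = 1L, C = 2L))

  # identical points do not dominate one another
  dup <- dominance_count(c(A = 1, B = 1), c(A = -1, B = -1))
  expect_equal(dup, c(A = 0L, B = 0L))

  expect_message(
    with_na <- dominance_count(c(A = 1, B = NA, C = 0),
                               c(A = -1, B = 0, C = 1)),
    "1 TF")
  expect_equal(names(with_na), c("A", "C"))
})

test_that("dominance counts match the literal O(n^2) oracle on random instances", {
  set.seed(77)
  for (i in 1:12) {
    n <- sample(2:200, 1)
    e <- stats::setNames(round(rnorm(n), sample(c(1, 6), 1)),
                         sprintf("tf%03d", 1:n))
    m <- stats::setNames(round(rnorm(n), sample(c(1, 6), 1)), names(e))
    expect_identical(dominance_count(e, m), brute_dominance(e, m))
  }
})

test_that("single-feature ranking directions and tie handling", {
  r <- rank_single_feature(c(a = 2, b = 0, c = -1), "descending")
  expect_equal(r$gene_id, c("a", "b", "c"))
  expect_equal(r$rank, 1:3)

  r2 <- rank_single_feature(c(a = -3, b = 0, c = 1), "ascending")
  expect_equal(r2$gene_id, c("a", "b", "c"))

  r3 <- rank_single_feature(c(a = 2, b = 0, c = -1), "ascending")
  expect_equal(r3$gene_id, rev(r$gene_id))

  tied <- rank_single_feature(c(b = 1, a = 1, c = 0), "descending")
  expect_equal(tied$gene_id, c("a", "b", "c"))  # tie ordered by id
  expect_equal(tied$rank, c(1L, 1L, 3L))        # smallest applicable rank
})

test_that("recovery curves count known factors along the ranked list", {
  cv <- recovery_curve(c(A = 1, B = 2, C = 3, D = 4), known = c("A", "C"))
  expect_equal(cv$position, 1:4)
  expect_equal(cv$fraction, c(0.5, 0.5, 1.0, 1.0))

  all_known <- recovery_curve(c(A = 1, B = 2), known = c("A", "B"))
  expect_equal(all_known$fraction[all_known$position == 2], 1.0)

  bottom <- recovery_curve(c(A = 1, B = 2, C = 3), known = "C")
  expect_equal(bottom$fraction, c(0, 0, 1))

  expect_error(recovery_curve(c(A = 1), known = character()), "empty")
  expect_warning(cv2 <- recovery_curve(c(A = 1, B = 2), known = c("A", "Z")),
                 "absent")
  expect_equal(attr(cv2, "n_known"), 1L)
})

test_that("recovery curves are monotone and terminate at 1 on random inputs", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(5:100, 1)
    scores <- stats::setNames(sample.int(20, n, replace = TRUE),
                              sprintf("tf%03d", 1:n))
    known <- sample(names(scores), sample(1:5, 1))
    cv <- recovery_curve(scores, known)
    expect_true(all(diff(cv$position) > 0))
    expect_true(all(diff(cv$fraction) >= 0))
    expect_equal(cv$fraction[nrow(cv)], 1.0)
    sm <- smooth_ties(cv)
    expect_identical(as.data.frame(smooth_ties(sm)), as.data.frame(sm))
    expect_setequal(unique(sm$fraction), unique(cv$fraction))
  }
})

test_that("tie smoothing keeps the most highly ranking position per fraction", {
  cv <- structure(data.frame(position = 1:4,
                             fraction = c(0.5, 0.5, 1.0, 1.0)),
                  class = c("recovery_curve", "data.frame"),
                  n_known = 2L, n_universe = 4L, smoothed = FALSE)
  sm <- smooth_ties(cv)
  expect_equal(sm$position, c(1L, 3L))
  expect_equal(sm$fraction, c(0.5, 1.0))

  flat <- structure(data.frame(position = 1:2, fraction = c(1, 1)),
                    class = c("recovery_curve", "data.frame"),
                    n_known = 1L, n_universe = 2L, smoothed = FALSE)
  expect_equal(nrow(smooth_ties(flat)), 1L)
})

test_that("signature box thresholds come from the anchors and are inclusive", {
  e <- c(k = 2, a = 3, b = 1, c = 3)
  m <- c(k = -3, a = -4, b = -4, c = -2)
  box <- select_signature_box(e, m, anchors = "k")
  expect_equal(box$dz_expr_min, 2)
  expect_equal(box$dz_mod_max, -3)
  expect_setequal(box$selected, c("k", "a"))

  # boundary candidate is selected (inclusive thresholds)
  e2 <- c(k = 2, x = 2); m2 <- c(k = -3, x = -3)
  expect_setequal(select_signature_box(e2, m2, "k")$selected, c("k", "x"))

  # anchors alone in the universe select exactly themselves
  expect_setequal(select_signature_box(c(k = 1), c(k = -1), "k")$selected,
                  "k")
  expect_error(select_signature_box(e, m, character()), "empty")
})

test_that("enlarging the signature box never removes a selected TF", {
  set.seed(21)
  e <- stats::setNames(rnorm(200), sprintf("tf%03d", 1:200))
  m <- stats::setNames(rnorm(200), names(e))
  anchors_small <- names(sort(e, decreasing = TRUE))[1:3]
  anchors_big <- c(anchors_small, sample(names(e), 10))
  small <- select_signature_box(e, m, anchors_small)
  big <- select_signature_box(e, m, anchors_big)
  expect_true(big$dz_expr_min <= small$dz_expr_min)
  expect_true(big$dz_mod_max >= small$dz_mod_max)
  expect_true(all(small$selected %in% big$selected))
})

test_that("fold enrichment follows its closed form", {
  expect_equal(fold_enrichment(3, 0, 1447), 1444 / 3, tolerance = 1e-12)
  expect_equal(round(fold_enrichment(3, 0, 1447), 2), 481.33)
  expect_error(fold_enrichment(0, 5, 100), "n_known")
  expect_error(fold_enrichment(3, 98, 100), "exceed")
})

test_that("one-sided KS statistics behave at the extremes", {
  same <- ks_one_sided(c(1, 2, 3), c(1, 2, 3), "greater")
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  disj <- ks_one_sided(c(10, 11, 12), c(0, 1, 2), "greater")
  expect_equal(disj$statistic, 1)
  wrong_dir <- ks_one_sided(c(10, 11, 12), c(0, 1, 2), "less")
  expect_equal(wrong_dir$statistic, 0)

  expect_error(ks_one_sided(numeric(), 1:3), "non-empty")
})

test_that("KS p-values agree with a permutation oracle", {
  set.seed(31)
  for (i in 1:4) {
    a <- rnorm(10, mean = runif(1, 0, 1.5))
    b <- rnorm(12)
    alt <- sample(c("greater", "less"), 1)
    ours <- ks_one_sided(a, b, alt)
    expect_equal(ours$statistic, ecdf_ks_stat(a, b, alt), tolerance = 1e-12)
    p_perm <- perm_ks_pvalue(a, b, alt, n_perm = 10000L)
    expect_equal(ours$p.value, p_perm, tolerance = 0.05)
  }
})

test_that("group means average the profile over the group", {
  dz <- c(g1 = 1, g2 = 2, g3 = 3)
  expect_equal(group_mean_dz(dz, "g2"), 2)
  expect_equal(group_mean_dz(dz, names(dz)), 2)
  # weighted average of group and complement reconstructs the global mean
  set.seed(14)
  big <- stats::setNames(rnorm(500), sprintf("g%03d", 1:500))
  grp <- sample(names(big), 80)
  rest <- setdiff(names(big), grp)
  recon <- (group_mean_dz(big, grp) * 80 +
              group_mean_dz(big, rest) * 420) / 500
  expect_equal(recon, mean(big), tolerance = 1e-12)
  expect_error(group_mean_dz(dz, "nope"), "intersect")
})

test_that("run_screen assembles ranks, selection and enrichment coherently", {
  set.seed(99)
  n <- 60
  e <- stats::setNames(rnorm(n), sprintf("tf%02d", 1:n))
  m <- stats::setNames(rnorm(n), names(e))
  known <- names(sort(e - m, decreasing = TRUE))[1:3]  # good corner
  res <- run_screen(e, m, names(e), known = known,
                    pair = c(source = "a", target = "b"))
  expect_s3_class(res, "screen_result")
  expect_equal(nrow(res), n)
  expect_equal(sort(unique(res$rank))[1], 1L)
  expect_true(all(res$dominance_count < n))
  expect_true(all(res$known[match(known, res$gene_id)]))
  expect_true(all(res$selected[res$known]))  # anchors always selected
  thr <- attr(res, "thresholds")
  inside <- res$dz_expr >= thr["dz_expr_min"] & res$dz_mod <= thr["dz_mod_max"]
  expect_equal(res$selected, unname(inside))
  expect_equal(attr(res, "enrichment"),
               fold_enrichment(3, sum(res$selected) - 3, n))
  summ <- screen_summary(res)
  expect_equal(summ$n_tfs, n)
  expect_true(summ$ks_p_expr >= 0 && summ$ks_p_expr <= 1)
})
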