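#' Pareto dominance count on the screen plane
#'
#' For every TF, counts the other TFs that are strictly better on both
#' screen criteria: greater differential expression AND lower differential
#' modification. A count of 0 marks the two-dimensional Pareto front;
#' smaller counts rank better. Identical points do not dominate one another
#' (strict inequalities).
#'
#' @param dz_expr,dz_mod Named numeric vectors over the same TF ids
#'   (differential expression and differential modification). TFs with a
#'   missing value in either vector are excluded with a message.
#' @return Named integer vector of dominance counts.
#' @examples
#' dominance_count(c(A = 2, B = 1, C = 0), c(A = -3, B = -1, C = 0))
#' @export
dominance_count <- function(dz_expr, dz_mod) {
  if (is.null(names(dz_expr)) || is.null(names(dz_mod)))
    stop("dz_expr and dz_mod must be named by TF id")
  ids <- intersect(names(dz_expr), names(dz_mod))
  if (length(ids) == 0L) stop("no shared TF ids")
  e <- dz_expr[ids]; m <- dz_mod[ids]
  ok <- !is.na(e) & !is.na(m)
  if (any(!ok))
    message(sum(!ok), " TF(s) with missing values excluded")
  ids <- ids[ok]; e <- e[ok]; m <- m[ok]
  n <- length(ids)
  if (n == 0L) stop("no TFs with complete values")
  # count(i) = #{j : e[j] > e[i] & m[j] < m[i]}
  counts <- integer(n)
  if (n > 1L) {
    dom <- outer(e, e, ">") & outer(m, m, "<")  # [j, i]
    counts <- as.integer(colSums(dom))
  }
  stats::setNames(counts, ids)
}

#' Rank TFs by a single differential feature
#'
#' Ranks descending for expression (most target-enriched first) or
#' ascending for modification (most source-repressed first). Tied values
#' share the smallest applicable rank; within a tie, rows are ordered
#' deterministically by gene id.
#'
#' @param values Named numeric vector of dZ values.
#' @param direction `"descending"` (expression) or `"ascending"`
#'   (modification).
#' @return `data.frame` with columns `gene_id`, `value`, `rank`, ordered by
#'   rank then gene id.
#' @export
rank_single_feature <- function(values,
                                direction = c("descending", "ascending")) {
  direction <- match.arg(direction)
  if (is.null(names(values))) stop("values must be named by TF id")
  if (length(values) == 0L) stop("no values to rank")
  key <- if (direction == "descending") -values else values
  rk <- rank(key, ties.method = "min")
  ord <- order(key, names(values))
  data.frame(gene_id = names(values)[ord],
             value = as.numeric(values[ord]),
             rank = as.integer(rk[ord]),
             stringsAsFactors = FALSE)
}

#' Recovery curve of known factors along a ranked list
#'
#' Computes, at each distinct score threshold, the fraction of known
#' transdifferentiation factors recovered among all TFs ranked at or better
#' than the threshold. `scores` are "smaller is better": ranks from
#' [rank_single_feature()] for single-feature rankings, dominance counts
#' from [dominance_count()] for the combined ranking (where the list
#' position at threshold `c` is the number of TFs with dominance count
#' `<= c`). Known factors absent from the ranked universe are excluded
#' from the denominator with a warning.
#'
#' @param scores Named numeric vector over the TF universe, smaller = better.
#' @param known Character vector of known factor ids.
#' @return A `recovery_curve` data.frame with columns `position` (number of
#'   TFs at-or-better), `fraction` (recovered fraction in \[0,1\]), and
#'   attributes `n_known`, `n_universe`, `smoothed = FALSE`. Positions are
#'   strictly increasing and fractions non-decreasing, ending at 1 when the
#'   full list is traversed.
#' @examples
#' recovery_curve(c(A = 1, B = 2, C = 3, D = 4), known = c("A", "C"))
#' @export
recovery_curve <- function(scores, known) {
  if (is.null(names(scores))) stop("scores must be named by TF id")
  if (length(known) == 0L) stop("empty known-factor set")
  known <- unique(as.character(known))
  absent <- setdiff(known, names(scores))
  if (length(absent) == length(known))
    stop("no known factor present in the ranked universe")
  if (length(absent))
    warning(length(absent), " known factor(s) absent from the ranked ",
            "universe excluded from the denominator: ",
            paste(head(absent, 5L), collapse = ", "))
  known <- setdiff(known, absent)
  thresholds <- sort(unique(scores))
  position <- vapply(thresholds, function(s) sum(scores <= s), integer(1))
  recovered <- vapply(thresholds,
                      function(s) sum(scores[known] <= s), integer(1))
  out <- data.frame(position = position,
                    fraction = recovered / length(known))
  structure(out, class = c("recovery_curve", "data.frame"),
            n_known = length(known), n_universe = length(scores),
            smoothed = FALSE)
}

#' Smooth a recovery curve over tied positions
#'
#' Tie resolution for ranked lists: where multiple positions recover the
#' same fraction of known factors, only the most highly ranking (smallest)
#' position is retained, yielding a sparse, still non-decreasing step
#' function. The operation is idempotent.
#'
#' @param curve A `recovery_curve` from [recovery_curve()].
#' @return The smoothed `recovery_curve` (`smoothed = TRUE`).
#' @export
smooth_ties <- function(curve) {
  if (nrow(curve) == 0L) stop("empty recovery curve")
  keep <- !duplicated(curve$fraction)
  out <- curve[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("recovery_curve", "data.frame"),
            n_known = attr(curve, "n_known"),
            n_universe = attr(curve, "n_universe"),
            smoothed = TRUE)
}

#' Fraction of known factors recovered within the top of the list
#'
#' Reads a recovery curve at a list position (e.g. the top 2% of the TF
#' universe). TFs tied at a score share the smallest applicable rank
#' (competition ranking, as in the screen's `rank` column), so a tied
#' block counts as recovered when the block begins at or before the
#' cutoff; for tie-free rankings this is simply the fraction at the
#' largest position not exceeding the cutoff.
#'
#' @param curve A `recovery_curve`.
#' @param top_fraction Fraction of the ranked universe to traverse (e.g.
#'   `0.02`).
#' @return Recovered fraction in \[0, 1\].
#' @export
recovery_at <- function(curve, top_fraction = 0.02) {
  cutoff <- top_fraction * attr(curve, "n_universe")
  block_start <- c(1, head(curve$position, -1) + 1)
  hit <- block_start <= cutoff
  if (!any(hit)) return(0)
  max(curve$fraction[hit])
}

#' Select the signature box around known anchor factors
#'
#' Draws the most permissive axis-aligned box that contains all anchor
#' (known) factors on the screen plane: differential expression at least
#' the anchors' minimum AND differential modification at most the anchors'
#' maximum (both thresholds inclusive, so anchors are always selected).
#' Single-feature variants apply only the corresponding threshold.
#'
#' @param dz_expr,dz_mod Named numeric vectors over the TF universe.
#' @param anchors Character vector of anchor TF ids; all must have both
#'   values.
#' @param feature `"both"` (the two-criteria box), `"expression"` or
#'   `"modification"` (one-sided variants).
#' @return List with `selected` (character vector of TF ids),
#'   `dz_expr_min`, `dz_mod_max`.
#' @export
select_signature_box <- function(dz_expr, dz_mod, anchors,
                                 feature = c("both", "expression",
                                             "modification")) {
  feature <- match.arg(feature)
  if (length(anchors) == 0L) stop("empty anchor set")
  anchors <- unique(as.character(anchors))
  if (!all(anchors %in% names(dz_expr)) || !all(anchors %in% names(dz_mod)))
    stop("anchor(s) missing dZ values: ",
         paste(head(setdiff(anchors, intersect(names(dz_expr),
                                               names(dz_mod))), 5L),
               collapse = ", "))
  ids <- intersect(names(dz_expr), names(dz_mod))
  e <- dz_expr[ids]; m <- dz_mod[ids]
  expr_min <- min(dz_expr[anchors])
  mod_max <- max(dz_mod[anchors])
  inside <- switch(feature,
    both = e >= expr_min & m <= mod_max,
    expression = e >= expr_min,
    modification = m <= mod_max
  )
  inside[is.na(inside)] <- FALSE
  list(selected = ids[inside],
       dz_expr_min = as.numeric(expr_min),
       dz_mod_max = as.numeric(mod_max))
}

#' Fold enrichment of known factors in a selected set
#'
#' Enrichment of the selected set for known transdifferentiation factors
#' relative to all TFs in the genome:
#' `(n_total - n_known) / (n_known + n_other_selected)` — the factor by
#' which selecting the box beats the background rate of known factors among
#' the remaining TFs. Reported values are conventionally rounded to the
#' nearest integer.
#'
#' @param n_known Number of known factors (all inside the box by
#'   construction); must be >= 1.
#' @param n_other_selected Number of other (non-known) TFs in the box.
#' @param n_total Total number of annotated TFs in the genome.
#' @return Unrounded fold enrichment (numeric scalar).
#' @examples
#' round(fold_enrichment(3, 9, 1447)) # 120
#' @export
fold_enrichment <- function(n_known, n_other_selected, n_total) {
  if (n_known < 1) stop("n_known must be at least 1")
  if (n_other_selected < 0) stop("n_other_selected must be non-negative")
  if (n_total <= n_known + n_other_selected)
    stop("n_total must exceed the selected set size")
  (n_total - n_known) / (n_known + n_other_selected)
}

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' Compares two groups of dZ values with a one-sided KS test. With
#' `alternative = "greater"`, the alternative hypothesis is that `group_a`
#' is stochastically larger than `group_b` (its ECDF lies below); used for
#' differential expression of known factors versus other TFs. With
#' `"less"`, that `group_a` is stochastically smaller; used for
#' differential modification. The statistic is the signed supremum of the
#' ECDF difference in the alternative's direction.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param alternative `"greater"` or `"less"` (direction for `group_a`).
#' @return List with `statistic` (D) and `p.value`.
#' @export
ks_one_sided <- function(group_a, group_b,
                         alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be non-empty")
  # stats::ks.test's "less" alternative is "ECDF of x below y", i.e. x
  # stochastically larger -- the opposite naming of this function's contract.
  r_alt <- if (alternative == "greater") "less" else "greater"
  res <- suppressWarnings(stats::ks.test(group_a, group_b,
                                         alternative = r_alt))
  list(statistic = unname(res$statistic), p.value = res$p.value,
       alternative = alternative)
}

#' Mean differential score of a gene group
#'
#' Arithmetic mean of dZ over the group's genes present in the profile
#' (e.g. the mean dZ-expression of known transdifferentiation factors).
#'
#' @param diff A `differential_profile` or a named numeric vector of dZ.
#' @param group Character vector of gene ids.
#' @return Numeric scalar.
#' @export
group_mean_dz <- function(diff, group) {
  values <- if (inherits(diff, "differential_profile")) diff$values else diff
  if (is.null(names(values))) stop("dZ values must be named by gene id")
  hit <- intersect(group, names(values))
  if (length(hit) == 0L) stop("group does not intersect the profile")
  mean(values[hit])
}

#' Run the two-criteria transdifferentiation screen
#'
#' Assembles the full screen for one ordered cell-type pair: per-TF
#' dominance counts and ranks on the (dZ-expression, dZ-modification)
#' plane, signature-box selection anchored on the known factors, and the
#' known-factor flags.
#'
#' @param dz_expr,dz_mod Named numeric vectors of gene-level differential
#'   scores (target minus source); may cover the whole genome — they are
#'   subset to `tf_ids`.
#' @param tf_ids Character vector: the TF universe (e.g. from
#'   [read_tf_catalog()]).
#' @param known Character vector of known transdifferentiation factors for
#'   this pair (used as box anchors); may be empty, in which case no box is
#'   drawn and `selected` is `FALSE` everywhere.
#' @param pair Optional `c(source, target)` cell-type labels.
#' @return A `screen_result` data.frame with columns `gene_id`, `dz_expr`,
#'   `dz_mod`, `dominance_count`, `rank`, `selected`, `known`, ordered by
#'   rank then gene id; attributes `thresholds`, `pair`, `n_total`,
#'   `enrichment` (the two-criteria fold enrichment, `NA` without known
#'   anchors).
#' @export
run_screen <- function(dz_expr, dz_mod, tf_ids, known = character(),
                       pair = c(source = NA_character_,
                                target = NA_character_)) {
  tf_ids <- unique(as.character(tf_ids))
  ids <- intersect(tf_ids, intersect(names(dz_expr), names(dz_mod)))
  if (length(ids) == 0L) stop("no TFs with both differential scores")
  dropped <- length(tf_ids) - length(ids)
  if (dropped > 0L)
    message(dropped, " TF(s) without both differential scores excluded")
  e <- dz_expr[ids]; m <- dz_mod[ids]
  counts <- dominance_count(e, m)
  rk <- rank(counts, ties.method = "min")
  known <- intersect(unique(as.character(known)), ids)
  if (length(known) > 0L) {
    box <- select_signature_box(e, m, anchors = known)
    selected <- ids %in% box$selected
    thresholds <- c(dz_expr_min = box$dz_expr_min,
                    dz_mod_max = box$dz_mod_max)
    enr <- fold_enrichment(length(known),
                           sum(selected) - length(known),
                           length(ids))
  } else {
    selected <- rep(FALSE, length(ids))
    thresholds <- c(dz_expr_min = NA_real_, dz_mod_max = NA_real_)
    enr <- NA_real_
  }
  out <- data.frame(
    gene_id = ids,
    dz_expr = as.numeric(e),
    dz_mod = as.numeric(m),
    dominance_count = as.integer(counts),
    rank = as.integer(rk),
    selected = selected,
    known = ids %in% known,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$rank, out$gene_id), ]
  rownames(out) <- NULL
  structure(out, class = c("screen_result", "data.frame"),
            thresholds = thresholds, pair = pair,
            n_total = length(ids), enrichment = enr)
}

#' Summarize a screen result
#'
#' Group means, one-sided KS comparisons of known factors versus all other
#' TFs, and the signature-box fold enrichment.
#'
#' @param result A `screen_result` from [run_screen()].
#' @return A one-row `data.frame`: `n_tfs`, `n_known`, `n_selected`,
#'   `mean_dz_expr_known`, `mean_dz_mod_known`, `mean_dz_expr_other`,
#'   `mean_dz_mod_other`, `ks_p_expr`, `ks_p_mod`, `fold_enrichment`.
#' @export
screen_summary <- function(result) {
  stopifnot(inherits(result, "screen_result"))
  kn <- result$known
  if (!any(kn)) stop("screen result has no known factors to summarize")
  ks_e <- ks_one_sided(result$dz_expr[kn], result$dz_expr[!kn], "greater")
  ks_m <- ks_one_sided(result$dz_mod[kn], result$dz_mod[!kn], "less")
  data.frame(
    n_tfs = nrow(result),
    n_known = sum(kn),
    n_selected = sum(result$selected),
    mean_dz_expr_known = mean(result$dz_expr[kn]),
    mean_dz_mod_known = mean(result$dz_mod[kn]),
    mean_dz_expr_other = mean(result$dz_expr[!kn]),
    mean_dz_mod_other = mean(result$dz_mod[!kn]),
    ks_p_expr = ks_e$p.value,
    ks_p_mod = ks_m$p.value,
    fold_enrichment = attr(result, "enrichment")
  )
}
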