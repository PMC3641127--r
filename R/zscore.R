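#' Log-transform TPM expression values
#'
#' Maps TPM to the natural log scale as `log(1 + TPM)`, the transform applied
#' to expression before Z-scoring. Zero TPM maps to zero; the transform is
#' strictly monotone.
#'
#' @param tpm Named numeric vector of non-negative TPM values.
#' @return Named numeric vector of log(1 + TPM) values.
#' @examples
#' log1p_expression(c(gA = 0, gB = exp(1) - 1, gC = 999))
#' @export
log1p_expression <- function(tpm) {
  if (!is.numeric(tpm)) stop("tpm must be numeric")
  if (any(tpm < 0, na.rm = TRUE)) stop("negative TPM value(s) supplied")
  log1p(tpm)
}

#' Z-score a vector of values
#'
#' Standardizes values to mean 0 and sample (n-1) standard deviation 1:
#' the number of standard deviations each entity lies from the mean. The
#' operation is affine-invariant (`zscore(a*x + b) == zscore(x)` for `a > 0`)
#' and idempotent.
#'
#' @param values Numeric vector (length >= 2, non-constant). `NA`s are
#'   dropped from the mean/sd computation and propagated in the output.
#' @return Numeric vector of Z-scores, names preserved.
#' @examples
#' zscore(c(1, 2, 3)) # -1 0 1
#' @export
zscore <- function(values) {
  if (!is.numeric(values)) stop("values must be numeric")
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("zscore needs at least 2 non-missing values")
  s <- sd(values[ok])
  if (!is.finite(s) || s == 0)
    stop("zscore undefined for constant input (zero variance)")
  (values - mean(values[ok])) / s
}

#' Build a per-entity feature profile of Z-scores
#'
#' Z-scores a vector of per-entity measurements (log-expression or
#' log-normalized modification signal) for one feature in one cell type.
#' Before input correction every profile satisfies mean 0 / sample sd 1
#' over its non-missing entities.
#'
#' @param values Named numeric vector (entity id -> measurement, already on
#'   the scale to be Z-scored, e.g. log(1+TPM)).
#' @param feature One of `"expression"`, `"H3K27me3"`, `"H3K9me3"`.
#' @param cell_type Cell-type label.
#' @return A `feature_profile` object: list with `feature`, `cell_type`,
#'   `values` (named Z-scores) and `input_corrected = FALSE`.
#' @export
zscore_profile <- function(values,
                           feature = c("expression", "H3K27me3", "H3K9me3"),
                           cell_type) {
  feature <- match.arg(feature)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("values must be named by entity id")
  if (anyDuplicated(names(values)))
    stop("duplicate entity ids in values")
  structure(
    list(feature = feature, cell_type = as.character(cell_type),
         values = zscore(values), input_corrected = FALSE),
    class = "feature_profile"
  )
}

#' @export
print.feature_profile <- function(x, ...) {
  cat("<feature_profile> ", x$feature, " in ", x$cell_type,
      if (isTRUE(x$input_corrected)) " (input-corrected)", "\n",
      "  ", length(x$values), " entities; range [",
      sprintf("%.3f", min(x$values, na.rm = TRUE)), ", ",
      sprintf("%.3f", max(x$values, na.rm = TRUE)), "]\n", sep = "")
  invisible(x)
}

#' Differential profile between two cell types
#'
#' Subtracts per-entity Z-scores, target minus source, so positive values
#' mean "higher in the target cell". Entities missing from either profile
#' are dropped with a message. Swapping source and target negates every
#' value exactly.
#'
#' @param target,source `feature_profile` objects for the same feature in
#'   the target and source cell type.
#' @return A `differential_profile` object: list with `feature`,
#'   `source_cell`, `target_cell`, `values` (named dZ), and `level`
#'   (`"transcript"` or `"gene"`, set to `"entity"` here and refined by
#'   [collapse_isoforms()]).
#' @export
differential_profile <- function(target, source) {
  stopifnot(inherits(target, "feature_profile"),
            inherits(source, "feature_profile"))
  if (!identical(target$feature, source$feature))
    stop("feature mismatch: '", target$feature, "' vs '", source$feature, "'")
  if (!identical(target$input_corrected, source$input_corrected))
    stop("profiles differ in input-correction status")
  common <- intersect(names(target$values), names(source$values))
  if (length(common) == 0L)
    stop("no shared entities between the two profiles")
  dropped <- length(union(names(target$values), names(source$values))) -
    length(common)
  if (dropped > 0L)
    message(dropped, " entit", if (dropped == 1L) "y" else "ies",
            " present in only one profile dropped")
  structure(
    list(feature = target$feature,
         source_cell = source$cell_type,
         target_cell = target$cell_type,
         values = target$values[common] - source$values[common],
         level = "entity"),
    class = "differential_profile"
  )
}

#' @export
print.differential_profile <- function(x, ...) {
  cat("<differential_profile> ", x$feature, ": ", x$target_cell, " - ",
      x$source_cell, " (", x$level, " level)\n",
      "  ", length(x$values), " entities; mean dZ ",
      sprintf("%.3f", mean(x$values, na.rm = TRUE)), "\n", sep = "")
  invisible(x)
}

#' Gene-level expression TPM from transcript-level TPM
#'
#' Expression is consumed at gene level: if transcript-level TPM is
#' supplied, gene TPM is the sum of its transcripts' TPM.
#'
#' @param tpm Named numeric vector keyed by transcript id.
#' @param gene_map `data.frame` with columns `transcript_id`, `gene_id`.
#' @return Named numeric vector of gene TPM.
#' @export
sum_tpm_by_gene <- function(tpm, gene_map) {
  gene_map <- .coerce_gene_map(gene_map)
  idx <- match(names(tpm), gene_map$transcript_id)
  if (anyNA(idx))
    stop("transcript(s) absent from gene_map: ",
         paste(head(names(tpm)[is.na(idx)], 3L), collapse = ", "))
  agg <- tapply(tpm, gene_map$gene_id[idx], sum)
  stats::setNames(as.numeric(agg), names(agg))
}
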