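#' Promoter interval of a transcript
#'
#' Defines the promoter as 1 kb upstream to 0.5 kb downstream of the
#' transcription start site, in 0-based half-open coordinates, clamped at
#' the chromosome start. On the plus strand this is
#' `[tss - 1000, tss + 500)`; on the minus strand the mirror image,
#' `[tss - 500 + 1, tss + 1000 + 1)`.
#'
#' @param annotation Transcript annotation table (see [read_annotation()]);
#'   may be a single-row data.frame or the full table.
#' @param upstream,downstream Extent in bp upstream/downstream of the TSS
#'   (defaults 1000 and 500).
#' @return `data.frame` with columns `transcript_id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @examples
#' ann <- data.frame(gene_id = "g", transcript_id = "t", chrom = "chr1",
#'                   strand = "+", start = 5000L, end = 7000L,
#'                   tss = 5000L, length = 2000L)
#' promoter_interval(ann) # [4000, 5500)
#' @export
promoter_interval <- function(annotation, upstream = 1000L,
                              downstream = 500L) {
  validate_annotation(annotation)
  plus <- annotation$strand == "+"
  start <- ifelse(plus,
                  annotation$tss - upstream,
                  annotation$tss - downstream + 1L)
  end <- ifelse(plus,
                annotation$tss + downstream,
                annotation$tss + upstream + 1L)
  start <- pmax(start, 0L)
  data.frame(
    transcript_id = annotation$transcript_id,
    chrom = annotation$chrom,
    start = as.integer(start),
    end = as.integer(end),
    strand = annotation$strand,
    stringsAsFactors = FALSE
  )
}

#' Rescale absolute methylation scores to [0, 1]
#'
#' Min-max rescales per-promoter absolute methylation scores (AMS, as
#' produced by meDIP analysis) within one sample so the least methylated
#' promoter maps to 0 and the most methylated to 1. The transform is
#' monotone and idempotent on input already spanning [0, 1].
#'
#' @param raw Named numeric vector (transcript id -> AMS).
#' @param cell_type Cell-type label.
#' @return A `methylation_profile` object: list with `cell_type` and
#'   `values` (named, all within \[0, 1\]).
#' @export
rescale_ams <- function(raw, cell_type) {
  if (is.null(names(raw))) stop("raw AMS values must be named by transcript")
  ok <- !is.na(raw)
  if (sum(ok) < 2L) stop("need at least 2 promoters to rescale")
  rng <- range(raw[ok])
  if (rng[1] == rng[2])
    stop("constant AMS values; rescaling undefined")
  structure(
    list(cell_type = as.character(cell_type),
         values = (raw - rng[1]) / (rng[2] - rng[1])),
    class = "methylation_profile"
  )
}

#' Differential promoter methylation between two cell types
#'
#' Subtracts rescaled methylation scores per transcript (target minus
#' source, each in \[0, 1\], so differences lie in \[-1, 1\]) and collapses
#' isoforms to genes by retaining, per gene, the isoform with the highest
#' absolute differential methylation (ties to the lexicographically
#' smallest transcript id, as in [collapse_isoforms()]).
#'
#' @param target,source `methylation_profile` objects from [rescale_ams()].
#' @param gene_map `data.frame` with columns `transcript_id`, `gene_id`; if
#'   `NULL` the result stays at transcript level.
#' @return Named numeric vector of per-gene (or per-transcript) dMeth
#'   values in \[-1, 1\].
#' @export
differential_methylation <- function(target, source, gene_map = NULL) {
  stopifnot(inherits(target, "methylation_profile"),
            inherits(source, "methylation_profile"))
  common <- intersect(names(target$values), names(source$values))
  if (length(common) == 0L)
    stop("no shared transcripts between methylation profiles")
  dmeth <- target$values[common] - source$values[common]
  if (is.null(gene_map)) return(dmeth)
  prof <- structure(
    list(feature = "methylation", source_cell = source$cell_type,
         target_cell = target$cell_type, values = dmeth,
         level = "entity"),
    class = "differential_profile"
  )
  collapse_isoforms(prof, gene_map)$values
}
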