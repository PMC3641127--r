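#' Count reads over gene bodies
#'
#' Counts, for every transcript, the number of read intervals overlapping
#' its full genomic span (introns included) by at least 1 bp. A read may
#' count toward multiple transcripts. Coordinates are 0-based half-open, so
#' abutting intervals (read start == transcript end) do not overlap. Reads
#' on chromosomes absent from the annotation count toward nothing and are
#' tallied in the `"n_skipped"` attribute.
#'
#' @param reads `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open), e.g. from [read_bed_reads()].
#' @param annotation Transcript annotation from [read_annotation()].
#' @param sample_label Label stored with the counts.
#' @return A `data.frame` (`transcript_id`, `count`, `length`) with
#'   attributes `sample_label` and `n_skipped`.
#' @export
count_gene_body_reads <- function(reads, annotation, sample_label = "sample") {
  validate_annotation(annotation)
  if (!all(c("chrom", "start", "end") %in% names(reads)))
    stop("reads need columns chrom, start, end")
  if (nrow(reads) > 0 && any(reads$start >= reads$end))
    stop("read interval(s) with start >= end")
  tx_gr <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start + 1L, annotation$end)
  )
  known_chrom <- reads$chrom %in% unique(annotation$chrom)
  n_skipped <- sum(!known_chrom)
  if (n_skipped > 0L)
    message(n_skipped, " read(s) on chromosomes absent from the annotation ",
            "skipped")
  rd <- reads[known_chrom, , drop = FALSE]
  counts <- if (nrow(rd) == 0L) integer(nrow(annotation)) else {
    rd_gr <- GenomicRanges::GRanges(
      rd$chrom, IRanges::IRanges(rd$start + 1L, rd$end)
    )
    GenomicRanges::countOverlaps(tx_gr, rd_gr, minoverlap = 1L)
  }
  out <- data.frame(
    transcript_id = annotation$transcript_id,
    count = as.integer(counts),
    length = annotation$length,
    stringsAsFactors = FALSE
  )
  attr(out, "sample_label") <- sample_label
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a 3+-column BED file of read intervals
#'
#' @param path Path to a BED file (at least chrom, start, end).
#' @return `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
read_bed_reads <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  raw <- fread(path, header = FALSE, sep = "\t", data.table = FALSE,
               select = 1:3)
  if (nrow(raw) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  bad <- which(is.na(suppressWarnings(as.integer(raw[[2]]))) |
               is.na(suppressWarnings(as.integer(raw[[3]]))))
  if (length(bad))
    stop("malformed BED record at line ", bad[1], " of ", path)
  data.frame(chrom = as.character(raw[[1]]),
             start = as.integer(raw[[2]]),
             end = as.integer(raw[[3]]),
             stringsAsFactors = FALSE)
}

#' Length-normalize gene-body counts and Z-score them
#'
#' Normalizes each transcript's read count by its length (reads per kb,
#' with one pseudo-read added so zero-count transcripts stay finite on the
#' log scale), takes the natural log, and Z-scores across all transcripts:
#' `z(log((count + 1) / (length/1000)))`.
#'
#' @param counts Gene-body count table from [count_gene_body_reads()] (or a
#'   `data.frame` with `transcript_id`, `count`, `length`).
#' @param feature `"H3K27me3"` or `"H3K9me3"` (the same pipeline serves
#'   both marks), or `"expression"` for count-based expression data.
#' @param cell_type Cell-type label.
#' @return A `feature_profile` over transcripts (see [zscore_profile()]).
#' @export
chip_zscore_profile <- function(counts, feature = "H3K27me3", cell_type) {
  if (!all(c("transcript_id", "count", "length") %in% names(counts)))
    stop("counts need columns transcript_id, count, length")
  if (any(counts$length <= 0)) stop("zero- or negative-length transcript(s)")
  if (any(counts$count < 0)) stop("negative read count(s)")
  normalized <- (counts$count + 1) / (counts$length / 1000)
  vals <- stats::setNames(log(normalized), counts$transcript_id)
  zscore_profile(vals, feature = feature, cell_type = cell_type)
}

#' Correct a ChIP profile by its input library
#'
#' Subtracts, per transcript, the Z-score of an un-enriched input library
#' from the ChIP Z-score, removing shared accessibility/copy-number signal.
#' Transcripts absent from the input profile are dropped with a message.
#'
#' @param chip `feature_profile` from [chip_zscore_profile()].
#' @param input_lib `feature_profile` of the matched input library
#'   (processed identically).
#' @return A `feature_profile` with `input_corrected = TRUE`. Note the
#'   corrected values are differences of Z-scores and are not re-standardized.
#' @export
input_correct <- function(chip, input_lib) {
  stopifnot(inherits(chip, "feature_profile"),
            inherits(input_lib, "feature_profile"))
  if (isTRUE(chip$input_corrected))
    stop("profile is already input-corrected")
  common <- intersect(names(chip$values), names(input_lib$values))
  if (length(common) == 0L)
    stop("no shared transcripts between ChIP and input profiles")
  dropped <- length(chip$values) - length(common)
  if (dropped > 0L)
    message(dropped, " transcript(s) absent from the input library dropped")
  structure(
    list(feature = chip$feature, cell_type = chip$cell_type,
         values = chip$values[common] - input_lib$values[common],
         input_corrected = TRUE),
    class = "feature_profile"
  )
}

#' Collapse a transcript-level differential profile to genes
#'
#' For genes with multiple isoforms, retains the isoform with the highest
#' differential modification level in absolute magnitude (strong repression
#' signals are negative dZ, and the screen must preserve them); ties are
#' broken by the lexicographically smallest transcript id.
#'
#' @param diff `differential_profile` over transcripts.
#' @param gene_map `data.frame` with columns `transcript_id`, `gene_id` (or
#'   path to such a TSV).
#' @return A `differential_profile` over genes (`level = "gene"`), with
#'   attribute `"chosen_transcript"` recording the retained isoform per gene.
#' @export
collapse_isoforms <- function(diff, gene_map) {
  stopifnot(inherits(diff, "differential_profile"))
  gene_map <- .coerce_gene_map(gene_map)
  idx <- match(names(diff$values), gene_map$transcript_id)
  if (anyNA(idx))
    stop("transcript(s) absent from gene_map: ",
         paste(head(names(diff$values)[is.na(idx)], 3L), collapse = ", "))
  dt <- data.table(
    transcript_id = names(diff$values),
    gene_id = gene_map$gene_id[idx],
    dz = as.numeric(diff$values)
  )
  dt <- dt[order(gene_id, -abs(dz), transcript_id)]
  top <- dt[, list(transcript_id = transcript_id[1L], dz = dz[1L]),
            by = "gene_id"]
  out <- structure(
    list(feature = diff$feature, source_cell = diff$source_cell,
         target_cell = diff$target_cell,
         values = stats::setNames(top$dz, top$gene_id),
         level = "gene"),
    class = "differential_profile"
  )
  attr(out, "chosen_transcript") <- stats::setNames(top$transcript_id,
                                                    top$gene_id)
  out
}
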