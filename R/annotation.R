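#' Read a transcript annotation (BED12 or GTF)
#'
#' Parses a transcript annotation into the package's transcript model table.
#' Coordinates are normalized to the 0-based half-open convention regardless
#' of the input dialect: BED12 is used as-is, GTF (1-based closed) is shifted
#' by one at the start. The transcription start site (`tss`) is `start` on
#' the plus strand and `end - 1` (the last base of the half-open span) on the
#' minus strand.
#'
#' BED12 has no gene field, so a two-column sidecar mapping
#' (`transcript_id<TAB>gene_id`, no header required if exactly two columns)
#' must be supplied via `gene_map`. For GTF input the `gene_id` and
#' `transcript_id` attributes are used.
#'
#' @param path Path to a BED12 or GTF file.
#' @param format `"auto"` (by file extension), `"bed12"` or `"gtf"`.
#' @param gene_map For BED12 input: path to a transcript-to-gene TSV, or a
#'   data.frame with columns `transcript_id`, `gene_id`.
#' @return A `data.frame` with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end`, `tss`, `length`. One row per transcript;
#'   `transcript_id` is unique.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\ttx1\t0\t+\t100\t200\t0\t1\t100,\t0,", bed)
#' map <- data.frame(transcript_id = "tx1", gene_id = "gA")
#' read_annotation(bed, gene_map = map)
#' @export
read_annotation <- function(path, format = c("auto", "bed12", "gtf"),
                            gene_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff)$", path, ignore.case = TRUE)) "gtf" else "bed12"
  }
  ann <- if (format == "gtf") .read_gtf(path) else .read_bed12(path, gene_map)
  if (nrow(ann) == 0L) {
    warning("annotation file '", path, "' contains no transcripts")
    return(ann)
  }
  validate_annotation(ann)
  ann
}

.read_bed12 <- function(path, gene_map) {
  raw <- tryCatch(
    suppressWarnings(
      fread(path, header = FALSE, sep = "\t", fill = TRUE,
            data.table = TRUE)),
    error = function(e) stop("failed to parse BED file '", path, "': ",
                             conditionMessage(e))
  )
  if (nrow(raw) == 0L) {
    return(.empty_annotation())
  }
  if (ncol(raw) < 6L)
    stop("BED annotation needs at least 6 columns (chrom, start, end, name, ",
         "score, strand); got ", ncol(raw))
  bad <- which(is.na(suppressWarnings(as.integer(raw[[2]]))) |
               is.na(suppressWarnings(as.integer(raw[[3]]))))
  if (length(bad))
    stop("malformed BED record at line ", bad[1],
         ": non-integer start/end coordinate")
  if (is.null(gene_map))
    stop("BED12 input has no gene attribute; supply 'gene_map' ",
         "(transcript_id -> gene_id)")
  map <- .coerce_gene_map(gene_map)
  ann <- data.frame(
    transcript_id = as.character(raw[[4]]),
    chrom = as.character(raw[[1]]),
    strand = as.character(raw[[6]]),
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    stringsAsFactors = FALSE
  )
  idx <- match(ann$transcript_id, map$transcript_id)
  if (anyNA(idx)) {
    missing <- ann$transcript_id[which(is.na(idx))]
    stop("missing gene_id mapping for transcript(s): ",
         paste(head(missing, 5L), collapse = ", "))
  }
  ann$gene_id <- map$gene_id[idx]
  .finish_annotation(ann)
}

.read_gtf <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("failed to parse GTF file '", path, "': ",
                             conditionMessage(e))
  )
  md <- S4Vectors::mcols(gr)
  if ("type" %in% colnames(md)) {
    keep <- as.character(md$type) == "transcript"
    if (any(keep)) gr <- gr[keep]
    else gr <- gr[as.character(S4Vectors::mcols(gr)$type) == "exon"]
  }
  if (length(gr) == 0L) return(.empty_annotation())
  md <- S4Vectors::mcols(gr)
  if (!"gene_id" %in% colnames(md) || anyNA(md$gene_id))
    stop("GTF records missing the gene_id attribute")
  if (!"transcript_id" %in% colnames(md) || anyNA(md$transcript_id))
    stop("GTF records missing the transcript_id attribute")
  ann <- data.frame(
    transcript_id = as.character(md$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    # GTF is 1-based closed; internal convention is 0-based half-open
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    gene_id = as.character(md$gene_id),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ann$transcript_id)) {
    # exon-level rows: take the transcript span
    dt <- as.data.table(ann)
    ann <- as.data.frame(dt[, list(
      chrom = chrom[1L], strand = strand[1L],
      start = min(start), end = max(end), gene_id = gene_id[1L]
    ), by = "transcript_id"])
  }
  .finish_annotation(ann)
}

.coerce_gene_map <- function(gene_map) {
  if (is.character(gene_map) && length(gene_map) == 1L) {
    gm <- fread(gene_map, header = "auto", data.table = FALSE)
    if (ncol(gm) < 2L) stop("gene map must have two columns")
    if (!all(c("transcript_id", "gene_id") %in% names(gm)))
      names(gm)[1:2] <- c("transcript_id", "gene_id")
    gene_map <- gm
  }
  gene_map <- as.data.frame(gene_map)
  if (!all(c("transcript_id", "gene_id") %in% names(gene_map)))
    stop("gene_map needs columns 'transcript_id' and 'gene_id'")
  gene_map$transcript_id <- as.character(gene_map$transcript_id)
  gene_map$gene_id <- as.character(gene_map$gene_id)
  gene_map
}

.finish_annotation <- function(ann) {
  ann$strand <- ifelse(ann$strand %in% c("+", "-"), ann$strand, "+")
  ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end - 1L)
  ann$length <- ann$end - ann$start
  ann[, c("gene_id", "transcript_id", "chrom", "strand",
          "start", "end", "tss", "length")]
}

.empty_annotation <- function() {
  data.frame(gene_id = character(), transcript_id = character(),
             chrom = character(), strand = character(),
             start = integer(), end = integer(),
             tss = integer(), length = integer(),
             stringsAsFactors = FALSE)
}

#' Validate a transcript annotation table
#'
#' Checks the invariants of the transcript model: `start < end`, positive
#' lengths, `tss` inside `[start, end)`, and unique transcript ids.
#'
#' @param ann Annotation `data.frame` as returned by [read_annotation()].
#' @return The annotation, invisibly; errors on violation.
#' @export
validate_annotation <- function(ann) {
  req <- c("gene_id", "transcript_id", "chrom", "strand",
           "start", "end", "tss", "length")
  miss <- setdiff(req, names(ann))
  if (length(miss)) stop("annotation missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(ann$start >= ann$end))
    stop("annotation has transcript(s) with start >= end: ",
         paste(head(ann$transcript_id[ann$start >= ann$end], 3L),
               collapse = ", "))
  if (any(ann$tss < ann$start | ann$tss >= ann$end))
    stop("annotation has tss outside [start, end)")
  dup <- ann$transcript_id[duplicated(ann$transcript_id)]
  if (length(dup))
    stop("duplicate transcript_id in annotation: ",
         paste(head(unique(dup), 3L), collapse = ", "))
  invisible(ann)
}

#' Write a transcript annotation as BED12
#'
#' Inverse of [read_annotation()] for BED12 input: writes one single-block
#' BED12 record per transcript in 0-based half-open coordinates, so that
#' reading the file back yields the identical annotation table.
#'
#' @param ann Annotation `data.frame` (see [read_annotation()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_bed12 <- function(ann, path) {
  validate_annotation(ann)
  bed <- data.table(
    chrom = ann$chrom, start = ann$start, end = ann$end,
    name = ann$transcript_id, score = 0L, strand = ann$strand,
    thickStart = ann$start, thickEnd = ann$end, itemRgb = "0",
    blockCount = 1L,
    blockSizes = paste0(ann$length, ","),
    blockStarts = "0,"
  )
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
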