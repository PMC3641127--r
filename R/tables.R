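#' Read a keyed numeric table (TSV)
#'
#' Reads a headered TSV into a keyed table, matching columns by name (column
#' order in the file is irrelevant), enforcing key uniqueness and numeric
#' types, and preserving empty cells as `NA`.
#'
#' @param path Path to a tab-separated file with a header line.
#' @param key Name of the key column (default `"gene_id"`).
#' @param numeric_cols Character vector of columns that must be numeric;
#'   default: all non-key columns.
#' @return A `data.frame` with the key column first; attribute `"key"` names
#'   the key column.
#' @export
read_keyed_table <- function(path, key = "gene_id", numeric_cols = NULL) {
  if (!file.exists(path)) stop("table not found: ", path)
  tab <- fread(path, sep = "\t", header = TRUE, data.table = FALSE,
               na.strings = c("", "NA"))
  if (!key %in% names(tab))
    stop("key column '", key, "' absent from ", path,
         " (found: ", paste(names(tab), collapse = ", "), ")")
  dup <- tab[[key]][duplicated(tab[[key]])]
  if (length(dup))
    stop("duplicate key(s) in '", path, "': ",
         paste(head(unique(dup), 5L), collapse = ", "))
  if (is.null(numeric_cols)) numeric_cols <- setdiff(names(tab), key)
  for (nc in numeric_cols) {
    if (!nc %in% names(tab))
      stop("column '", nc, "' absent from ", path)
    if (!is.numeric(tab[[nc]])) {
      coerced <- suppressWarnings(as.numeric(tab[[nc]]))
      bad <- which(is.na(coerced) & !is.na(tab[[nc]]))
      if (length(bad))
        stop("non-numeric value '", tab[[nc]][bad[1]], "' in column '", nc,
             "' of ", path)
      tab[[nc]] <- coerced
    }
  }
  tab <- tab[, c(key, setdiff(names(tab), key)), drop = FALSE]
  attr(tab, "key") <- key
  tab
}

#' Read a TPM expression table
#'
#' Convenience wrapper around [read_keyed_table()] for two-column
#' (`gene_id`, `tpm`) expression tables; returns a named numeric vector.
#'
#' @param path Path to the TSV.
#' @return Named numeric vector of TPM values, keyed by gene id.
#' @export
read_tpm_table <- function(path) {
  tab <- read_keyed_table(path, key = "gene_id", numeric_cols = "tpm")
  stats::setNames(tab$tpm, tab$gene_id)
}

#' Read a transcription factor catalog
#'
#' One gene id per line (AnimalTFDB-style list); blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path Path to the list.
#' @param genome_label Optional label for the genome the catalog refers to.
#' @return Character vector of unique TF gene ids, with attribute
#'   `"genome_label"`.
#' @export
read_tf_catalog <- function(path, genome_label = NA_character_) {
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  ids <- unique(ids)
  if (length(ids) == 0L) stop("TF catalog '", path, "' is empty")
  attr(ids, "genome_label") <- genome_label
  ids
}

#' Read a known-transdifferentiation-factor table
#'
#' Reads a TSV with columns `source_cell`, `target_cell`, `gene_id` listing
#' published conversion factors per ordered cell-type pair. Factors missing
#' from a supplied TF catalog are kept but flagged with a warning (they are
#' excluded later from recovery denominators by the screen functions).
#'
#' @param path Path to the TSV.
#' @param tf_catalog Optional character vector of TF ids to check against.
#' @return A `data.frame` with columns `source_cell`, `target_cell`,
#'   `gene_id`.
#' @export
read_known_factors <- function(path, tf_catalog = NULL) {
  tab <- fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  req <- c("source_cell", "target_cell", "gene_id")
  if (!all(req %in% names(tab)))
    stop("known-factor table needs columns: ", paste(req, collapse = ", "))
  if (!is.null(tf_catalog)) {
    miss <- setdiff(tab$gene_id, tf_catalog)
    if (length(miss))
      warning("known factor(s) absent from the TF catalog: ",
              paste(head(miss, 5L), collapse = ", "))
  }
  tab[, req]
}

#' Write a screen result table
#'
#' Writes one row per TF with columns `gene_id`, `dz_expr`, `dz_mod`,
#' `dominance_count`, `rank`, `selected`, `known`. Values round-trip through
#' [read_keyed_table()] losslessly to at least 6 decimals.
#'
#' @param result A screen result `data.frame` from [run_screen()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_result <- function(result, path) {
  req <- c("gene_id", "dz_expr", "dz_mod", "dominance_count", "rank",
           "selected", "known")
  if (!is.data.frame(result) || nrow(result) == 0L)
    stop("screen result is empty; nothing to write")
  miss <- setdiff(req, names(result))
  if (length(miss)) stop("screen result missing column(s): ",
                         paste(miss, collapse = ", "))
  ok <- tryCatch({
    fwrite(result[, req], path, sep = "\t")
    TRUE
  }, error = function(e) stop("cannot write screen result to '", path,
                              "': ", conditionMessage(e)))
  invisible(path)
}

#' Read back a screen result table
#'
#' @param path Path written by [write_screen_result()].
#' @return The screen result `data.frame` with logical `selected`/`known`.
#' @export
read_screen_result <- function(path) {
  tab <- read_keyed_table(path, key = "gene_id",
                          numeric_cols = c("dz_expr", "dz_mod",
                                           "dominance_count", "rank"))
  tab$selected <- as.logical(tab$selected)
  tab$known <- as.logical(tab$known)
  tab
}
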