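#' Configuration for the paired two-cell-type simulator
#'
#' Defines the study conditions emulated by [simulate_dataset()]: a genome
#' of `n_genes` genes (of which `n_tfs` are transcription factors and
#' `n_planted` TFs are planted transdifferentiation factors), profiled in a
#' source and a target cell type by expression (TPM tables) and H3K27me3
#' ChIP-seq plus matched input libraries (read intervals).
#'
#' Planted factors receive a log-expression shift of `delta_expr` in the
#' target cell and a log-modification shift of `delta_mod` in the source
#' cell; after genome-wide Z-scoring these defaults realize planted group
#' means of approximately +1.8 (dZ-expression) and -3.1
#' (dZ-H3K27me3), with background group means near 0, matching the
#' signature the screen is built to detect.
#'
#' @param n_genes Number of genes (default 5000).
#' @param n_tfs Number of TF genes (default 1400).
#' @param n_planted Number of planted transdifferentiation factors
#'   (default 40).
#' @param delta_expr Target-cell log(1+TPM) shift for planted genes.
#' @param delta_mod Source-cell log-modification-rate shift for planted
#'   genes.
#' @param sigma_between Gene-to-gene baseline sd on the log scale (shared
#'   by expression and modification).
#' @param sigma_within_expr Cell-type expression noise sd (log scale).
#' @param sigma_within_chip Cell-type modification noise sd (log scale),
#'   applied per gene: isoforms of a gene share their H3K27me3 domain, so
#'   the cell-type noise is drawn at gene level with a small independent
#'   per-transcript term (`sigma_iso`) on top.
#' @param sigma_iso Per-transcript modification noise sd (log scale).
#' @param sigma_access Sd of the per-transcript log-accessibility term
#'   shared by the ChIP and input rates of every library (the signal input
#'   correction removes).
#' @param mean_depth Expected ChIP/input reads per transcript at baseline.
#' @param isoforms_per_gene Isoforms per gene (>= 1).
#' @param mu_expr Mean baseline log(1+TPM).
#' @param read_length Read length in bp for simulated intervals.
#' @param seed Integer seed; the dataset is deterministic given the config.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 5000L,
                              n_tfs = 1400L,
                              n_planted = 40L,
                              delta_expr = 2.05,
                              delta_mod = 4.6,
                              sigma_between = 1.0,
                              sigma_within_expr = 0.40,
                              sigma_within_chip = 0.9,
                              sigma_iso = 0.2,
                              sigma_access = 0.8,
                              mean_depth = 150,
                              isoforms_per_gene = 2L,
                              mu_expr = 4.0,
                              read_length = 36L,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
              n_planted = as.integer(n_planted),
              delta_expr = delta_expr, delta_mod = delta_mod,
              sigma_between = sigma_between,
              sigma_within_expr = sigma_within_expr,
              sigma_within_chip = sigma_within_chip,
              sigma_iso = sigma_iso,
              sigma_access = sigma_access,
              mean_depth = mean_depth,
              isoforms_per_gene = as.integer(isoforms_per_gene),
              mu_expr = mu_expr, read_length = as.integer(read_length),
              seed = as.integer(seed))
  if (cfg$n_genes < 2L) stop("n_genes must be at least 2")
  if (cfg$n_tfs > cfg$n_genes) stop("n_tfs cannot exceed n_genes")
  if (cfg$n_planted > cfg$n_tfs) stop("n_planted cannot exceed n_tfs")
  if (cfg$n_planted < 1L) stop("n_planted must be at least 1")
  if (cfg$isoforms_per_gene < 1L) stop("isoforms_per_gene must be >= 1")
  if (any(c(cfg$sigma_between, cfg$sigma_within_expr,
            cfg$sigma_within_chip, cfg$sigma_access) <= 0))
    stop("all sigma parameters must be positive")
  if (cfg$sigma_iso < 0) stop("sigma_iso must be non-negative")
  if (cfg$mean_depth <= 0) stop("mean_depth must be positive")
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a paired two-cell-type dataset with planted factors
#'
#' Generates annotation, per-cell-type expression tables, and ChIP/input
#' read intervals for a source ("cellA") and target ("cellB") cell type,
#' with `n_planted` TFs carrying the transdifferentiation signature:
#' higher expression in the target cell and stronger H3K27me3 in the
#' source cell.
#'
#' Generative model, per gene g with baseline `a_g ~ N(mu_expr,
#' sigma_between^2)`: cell-type log(1+TPM) is `a_g + N(0,
#' sigma_within_expr^2)`, plus `delta_expr` in the target cell iff g is
#' planted; TPM = `expm1` of the (floored-at-zero) log value, renormalized
#' to sum to 1e6. Per transcript t with gene baseline `b_g ~ N(0,
#' sigma_between^2)` and shared accessibility `acc_t ~ N(0,
#' sigma_access^2)`: the ChIP read count is Poisson with mean
#' `exp(b_g + acc_t + N(0, sigma_within_chip^2) + delta_mod[planted,
#' source]) * length * depth_scale`, the input count Poisson with mean
#' `exp(acc_t) * length * depth_scale`; reads are placed uniformly within
#' the transcript span. All transcripts are tiled on one synthetic
#' chromosome (`chrS`) with fixed spacing; gene lengths are log-normal
#' (median 10 kb). Isoforms share the gene's planted status with their
#' modification shift jittered by +/-10%.
#'
#' @param config A `simulation_config`.
#' @return A `simulated_dataset`: list with `annotation`, `gene_map`,
#'   `expression` (list source/target of named TPM vectors), `chip_reads`
#'   and `input_reads` (lists source/target of read data.frames),
#'   `chip_counts` (the per-transcript counts drawn, for verification),
#'   `tf_catalog`, `known` (planted factor ids with source/target labels),
#'   and `config`. Deterministic given the config seed.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ng <- config$n_genes; K <- config$isoforms_per_gene

  # --- gene layout on one synthetic chromosome ---
  gene_len <- pmax(200L, as.integer(round(rlnorm(ng, log(10000), 0.5))))
  gap <- 2000L
  gene_start <- cumsum(c(0L, head(gene_len, -1L) + gap))
  gene_id <- sprintf("g%05d", seq_len(ng))
  strand <- sample(c("+", "-"), ng, replace = TRUE)

  iso_frac <- matrix(1, nrow = ng, ncol = K)
  if (K > 1L)
    iso_frac[, -1L] <- matrix(runif(ng * (K - 1L), 0.6, 1.0),
                              nrow = ng)
  tx_len <- matrix(pmax(200L, as.integer(round(gene_len * iso_frac))),
                   nrow = ng)
  ann <- data.frame(
    gene_id = rep(gene_id, each = K),
    transcript_id = paste0(rep(gene_id, each = K), ".",
                           rep(seq_len(K), ng)),
    chrom = "chrS",
    strand = rep(strand, each = K),
    start = rep(gene_start, each = K),
    stringsAsFactors = FALSE
  )
  ann$end <- ann$start + as.integer(t(tx_len))
  ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end - 1L)
  ann$length <- ann$end - ann$start
  gene_map <- ann[, c("transcript_id", "gene_id")]

  tf_ids <- sort(sample(gene_id, config$n_tfs))
  planted <- sort(sample(tf_ids, config$n_planted))
  is_planted_gene <- gene_id %in% planted

  # --- expression (gene level) ---
  a_g <- rnorm(ng, config$mu_expr, config$sigma_between)
  make_tpm <- function(target_cell) {
    x <- a_g + rnorm(ng, 0, config$sigma_within_expr)
    if (target_cell) x <- x + config$delta_expr * is_planted_gene
    tpm <- expm1(pmax(x, 0))
    tpm <- tpm / sum(tpm) * 1e6
    stats::setNames(tpm, gene_id)
  }
  expression <- list(source = make_tpm(FALSE), target = make_tpm(TRUE))

  # --- chromatin (transcript level) ---
  ntx <- nrow(ann)
  b_g <- rnorm(ng, 0, config$sigma_between)
  b_t <- rep(b_g, each = K)
  acc_t <- rnorm(ntx, 0, config$sigma_access)
  planted_t <- rep(is_planted_gene, each = K)
  delta_t <- config$delta_mod * (1 + runif(ntx, -0.1, 0.1)) * planted_t
  s2 <- config$sigma_between^2 + config$sigma_access^2 +
    config$sigma_within_chip^2 + config$sigma_iso^2
  ds_chip <- config$mean_depth / (10000 * exp(s2 / 2))
  ds_input <- config$mean_depth / (10000 * exp(config$sigma_access^2 / 2))

  draw_reads <- function(counts) {
    idx <- rep.int(seq_len(ntx), counts)
    span <- pmax(ann$length[idx] - config$read_length, 1L)
    start <- ann$start[idx] + as.integer(floor(runif(length(idx)) * span))
    data.frame(chrom = "chrS", start = start,
               end = start + config$read_length,
               stringsAsFactors = FALSE)
  }
  chip_rate <- function(source_cell) {
    # cell-type noise is gene-level (isoforms share their H3K27me3 domain)
    # with a small independent per-transcript component
    w_g <- rep(rnorm(ng, 0, config$sigma_within_chip), each = K)
    lograte <- b_t + acc_t + w_g + rnorm(ntx, 0, config$sigma_iso)
    if (source_cell) lograte <- lograte + delta_t
    exp(lograte) * ann$length * ds_chip
  }
  chip_counts <- list(
    source = rpois(ntx, chip_rate(TRUE)),
    target = rpois(ntx, chip_rate(FALSE))
  )
  input_counts <- list(
    source = rpois(ntx, exp(acc_t) * ann$length * ds_input),
    target = rpois(ntx, exp(acc_t) * ann$length * ds_input)
  )
  chip_reads <- lapply(chip_counts, draw_reads)
  input_reads <- lapply(input_counts, draw_reads)
  counts_tab <- data.frame(
    transcript_id = ann$transcript_id,
    chip_source = chip_counts$source, chip_target = chip_counts$target,
    input_source = input_counts$source, input_target = input_counts$target,
    stringsAsFactors = FALSE
  )

  structure(
    list(annotation = ann, gene_map = gene_map, expression = expression,
         chip_reads = chip_reads, input_reads = input_reads,
         chip_counts = counts_tab,
         tf_catalog = tf_ids,
         known = list(source_cell = "cellA", target_cell = "cellB",
                      factor_ids = planted),
         config = config),
    class = "simulated_dataset"
  )
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("<simulated_dataset> ", x$config$n_genes, " genes (",
      length(x$tf_catalog), " TFs, ", length(x$known$factor_ids),
      " planted), ", nrow(x$annotation), " transcripts, seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits exactly the formats the readers consume: BED12 annotation plus a
#' transcript-to-gene map, per-cell-type expression TSVs
#' (`gene_id`, `tpm`), ChIP and input read BED files, a TF catalog list,
#' and a known-factor TSV. Reading the files back reproduces the in-memory
#' dataset.
#'
#' @param dataset A `simulated_dataset`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the files written, invisibly.
#' @export
emit_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  if (nrow(dataset$annotation) == 0L) stop("empty dataset")
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create directory ", dir)
  paths <- c(
    annotation = file.path(dir, "annotation.bed"),
    gene_map = file.path(dir, "gene_map.tsv"),
    expr_source = file.path(dir, "expr_source.tsv"),
    expr_target = file.path(dir, "expr_target.tsv"),
    chip_source = file.path(dir, "chip_source.bed"),
    chip_target = file.path(dir, "chip_target.bed"),
    input_source = file.path(dir, "input_source.bed"),
    input_target = file.path(dir, "input_target.bed"),
    tf_catalog = file.path(dir, "tf_catalog.txt"),
    known = file.path(dir, "known_factors.tsv"),
    config = file.path(dir, "config.txt")
  )
  write_annotation_bed12(dataset$annotation, paths["annotation"])
  fwrite(dataset$gene_map, paths["gene_map"], sep = "\t")
  for (cell in c("source", "target")) {
    tpm <- dataset$expression[[cell]]
    fwrite(data.table(gene_id = names(tpm), tpm = as.numeric(tpm)),
           paths[paste0("expr_", cell)], sep = "\t")
    fwrite(dataset$chip_reads[[cell]], paths[paste0("chip_", cell)],
           sep = "\t", col.names = FALSE)
    fwrite(dataset$input_reads[[cell]], paths[paste0("input_", cell)],
           sep = "\t", col.names = FALSE)
  }
  writeLines(dataset$tf_catalog, paths["tf_catalog"])
  kn <- dataset$known
  fwrite(data.table(source_cell = kn$source_cell,
                    target_cell = kn$target_cell,
                    gene_id = kn$factor_ids),
         paths["known"], sep = "\t")
  cfg <- dataset$config
  writeLines(paste0(names(unclass(cfg)), "=",
                    vapply(unclass(cfg), format, character(1))),
             paths["config"])
  invisible(paths)
}

#' Run the full screen pipeline on a simulated dataset
#'
#' Executes every stage the screen applies to real data: gene-level
#' expression Z-scores and their target-minus-source difference; gene-body
#' read counting, length normalization, Z-scoring, input correction,
#' differencing and isoform collapse for the modification signal; then the
#' dominance screen and recovery evaluation against the planted factors.
#'
#' @param dataset A `simulated_dataset`.
#' @return List with `dz_expr`, `dz_mod` (gene-level named vectors),
#'   `screen` (a `screen_result`), `recovery` (list of `recovery_curve`s:
#'   `combined`, `expression`, `modification`; apply [smooth_ties()] for
#'   display), and `summary` (from [screen_summary()]).
#' @export
screen_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  ann <- dataset$annotation

  expr_prof <- lapply(c(source = "source", target = "target"), function(cell)
    zscore_profile(log1p_expression(dataset$expression[[cell]]),
                   feature = "expression",
                   cell_type = if (cell == "source") "cellA" else "cellB"))
  dz_expr <- differential_profile(expr_prof$target, expr_prof$source)$values

  corrected <- lapply(c(source = "source", target = "target"), function(cell) {
    label <- if (cell == "source") "cellA" else "cellB"
    chip <- chip_zscore_profile(
      count_gene_body_reads(dataset$chip_reads[[cell]], ann,
                            paste0("chip_", cell)),
      feature = "H3K27me3", cell_type = label)
    input <- chip_zscore_profile(
      count_gene_body_reads(dataset$input_reads[[cell]], ann,
                            paste0("input_", cell)),
      feature = "H3K27me3", cell_type = label)
    input_correct(chip, input)
  })
  dz_mod_tx <- differential_profile(corrected$target, corrected$source)
  dz_mod <- collapse_isoforms(dz_mod_tx, dataset$gene_map)$values

  known <- dataset$known$factor_ids
  scr <- run_screen(dz_expr, dz_mod, dataset$tf_catalog, known = known,
                    pair = c(source = "cellA", target = "cellB"))
  counts <- stats::setNames(scr$dominance_count, scr$gene_id)
  e <- stats::setNames(scr$dz_expr, scr$gene_id)
  m <- stats::setNames(scr$dz_mod, scr$gene_id)
  rk_e <- rank_single_feature(e, "descending")
  rk_m <- rank_single_feature(m, "ascending")
  recovery <- list(
    combined = recovery_curve(counts, known),
    expression = recovery_curve(
      stats::setNames(rk_e$rank, rk_e$gene_id), known),
    modification = recovery_curve(
      stats::setNames(rk_m$rank, rk_m$gene_id), known)
  )
  list(dz_expr = dz_expr, dz_mod = dz_mod, screen = scr,
       recovery = recovery, summary = screen_summary(scr))
}
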