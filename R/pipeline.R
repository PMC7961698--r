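#' Run the full single-cell program-discovery pipeline
#'
#' Orchestrates preprocessing and program discovery on a count matrix:
#' QC filtering, marker gating of cultures, normalization, aggregate-
#' expression gene filtering, per-patient mean-centering, NNMF, exclusion
#' of patient-specific factors, signature extraction, background-binned
#' scoring, meta-signature combination, and cell-type assignment. Each
#' stage logs its input/output dimensions; a stage failure aborts with a
#' stage-tagged error.
#'
#' @param counts a [count_matrix()].
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when set, stage outputs are written
#'   as TSV/GMT and their digests recorded in the manifest.
#' @param lgr5_gate if `TRUE` (default), cultures failing the strict
#'   marker-score threshold are dropped before centering and NNMF.
#' @param verbose print per-stage summaries.
#' @return List of class \code{pipeline_result} with elements `qc`,
#'   `gate`, `expression`, `centered`, `nnmf`, `retained_factors`,
#'   `signatures`, `scores`, `meta_signatures`, `meta_scores`,
#'   `assignment`, and `manifest`.
#' @export
run_pipeline <- function(counts, config = pipeline_config(),
                         out_dir = NULL, lgr5_gate = TRUE,
                         verbose = FALSE) {
  stopifnot(inherits(counts, "count_matrix"),
            inherits(config, "pipeline_config"))
  log_ <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
  }
  summaries <- list()

  n_in <- ncol(counts$counts)
  qc <- stage("qc", qc_filter(counts, min_reads = config$min_reads,
                              min_genes = config$min_genes,
                              max_mito = config$max_mito,
                              top_read_quantile = config$top_read_quantile,
                              pca_outlier_sd = config$pca_outlier_sd))
  summaries$qc <- attr(qc, "qc_summary")
  log_("qc: %d -> %d cells", n_in, ncol(qc$counts))

  gate <- stage("gate", lgr5_score(qc, gene = config$lgr5_gene,
                                   threshold = config$lgr5_threshold))
  gated <- qc
  if (lgr5_gate) {
    keep_pat <- gate$patient[gate$positive]
    if (length(keep_pat) == 0L)
      stop("[stage gate] no culture passes the marker threshold")
    gated <- subset_cells(qc, which(qc$patient %in% keep_pat))
    log_("gate: %d of %d cultures positive", length(keep_pat), nrow(gate))
  }

  expr <- stage("normalize", normalize_cpm_log(gated))
  n_genes0 <- nrow(expr$values)
  expr <- stage("ea_filter",
                filter_low_expression(expr, min_ea = config$min_ea,
                                      aggregate = config$ea_aggregate))
  summaries$ea <- c(genes_in = n_genes0, genes_out = nrow(expr$values))
  log_("ea_filter: %d -> %d genes", n_genes0, nrow(expr$values))

  centered <- stage("center", mean_center_by_patient(expr))

  model <- stage("nnmf", fit_nnmf(centered, k = config$k,
                                  seed = config$nnmf_seed,
                                  n_restarts = config$n_restarts,
                                  max_iter = config$max_iter,
                                  tol = config$tol))
  retained <- stage("factor_filter", filter_patient_specific_factors(
    model, overlap_threshold = config$overlap_threshold,
    min_patients = config$min_patients, n_bins = config$overlap_bins))
  summaries$factors <- c(total = model$k, retained = length(retained))
  log_("factors: %d of %d retained", length(retained), model$k)

  top_n <- min(config$signature_top_n, nrow(expr$values))
  sigs <- stage("signatures", lapply(as.integer(retained), function(f)
    extract_signature(model, f, top_n = top_n)))

  scores <- stage("score", score_signatures(
    expr, sigs, n_bins = config$score_bins,
    n_control_per_gene = config$n_control_per_gene,
    seed = config$score_seed))

  metas <- stage("meta", if (length(sigs) >= 2L)
    combine_meta_signatures(scores, sigs, r_threshold = config$r_threshold)
    else sigs)
  meta_scores <- stage("meta_score", score_signatures(
    expr, metas, n_bins = config$score_bins,
    n_control_per_gene = config$n_control_per_gene,
    seed = config$score_seed))

  assignment <- stage("assign", assign_cell_types(meta_scores))
  summaries$types <- table(assignment$assigned)
  log_("assignment: %s",
       paste(names(summaries$types), summaries$types,
             sep = "=", collapse = ", "))

  outputs <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p1 <- file.path(out_dir, "signatures.gmt")
    write_gmt(metas, p1)
    p2 <- file.path(out_dir, "cell_scores.tsv")
    atomic_write(function(f) write.table(
      data.frame(cell = rownames(meta_scores), meta_scores,
                 check.names = FALSE),
      f, sep = "\t", row.names = FALSE, quote = FALSE), p2)
    p3 <- file.path(out_dir, "assignment.tsv")
    atomic_write(function(f) write.table(as.data.frame(assignment), f,
                                         sep = "\t", row.names = FALSE,
                                         quote = FALSE), p3)
    outputs <- c(p1, p2, p3)
  }

  manifest <- list(
    config = unclass(config),
    seeds = c(nnmf = config$nnmf_seed, score = config$score_seed),
    dims = list(cells_in = n_in, cells_qc = ncol(qc$counts),
                cells_analyzed = ncol(gated$counts),
                genes_in = n_genes0, genes_kept = nrow(expr$values)),
    summaries = summaries,
    outputs = if (length(outputs))
      setNames(as.character(tools::md5sum(outputs)), basename(outputs))
      else NULL)

  structure(list(qc = qc, gate = gate, expression = expr,
                 centered = centered, nnmf = model,
                 retained_factors = as.integer(retained),
                 signatures = sigs, scores = scores,
                 meta_signatures = metas, meta_scores = meta_scores,
                 assignment = assignment, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  d <- x$manifest$dims
  cat(sprintf(paste0(
    "pipeline_result: %d/%d cells passed QC, %d analyzed;\n",
    "  %d/%d genes kept; %d/%d factors retained; %d meta-signature(s)\n"),
    d$cells_qc, d$cells_in, d$cells_analyzed, d$genes_kept, d$genes_in,
    length(x$retained_factors), x$nnmf$k, length(x$meta_signatures)))
  print(table(x$assignment$assigned))
  invisible(x)
}
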