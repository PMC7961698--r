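#' Quality-control filtering of single-cell libraries
#'
#' Retains cells that satisfy all library-level criteria: strictly more than
#' `min_reads` sequenced reads, strictly more than `min_genes` detected
#' genes, and strictly less than `max_mito` mitochondrial read fraction.
#' Cells in the top `top_read_quantile` of read counts are then removed
#' within each patient independently (deep outlier libraries are enriched
#' for multiplets). Optionally, cells far from the centroid in the space of
#' the top 10 principal components of log expression can be dropped.
#'
#' The three threshold criteria are evaluated on the full input and
#' intersected, and the per-patient top-read rule is applied to the
#' survivors, so the result does not depend on the order in which criteria
#' are listed.
#'
#' @param m a [count_matrix()] with `total_reads` and `mito_fraction`.
#' @param min_reads minimum sequenced reads per cell (exclusive bound).
#' @param min_genes minimum detected genes per cell (exclusive bound).
#' @param max_mito maximum mitochondrial read fraction (exclusive bound).
#' @param top_read_quantile fraction of the deepest libraries removed per
#'   patient; with `n` surviving cells of a patient, `floor(q * n)` cells
#'   are removed in decreasing read order, ties broken by original cell
#'   order.
#' @param pca_outlier_sd if non-`NULL`, cells whose Euclidean distance from
#'   the centroid in top-10 PC space exceeds the mean distance by more than
#'   this many standard deviations are removed.
#' @return The filtered [count_matrix()] with a `"qc_summary"` attribute
#'   recording per-rule removals.
#' @export
qc_filter <- function(m, min_reads = 1e5, min_genes = 1000, max_mito = 0.15,
                      top_read_quantile = 0.05, pca_outlier_sd = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  if (is.null(m$total_reads))
    stop("missing metadata: 'total_reads' is required for QC")
  if (is.null(m$mito_fraction))
    stop("missing metadata: 'mito_fraction' is required for QC")
  n0 <- ncol(m$counts)
  detected <- as.numeric(Matrix::colSums(m$counts > 0))
  pass_reads <- m$total_reads > min_reads
  pass_genes <- detected > min_genes
  pass_mito <- m$mito_fraction < max_mito
  keep <- pass_reads & pass_genes & pass_mito

  # per-patient removal of the deepest libraries among survivors
  removed_top <- rep(FALSE, n0)
  for (p in unique(m$patient)) {
    idx <- which(keep & m$patient == p)
    n_remove <- floor(top_read_quantile * length(idx))
    if (n_remove > 0L) {
      ord <- idx[order(-m$total_reads[idx], idx)]
      removed_top[ord[seq_len(n_remove)]] <- TRUE
    }
  }
  keep <- keep & !removed_top

  removed_pca <- rep(FALSE, n0)
  if (!is.null(pca_outlier_sd) && sum(keep) > 2L) {
    idx <- which(keep)
    e <- log2(sweep(as.matrix(m$counts[, idx, drop = FALSE]), 2,
                    pmax(Matrix::colSums(m$counts[, idx, drop = FALSE]), 1),
                    "/") * 1e6 / 10 + 1)
    npc <- min(10L, ncol(e) - 1L, nrow(e))
    pc <- prcomp(t(e), center = TRUE, scale. = FALSE, rank. = npc)
    d <- sqrt(rowSums(pc$x^2))
    out <- d > mean(d) + pca_outlier_sd * sd(d)
    removed_pca[idx[out]] <- TRUE
    keep <- keep & !removed_pca
  }

  if (!any(keep))
    stop("QC removed all cells; check thresholds against the input")
  res <- subset_cells(m, which(keep))
  attr(res, "qc_summary") <- data.frame(
    rule = c("reads", "genes", "mito", "top_reads", "pca_outlier"),
    removed = c(sum(!pass_reads), sum(!pass_genes), sum(!pass_mito),
                sum(removed_top), sum(removed_pca)))
  res
}

#' Log2 counts-per-million normalization
#'
#' Computes `E = log2(CPM/10 + 1)` per gene and cell, where CPM is counts
#' per million against each cell's total count over all genes present at
#' input (denominators are fixed before any gene filtering).
#'
#' @param m a [count_matrix()]; every cell must have at least one count.
#' @return An [expression_matrix()] of E values.
#' @export
normalize_cpm_log <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  totals <- as.numeric(Matrix::colSums(m$counts))
  if (any(totals == 0))
    stop("zero-count cell(s): ",
         paste(head(m$cells[totals == 0], 5L), collapse = ", "))
  cpm <- sweep(as.matrix(m$counts), 2, totals, "/") * 1e6
  e <- log2(cpm / 10 + 1)
  dimnames(e) <- dimnames(as.matrix(m$counts))
  expression_matrix(e, m$patient)
}

#' Aggregate-expression gene filtering
#'
#' Removes weakly expressed genes by thresholding the per-gene aggregate
#' expression Ea across all cells of the (merged) cohort. Two aggregation
#' conventions are available:
#' \describe{
#'   \item{`"linear"` (default)}{`Ea = log2(mean(CPM/10) + 1)`, i.e., the
#'     mean is taken on the linear CPM/10 scale (recovered as `2^E - 1`).}
#'   \item{`"log"`}{`Ea = log2(mean(E) + 1)`, the mean of the log-scale E
#'     values themselves; with the default cutoff this retains only genes
#'     with `mean(E) >= 2^3.5 - 1`, a far harsher rule useful mainly for
#'     boundary analysis.}
#' }
#' Genes with `Ea < min_ea` are excluded (strict); a gene at exactly
#' `min_ea` is retained.
#'
#' @param e an [expression_matrix()].
#' @param min_ea aggregate-expression cutoff (log2 units).
#' @param aggregate aggregation convention, see Details.
#' @return The filtered [expression_matrix()] with per-gene `ea` attached.
#' @export
filter_low_expression <- function(e, min_ea = 3.5,
                                  aggregate = c("linear", "log")) {
  stopifnot(inherits(e, "expression_matrix"))
  aggregate <- match.arg(aggregate)
  ea <- if (aggregate == "linear") {
    log2(rowMeans(2^e$values - 1) + 1)
  } else {
    log2(rowMeans(e$values) + 1)
  }
  keep <- ea >= min_ea
  expression_matrix(e$values[keep, , drop = FALSE], e$patient,
                    ea = ea[keep])
}

#' Per-patient mean-centering
#'
#' Subtracts, per gene and per patient, the mean expression across that
#' patient's cells, eliminating global inter-patient expression shifts so
#' that downstream factorization captures within-patient heterogeneity.
#'
#' @param e an [expression_matrix()].
#' @param patient optional labels overriding those stored in `e`.
#' @return A list of class \code{centered_matrix} with signed `values`
#'   (genes x cells) and `patient`.
#' @export
mean_center_by_patient <- function(e, patient = NULL) {
  stopifnot(inherits(e, "expression_matrix"))
  patient <- if (is.null(patient)) e$patient else as.character(patient)
  if (length(patient) != ncol(e$values))
    stop("patient labels must match cell count")
  if (any(table(patient) < 1L)) stop("patient with zero cells")
  er <- e$values
  for (p in unique(patient)) {
    j <- patient == p
    er[, j] <- er[, j, drop = FALSE] -
      rowMeans(er[, j, drop = FALSE])
  }
  structure(list(values = er, genes = rownames(er), cells = colnames(er),
                 patient = patient),
            class = "centered_matrix")
}

#' @export
print.centered_matrix <- function(x, ...) {
  cat(sprintf("centered_matrix: %d genes x %d cells, %d patient(s)\n",
              nrow(x$values), ncol(x$values), length(unique(x$patient))))
  invisible(x)
}

#' Stem-marker (LGR5) gating of cultures
#'
#' Scores each culture as total transcript counts of a marker gene divided
#' by the culture's cell number, and calls the culture positive when the
#' score strictly exceeds the threshold. A score of exactly 1 is negative.
#'
#' @param m a [count_matrix()].
#' @param gene marker gene identifier (default `"LGR5"`); if absent, all
#'   scores are 0 with a warning.
#' @param threshold strict positivity threshold.
#' @return A data.frame with one row per patient: `patient`, `score`,
#'   `n_cells`, `positive`.
#' @export
lgr5_score <- function(m, gene = "LGR5", threshold = 1.0) {
  stopifnot(inherits(m, "count_matrix"))
  pats <- unique(m$patient)
  if (!gene %in% m$genes) {
    warning("gene '", gene, "' not present; all scores set to 0")
    cnt <- rep(0, ncol(m$counts))
  } else {
    cnt <- as.numeric(m$counts[gene, ])
  }
  tot <- tapply(cnt, factor(m$patient, levels = pats), sum)
  n <- tapply(cnt, factor(m$patient, levels = pats), length)
  score <- as.numeric(tot) / as.numeric(n)
  data.frame(patient = pats, score = score, n_cells = as.integer(n),
             positive = lgr5_positive(score, threshold),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Strict positivity gate on marker scores
#'
#' @param score numeric marker scores (transcripts per cell).
#' @param threshold strict lower bound; a score equal to the threshold is
#'   negative.
#' @return Logical vector.
#' @export
lgr5_positive <- function(score, threshold = 1.0) score > threshold

#' Per-patient differential expression (one vs rest)
#'
#' For every patient with at least 3 cells, tests each gene by a two-sided
#' Wilcoxon rank-sum test of that patient's cells against all other cells,
#' adjusts p-values per patient by Benjamini-Hochberg, and reports genes
#' passing `adj_p < alpha` and log fold-change strictly greater than
#' `min_lfc` (mean E in patient minus mean E in the rest), ranked by
#' adjusted p then decreasing |log-FC|.
#'
#' @param e an [expression_matrix()].
#' @param alpha adjusted-p cutoff (strict).
#' @param min_lfc log2 fold-change cutoff (strict, up in patient).
#' @param top_n genes reported per patient.
#' @return A data.frame with columns `patient`, `gene`, `lfc`, `p`,
#'   `adj_p`, `rank`.
#' @export
de_genes_per_patient <- function(e, alpha = 0.05, min_lfc = 0.25,
                                 top_n = 10L) {
  stopifnot(inherits(e, "expression_matrix"))
  pats <- unique(e$patient)
  if (length(pats) < 2L) stop("need at least 2 patients")
  out <- list()
  for (p in pats) {
    j <- e$patient == p
    if (sum(j) < 3L) {
      warning("patient '", p, "' has fewer than 3 cells; excluded")
      next
    }
    x <- e$values[, j, drop = FALSE]
    y <- e$values[, !j, drop = FALSE]
    lfc <- rowMeans(x) - rowMeans(y)
    pv <- vapply(seq_len(nrow(x)), function(i) {
      if (all(x[i, ] == x[i, 1L]) && all(y[i, ] == x[i, 1L])) return(1)
      suppressWarnings(wilcox.test(x[i, ], y[i, ], exact = FALSE)$p.value)
    }, numeric(1))
    pv[is.na(pv)] <- 1
    adj <- p.adjust(pv, method = "BH")
    sel <- which(adj < alpha & lfc > min_lfc)
    if (length(sel) == 0L) next
    ord <- sel[order(adj[sel], -abs(lfc[sel]))]
    ord <- head(ord, top_n)
    out[[p]] <- data.frame(patient = p, gene = rownames(x)[ord],
                           lfc = lfc[ord], p = pv[ord], adj_p = adj[ord],
                           rank = seq_along(ord), row.names = NULL,
                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(patient = character(), gene = character(),
                      lfc = numeric(), p = numeric(), adj_p = numeric(),
                      rank = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
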