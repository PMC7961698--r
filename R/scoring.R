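# Gene bins by aggregate expression (linear CPM/10 scale), equal-occupancy.
expression_bins <- function(e, n_bins = 25L) {
  agg <- rowMeans(2^e$values - 1)
  rk <- rank(agg, ties.method = "first")
  as.integer(ceiling(rk / length(rk) * n_bins))
}

#' Background-corrected signature scoring of cells
#'
#' Scores every cell for a signature as the mean expression (E values) of
#' the signature genes present in the matrix, minus the mean expression of
#' a control gene set that matches the signature's expression profile: all
#' genes are binned by aggregate expression (equal-occupancy bins on the
#' linear CPM/10 scale) and, for each signature gene, `n_control_per_gene`
#' control genes are drawn from the same bin (without replacement where the
#' bin allows, with replacement otherwise). The subtraction cancels
#' technical covariates such as library complexity that shift all genes of
#' an expression stratum together.
#'
#' @param e an [expression_matrix()] of uncentered E values.
#' @param sig a [signature()].
#' @param n_bins number of aggregate-expression bins.
#' @param n_control_per_gene control genes sampled per signature gene.
#' @param seed integer seed for control sampling.
#' @param min_present minimum fraction of signature genes that must be
#'   present in the matrix.
#' @return A data.frame with per-cell `raw`, `control`, `corrected` scores;
#'   attributes `"mean"` and `"sd"` (population SD) of the corrected score
#'   and `"n_present"`.
#' @export
score_cells <- function(e, sig, n_bins = 25L, n_control_per_gene = 100L,
                        seed = 1L, min_present = 0.5) {
  stopifnot(inherits(e, "expression_matrix"), inherits(sig, "signature"))
  present <- intersect(sig$genes, rownames(e$values))
  if (length(present) == 0L)
    stop("no signature genes present in the matrix")
  if (length(present) < min_present * length(sig$genes))
    stop(sprintf("only %d/%d signature genes present (< %.0f%%)",
                 length(present), length(sig$genes), 100 * min_present))
  bins <- expression_bins(e, n_bins)
  names(bins) <- rownames(e$values)
  raw <- colMeans(e$values[present, , drop = FALSE])

  ctrl <- with_seed(seed, {
    lapply(present, function(g) {
      pool <- names(bins)[bins == bins[[g]]]
      if (length(pool) >= n_control_per_gene)
        sample(pool, n_control_per_gene)
      else sample(pool, n_control_per_gene, replace = TRUE)
    })
  })
  ctrl <- unlist(ctrl)
  tab <- table(ctrl)
  idx <- match(names(tab), rownames(e$values))
  control <- as.numeric(crossprod(
    e$values[idx, , drop = FALSE], as.numeric(tab))) / length(ctrl)
  # crossprod above computes t(E[idx,]) %*% weights => per-cell weighted sum
  corrected <- raw - control
  res <- data.frame(cell = colnames(e$values), raw = as.numeric(raw),
                    control = control, corrected = corrected,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "mean") <- mean(corrected)
  attr(res, "sd") <- sd_pop(corrected)
  attr(res, "n_present") <- length(present)
  res
}

# Population standard deviation (divisor n, not n-1).
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Score a set of signatures, returning a cells x signatures matrix
#'
#' Convenience wrapper around [score_cells()]; column `s` holds the
#' background-corrected score of signature `s` for every cell.
#'
#' @inheritParams score_cells
#' @param sigs list of [signature()] objects (names taken from each).
#' @return Numeric matrix cells x signatures of corrected scores.
#' @export
score_signatures <- function(e, sigs, n_bins = 25L,
                             n_control_per_gene = 100L, seed = 1L,
                             min_present = 0.5) {
  stopifnot(length(sigs) >= 1L)
  cols <- lapply(seq_along(sigs), function(i)
    score_cells(e, sigs[[i]], n_bins, n_control_per_gene,
                seed = seed + i - 1L, min_present = min_present)$corrected)
  m <- do.call(cbind, cols)
  dimnames(m) <- list(colnames(e$values),
                      vapply(sigs, function(s) s$name, character(1)))
  m
}

#' Combine correlated signatures into meta-signatures
#'
#' Signatures whose per-cell score patterns agree describe the same
#' underlying program (factor splitting is a known NNMF artifact). Score
#' vectors are clustered by complete linkage on the distance
#' `1 - Pearson r`, the tree is cut at height `1 - r_threshold`, and each
#' cluster becomes one meta-signature whose gene list is the union of its
#' members' lists, ordered by each gene's best (minimum) rank across
#' members (ties by gene identifier).
#'
#' @param scores cells x signatures matrix of corrected scores (columns
#'   named; e.g., from [score_signatures()]).
#' @param sigs list of the [signature()] objects that produced `scores`.
#' @param r_threshold minimum Pearson correlation for two signatures to be
#'   merged.
#' @return List of [signature()] objects (meta-signatures); each carries
#'   attribute `"members"` with the member signature names.
#' @export
combine_meta_signatures <- function(scores, sigs, r_threshold = 0.6) {
  stopifnot(is.matrix(scores), length(sigs) == ncol(scores))
  if (ncol(scores) < 2L) stop("need at least 2 signatures")
  sig_names <- vapply(sigs, function(s) s$name, character(1))
  stopifnot(identical(colnames(scores), sig_names))
  r <- suppressWarnings(cor(scores))
  r[!is.finite(r)] <- 0
  d <- as.dist(1 - r)
  cl <- cutree(hclust(d, method = "complete"), h = 1 - r_threshold)
  out <- list()
  for (g in sort(unique(cl))) {
    members <- which(cl == g)
    ranks <- list()
    for (i in members) {
      gs <- sigs[[i]]$genes
      for (k in seq_along(gs)) {
        gene <- gs[k]
        if (is.null(ranks[[gene]]) || ranks[[gene]] > k) ranks[[gene]] <- k
      }
    }
    genes <- names(ranks)[order(unlist(ranks), names(ranks))]
    ms <- signature(name = paste0("meta_", paste(sig_names[members],
                                                 collapse = "+")),
                    genes = genes)
    attr(ms, "members") <- sig_names[members]
    out[[length(out) + 1L]] <- ms
  }
  out
}

#' Cell-type assignment from type meta-signature scores
#'
#' A program is called active in a cell when its background-corrected
#' score strictly exceeds the mean plus one population standard deviation
#' of that program's scores across all cells. Each cell is assigned to the
#' active program with the highest corrected score; cells with no active
#' program are `"unassigned"`. Constant score columns (zero SD) yield no
#' active cells.
#'
#' @param scores cells x type-signatures matrix of corrected scores with
#'   column names.
#' @param sd_mult multiple of the SD added to the mean (default 1).
#' @return An object of class \code{cell_type_assignment}: data.frame with
#'   `cell`, `assigned`, plus attribute `"active"` (logical cells x
#'   programs matrix) and `"thresholds"`.
#' @export
assign_cell_types <- function(scores, sd_mult = 1) {
  stopifnot(is.matrix(scores), !is.null(colnames(scores)))
  mu <- colMeans(scores)
  sdv <- apply(scores, 2, sd_pop)
  thr <- mu + sd_mult * sdv
  active <- sweep(scores, 2, thr, ">")
  active[, sdv == 0] <- FALSE
  assigned <- rep("unassigned", nrow(scores))
  for (i in seq_len(nrow(scores))) {
    act <- which(active[i, ])
    if (length(act) > 0L)
      assigned[i] <- colnames(scores)[act[which.max(scores[i, act])]]
  }
  res <- data.frame(cell = rownames(scores) %||% seq_len(nrow(scores)),
                    assigned = assigned, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(res) <- c("cell_type_assignment", "data.frame")
  attr(res, "active") <- active
  attr(res, "thresholds") <- thr
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise comparison of state-program scores across cell types
#'
#' For every state signature and every pair of assigned cell types with at
#' least 2 cells each, compares the state's corrected scores between the
#' two types by a two-tailed Mann-Whitney (Wilcoxon rank-sum) test and
#' reports the U statistic, p-value, and per-group median and quartiles.
#'
#' @param assignment a \code{cell_type_assignment}.
#' @param state_scores cells x state-signatures matrix of corrected scores
#'   (rows aligned with `assignment`).
#' @return A data.frame with one row per (state, type pair).
#' @export
compare_states_across_types <- function(assignment, state_scores) {
  stopifnot(inherits(assignment, "cell_type_assignment"),
            is.matrix(state_scores),
            nrow(state_scores) == nrow(assignment))
  types <- setdiff(unique(assignment$assigned), "unassigned")
  out <- list()
  for (s in colnames(state_scores)) {
    for (a_i in seq_along(types)) for (b_i in seq_along(types)) {
      if (a_i >= b_i) next
      ta <- types[a_i]; tb <- types[b_i]
      xa <- state_scores[assignment$assigned == ta, s]
      xb <- state_scores[assignment$assigned == tb, s]
      if (length(xa) < 2L || length(xb) < 2L) {
        warning("fewer than 2 cells in a compared group; pair skipped")
        next
      }
      wt <- suppressWarnings(
        wilcox.test(xa, xb, alternative = "two.sided"))
      qa <- quantile(xa, c(0.25, 0.5, 0.75), names = FALSE)
      qb <- quantile(xb, c(0.25, 0.5, 0.75), names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        state = s, type_a = ta, type_b = tb,
        n_a = length(xa), n_b = length(xb),
        U = unname(wt$statistic), p = wt$p.value,
        median_a = qa[2], q1_a = qa[1], q3_a = qa[3],
        median_b = qb[2], q1_b = qb[1], q3_b = qb[3],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) stop("no comparable type pairs")
  do.call(rbind, out)
}
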