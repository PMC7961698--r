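#' Single-cell count matrix with per-cell metadata
#'
#' Lightweight container for a genes x cells matrix of raw integer counts
#' together with the per-cell metadata the QC stage needs. Counts may be a
#' base matrix or a sparse \code{Matrix::dgCMatrix}.
#'
#' @param counts genes x cells matrix of non-negative integers; must carry
#'   row (gene) and column (cell) names, or they are generated.
#' @param patient character/factor of length \code{ncol(counts)}: culture or
#'   patient label per cell.
#' @param total_reads optional per-cell sequenced-read totals (library
#'   reads, not UMI counts) used by the read-depth QC rules.
#' @param mito_fraction optional per-cell fraction of mitochondrial reads in
#'   \code{[0, 1]}. When missing it is derived from genes whose symbol starts
#'   with \code{"MT-"} (standard human annotation), as a fraction of counts.
#' @return An object of class \code{count_matrix}: a list with elements
#'   \code{counts}, \code{genes}, \code{cells}, \code{patient},
#'   \code{total_reads}, \code{mito_fraction}.
#' @export
count_matrix <- function(counts, patient, total_reads = NULL,
                         mito_fraction = NULL) {
  if (length(dim(counts)) != 2L) stop("'counts' must be a matrix")
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("'counts' must have positive dimensions")
  cnt <- if (inherits(counts, "Matrix")) counts else as.matrix(counts)
  v <- if (inherits(cnt, "Matrix")) cnt@x else cnt
  if (any(v < 0)) stop("counts must be non-negative")
  if (any(v != round(v))) stop("counts must be integral")
  if (is.null(rownames(cnt)))
    rownames(cnt) <- sprintf("gene%0*d", nchar(nrow(cnt)), seq_len(nrow(cnt)))
  if (anyDuplicated(rownames(cnt)))
    stop("duplicate gene identifiers are not allowed")
  if (is.null(colnames(cnt)))
    colnames(cnt) <- sprintf("cell%0*d", nchar(ncol(cnt)), seq_len(ncol(cnt)))
  patient <- as.character(patient)
  if (length(patient) != ncol(cnt))
    stop("'patient' must have one label per cell")
  if (!is.null(total_reads) && length(total_reads) != ncol(cnt))
    stop("'total_reads' must have one value per cell")
  if (is.null(mito_fraction)) {
    mt <- startsWith(rownames(cnt), "MT-")
    tot <- Matrix::colSums(cnt)
    mito_fraction <- if (any(mt)) {
      as.numeric(Matrix::colSums(cnt[mt, , drop = FALSE]) / pmax(tot, 1))
    } else rep(0, ncol(cnt))
  }
  if (length(mito_fraction) != ncol(cnt))
    stop("'mito_fraction' must have one value per cell")
  if (any(mito_fraction < 0 | mito_fraction > 1))
    stop("'mito_fraction' must lie in [0, 1]")
  structure(list(counts = cnt, genes = rownames(cnt), cells = colnames(cnt),
                 patient = patient,
                 total_reads = if (is.null(total_reads)) NULL
                               else as.numeric(total_reads),
                 mito_fraction = as.numeric(mito_fraction)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells, %d patient(s)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$patient))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# Subset a count_matrix by cell index, keeping metadata aligned.
subset_cells <- function(m, keep) {
  structure(list(counts = m$counts[, keep, drop = FALSE], genes = m$genes,
                 cells = m$cells[keep], patient = m$patient[keep],
                 total_reads = m$total_reads[keep],
                 mito_fraction = m$mito_fraction[keep]),
            class = "count_matrix")
}

#' Log-normalized expression matrix
#'
#' Container for E = log2(CPM/10 + 1) values as produced by
#' [normalize_cpm_log()]. Gene aggregate expression (`ea`) is attached by
#' [filter_low_expression()].
#'
#' @param values genes x cells numeric matrix of E values (log2 units, >= 0).
#' @param patient per-cell patient labels.
#' @param ea optional per-gene aggregate expression.
#' @return An object of class \code{expression_matrix}.
#' @export
expression_matrix <- function(values, patient, ea = NULL) {
  stopifnot(is.matrix(values), length(patient) == ncol(values))
  if (any(values < 0)) stop("E values must be non-negative")
  structure(list(values = values, genes = rownames(values),
                 cells = colnames(values), patient = as.character(patient),
                 ea = ea),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$ea)) "" else " (Ea attached)"))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Gene signature
#'
#' A named, ranked gene list, typically the top-loading genes of one NNMF
#' factor ([extract_signature()]) or the combined list of a meta-signature.
#'
#' @param name signature name.
#' @param genes character vector of unique gene identifiers, ranked.
#' @param source_factor optional integer id of the originating factor.
#' @return An object of class \code{signature}.
#' @export
signature <- function(name, genes, source_factor = NA_integer_) {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("a signature needs at least one gene")
  if (anyDuplicated(genes)) stop("signature genes must be unique")
  structure(list(name = as.character(name), genes = genes,
                 source_factor = source_factor),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("signature '%s': %d genes (%s%s)\n", x$name, length(x$genes),
              paste(head(x$genes, 3L), collapse = ", "),
              if (length(x$genes) > 3L) ", ..." else ""))
  invisible(x)
}

#' Bulk expression cohort with survival annotations
#'
#' @param expr samples x genes numeric matrix of log-scale expression.
#' @param time non-negative survival/progression times.
#' @param event 0/1 event indicators.
#' @param covariates optional data.frame of per-sample covariates.
#' @param cluster optional externally known per-sample labels (e.g., the
#'   generating archetype of a simulated cohort).
#' @return An object of class \code{bulk_cohort}.
#' @export
bulk_cohort <- function(expr, time, event, covariates = NULL, cluster = NULL) {
  stopifnot(is.matrix(expr))
  if (nrow(expr) < 2L) stop("degenerate cohort: need at least 2 samples")
  n <- nrow(expr)
  if (length(time) != n || length(event) != n)
    stop("survival vectors must match sample count")
  if (any(time < 0)) stop("survival times must be >= 0")
  if (!all(event %in% c(0, 1))) stop("events must be 0/1")
  structure(list(expr = expr, time = as.numeric(time),
                 event = as.integer(event), covariates = covariates,
                 cluster = cluster),
            class = "bulk_cohort")
}

#' @export
print.bulk_cohort <- function(x, ...) {
  cat(sprintf("bulk_cohort: %d samples x %d genes, %d events\n",
              nrow(x$expr), ncol(x$expr), sum(x$event)))
  invisible(x)
}

#' Limiting-dilution assay table
#'
#' One row per cell dose: number of wells (or mice) tested and number
#' positive (sphere or tumor formation).
#'
#' @param dose positive cell doses.
#' @param tested wells tested per dose.
#' @param positive positive wells per dose.
#' @param condition optional condition label for the whole assay.
#' @return A data.frame of class \code{dilution_assay}.
#' @export
dilution_assay <- function(dose, tested, positive, condition = NA_character_) {
  if (length(dose) < 1L) stop("need at least one dose row")
  if (length(tested) != length(dose) || length(positive) != length(dose))
    stop("dose, tested and positive must have equal length")
  if (any(dose <= 0)) stop("doses must be positive")
  if (any(tested < 1) || any(tested != round(tested)))
    stop("'tested' must be positive integers")
  if (any(positive < 0) || any(positive > tested) ||
      any(positive != round(positive)))
    stop("'positive' must be integers in [0, tested]")
  structure(data.frame(dose = as.numeric(dose), tested = as.integer(tested),
                       positive = as.integer(positive),
                       condition = condition,
                       stringsAsFactors = FALSE),
            class = c("dilution_assay", "data.frame"))
}

# Run expr with a local, restorable RNG state seeded at `seed`; global
# .Random.seed is untouched by any generator call.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}
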