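# Atomic text write: write to a temp file in the same directory, then
# rename. Rename is atomic on one filesystem, so a failed write never
# leaves a partial file behind.
atomic_write <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not move temporary file onto ", path)
  invisible(path)
}

#' Read a count matrix from MTX triplet or dense TSV
#'
#' The MTX layout is `matrix.mtx` (Matrix Market, genes x cells) with
#' `genes.tsv` (one gene id per line) and `barcodes.tsv` (tab-separated:
#' cell id, patient, and optionally total_reads and mito_fraction) in the
#' same directory. The TSV layout is one dense genes x cells table with
#' gene ids in the first column and cell ids as header, plus a metadata
#' TSV supplied via `meta`.
#'
#' @param path directory (MTX) or matrix file (TSV).
#' @param format `"mtx"` or `"tsv"`.
#' @param meta for `format = "tsv"`: path of the per-cell metadata TSV
#'   with columns `cell`, `patient` and optionally `total_reads`,
#'   `mito_fraction`.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, format = c("mtx", "tsv"), meta = NULL) {
  format <- match.arg(format)
  if (format == "mtx") {
    mtx <- file.path(path, "matrix.mtx")
    gf <- file.path(path, "genes.tsv")
    bf <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, gf, bf))
      if (!file.exists(f)) stop("missing file: ", f)
    m <- tryCatch(Matrix::readMM(mtx),
                  error = function(e) stop("MTX parse error: ",
                                           conditionMessage(e)))
    genes <- read.delim(gf, header = FALSE,
                        stringsAsFactors = FALSE)[[1L]]
    bc <- read.delim(bf, header = TRUE, stringsAsFactors = FALSE)
    if (nrow(m) != length(genes))
      stop("dimension mismatch: ", nrow(m), " matrix rows vs ",
           length(genes), " genes")
    if (ncol(m) != nrow(bc))
      stop("dimension mismatch: ", ncol(m), " matrix columns vs ",
           nrow(bc), " barcodes")
    if (any(m@x != round(m@x))) stop("non-integer entries in MTX")
    dimnames(m) <- list(genes, bc$cell)
    count_matrix(m, patient = bc$patient,
                 total_reads = bc$total_reads,
                 mito_fraction = bc$mito_fraction)
  } else {
    tab <- read.delim(path, header = TRUE, row.names = 1L,
                      check.names = FALSE)
    m <- as.matrix(tab)
    if (is.null(meta)) stop("missing metadata: supply 'meta' for TSV input")
    md <- read.delim(meta, header = TRUE, stringsAsFactors = FALSE)
    if (!all(c("cell", "patient") %in% names(md)))
      stop("metadata must have columns 'cell' and 'patient'")
    if (!setequal(md$cell, colnames(m)))
      stop("metadata cells do not match matrix columns")
    md <- md[match(colnames(m), md$cell), ]
    count_matrix(m, patient = md$patient,
                 total_reads = md$total_reads,
                 mito_fraction = md$mito_fraction)
  }
}

#' Write a count matrix as MTX triplet or dense TSV
#'
#' All files are written atomically (temporary file + rename).
#'
#' @param m a [count_matrix()].
#' @param path output directory (MTX) or matrix file (TSV).
#' @param format `"mtx"` or `"tsv"`.
#' @param meta for TSV: metadata output path (defaults to
#'   `<path>.meta.tsv`).
#' @return The path, invisibly.
#' @export
write_counts <- function(m, path, format = c("mtx", "tsv"), meta = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  format <- match.arg(format)
  bc <- data.frame(cell = m$cells, patient = m$patient,
                   stringsAsFactors = FALSE)
  if (!is.null(m$total_reads)) bc$total_reads <- m$total_reads
  if (!is.null(m$mito_fraction)) bc$mito_fraction <- m$mito_fraction
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    sp <- methods::as(methods::as(Matrix::Matrix(m$counts, sparse = TRUE),
                                  "generalMatrix"), "CsparseMatrix")
    atomic_write(function(f) Matrix::writeMM(sp, f),
                 file.path(path, "matrix.mtx"))
    atomic_write(function(f) writeLines(m$genes, f),
                 file.path(path, "genes.tsv"))
    atomic_write(function(f) write.table(bc, f, sep = "\t",
                                         row.names = FALSE, quote = FALSE),
                 file.path(path, "barcodes.tsv"))
    invisible(path)
  } else {
    atomic_write(function(f) write.table(
      data.frame(gene = m$genes, as.matrix(m$counts),
                 check.names = FALSE),
      f, sep = "\t", row.names = FALSE, quote = FALSE), path)
    meta <- meta %||% paste0(path, ".meta.tsv")
    atomic_write(function(f) write.table(bc, f, sep = "\t",
                                         row.names = FALSE, quote = FALSE),
                 meta)
    invisible(path)
  }
}

#' Read gene signatures from a GMT file
#'
#' One signature per line: name, description, then tab-separated genes.
#'
#' @param path GMT file path.
#' @return Named list of [signature()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("GMT line with fewer than 3 fields: ", substr(l, 1, 40))
    signature(parts[1L], parts[-(1:2)])
  })
  names(out) <- vapply(out, function(s) s$name, character(1))
  out
}

#' Write gene signatures to a GMT file
#'
#' @param sigs list of [signature()] objects.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(sigs, path) {
  lines <- vapply(sigs, function(s)
    paste(c(s$name, "na", s$genes), collapse = "\t"), character(1))
  atomic_write(function(f) writeLines(lines, f), path)
}

#' Pipeline configuration with validated defaults
#'
#' Bundles every stage parameter of the spheroid analysis chain; the
#' defaults are the published analysis settings (QC read/gene/mito
#' cutoffs, Ea cutoff 3.5, k = 25 NNMF with 10 restarts, the <50%
#' overlap / >= 5 patients factor-exclusion rule, 200-gene signatures,
#' 25-bin background scoring). Unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed above, e.g. `k = 10`.
#' @return A validated list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    min_reads = 1e5, min_genes = 1000L, max_mito = 0.15,
    top_read_quantile = 0.05, pca_outlier_sd = NULL,
    min_ea = 3.5, ea_aggregate = "linear",
    lgr5_gene = "LGR5", lgr5_threshold = 1.0,
    k = 25L, nnmf_seed = 1L, n_restarts = 10L,
    max_iter = 500L, tol = 1e-4,
    overlap_threshold = 0.5, min_patients = 5L, overlap_bins = 50L,
    signature_top_n = 200L,
    score_bins = 25L, n_control_per_gene = 100L, score_seed = 1L,
    r_threshold = 0.6,
    type_programs = c("stem", "TA", "Paneth", "Tdiff"),
    survival_alpha = 0.1)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- defaults
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  num_pos <- c("min_reads", "min_genes", "k", "n_restarts", "max_iter",
               "signature_top_n", "score_bins", "n_control_per_gene",
               "overlap_bins", "min_patients")
  for (f in num_pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1)
      stop("config field '", f, "' must be a positive number")
  }
  for (f in c("max_mito", "top_read_quantile", "overlap_threshold")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("config field '", f, "' must lie in [0, 1]")
  }
  if (!cfg$ea_aggregate %in% c("linear", "log"))
    stop("config field 'ea_aggregate' must be 'linear' or 'log'")
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_config()] returns a validated \code{pipeline_config};
#'   [write_config()] returns the path invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param cfg a \code{pipeline_config}.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  x <- unclass(cfg)
  x <- x[!vapply(x, is.null, logical(1))]
  atomic_write(function(f) yaml::write_yaml(x, f), path)
}
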