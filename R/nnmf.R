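#' Non-negative matrix factorization of centered expression
#'
#' Factorizes the per-patient centered expression (negative residuals
#' clipped to 0) as `V ~ W %*% H` with non-negative gene loadings `W`
#' (genes x k) and cell scores `H` (k x cells). The fit uses alternating
#' least squares with projection to the non-negative orthant, random
#' uniform initialization, and multiple restarts; the restart with the
#' lowest Frobenius reconstruction error wins. Within a restart the
#' recorded error trajectory is non-increasing: if a projected ALS step
#' increases the error the step is reverted and the restart stops.
#'
#' @param er a \code{centered_matrix} (from [mean_center_by_patient()]) or
#'   a non-negative numeric matrix. Negative entries are clipped to 0.
#' @param k number of factors.
#' @param seed integer seed; restart `r` uses `seed + r - 1`.
#' @param n_restarts independent random restarts.
#' @param max_iter maximum ALS iterations per restart.
#' @param tol stop when the relative error change drops below `tol`.
#' @return An object of class \code{nnmf_fit}: list with `W`, `H`, `k`,
#'   `reconstruction_error` (Frobenius), `error_trace` (best restart),
#'   `restart_errors`, `seed`, `n_restarts`, and `patient` labels when the
#'   input carried them.
#' @export
fit_nnmf <- function(er, k = 25L, seed = 1L, n_restarts = 10L,
                     max_iter = 500L, tol = 1e-4) {
  patient <- NULL
  if (inherits(er, "centered_matrix")) {
    patient <- er$patient
    v <- er$values
  } else {
    v <- as.matrix(er)
  }
  if (any(!is.finite(v))) stop("input must be finite")
  v <- pmax(v, 0)
  if (all(v == 0)) stop("all-zero matrix cannot be factorized")
  if (k > min(dim(v)))
    stop("k must not exceed min(genes, cells)")
  if (k < 1L) stop("k must be >= 1")

  best <- NULL
  restart_errors <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(seed + r - 1L,
                     nnmf_als_once(v, k, max_iter = max_iter, tol = tol))
    restart_errors[r] <- fit$error
    if (is.null(best) || fit$error < best$error) best <- fit
  }
  dimnames(best$W) <- list(rownames(v), paste0("factor", seq_len(k)))
  dimnames(best$H) <- list(paste0("factor", seq_len(k)), colnames(v))
  structure(list(W = best$W, H = best$H, k = as.integer(k),
                 reconstruction_error = best$error,
                 error_trace = best$trace,
                 restart_errors = restart_errors,
                 seed = seed, n_restarts = as.integer(n_restarts),
                 patient = patient),
            class = "nnmf_fit")
}

# One projected-ALS run. Returns W, H, final Frobenius error and the
# (non-increasing) per-iteration error trace.
nnmf_als_once <- function(v, k, max_iter, tol) {
  ng <- nrow(v); nc <- ncol(v)
  scale0 <- sqrt(mean(v) / k)
  w <- matrix(runif(ng * k, 0, 2 * scale0), ng, k)
  h <- matrix(runif(k * nc, 0, 2 * scale0), k, nc)
  ridge <- 1e-10
  frob <- function(w, h) sqrt(sum((v - w %*% h)^2))
  err <- frob(w, h)
  trace <- err
  for (it in seq_len(max_iter)) {
    wtw <- crossprod(w) + diag(ridge, k)
    h_new <- pmax(solve(wtw, crossprod(w, v)), 0)
    hht <- tcrossprod(h_new) + diag(ridge, k)
    w_new <- pmax(t(solve(hht, tcrossprod(h_new, v))), 0)
    err_new <- frob(w_new, h_new)
    if (err_new > err + 1e-12) break  # revert-and-stop safeguard
    w <- w_new; h <- h_new
    delta <- (err - err_new) / max(err, .Machine$double.eps)
    err <- err_new
    trace <- c(trace, err)
    if (delta < tol) break
  }
  list(W = w, H = h, error = err, trace = trace)
}

#' @export
print.nnmf_fit <- function(x, ...) {
  cat(sprintf(
    "nnmf_fit: %d genes x %d cells, k = %d\n  Frobenius error %.4g (best of %d restarts)\n",
    nrow(x$W), ncol(x$H), x$k, x$reconstruction_error, x$n_restarts))
  invisible(x)
}

#' @export
summary.nnmf_fit <- function(object, ...) {
  cat(sprintf("NNMF with k = %d (seed %s, %d restarts)\n",
              object$k, format(object$seed), object$n_restarts))
  cat(sprintf("  reconstruction error: %.6g\n",
              object$reconstruction_error))
  cat(sprintf("  restart errors: %s\n",
              paste(signif(object$restart_errors, 4), collapse = ", ")))
  cat(sprintf("  iterations (best restart): %d\n",
              length(object$error_trace) - 1L))
  invisible(object)
}

#' @export
coef.nnmf_fit <- function(object, ...) object$W

# Histogram-intersection overlap between two score vectors on shared
# equal-width bins spanning their pooled range. Returns a value in [0, 1].
hist_overlap <- function(x, y, breaks) {
  hx <- tabulate(findInterval(x, breaks, all.inside = TRUE),
                 nbins = length(breaks) - 1L)
  hy <- tabulate(findInterval(y, breaks, all.inside = TRUE),
                 nbins = length(breaks) - 1L)
  sum(pmin(hx / sum(hx), hy / sum(hy)))
}

#' Exclusion of patient-specific factors
#'
#' A factor driven by a single patient's private biology or batch shows
#' cell-score distributions that do not overlap between that patient and
#' the others. For each factor, per-patient histograms of the factor's cell
#' scores are formed on shared equal-width bins spanning the pooled score
#' range, and each patient pair's overlap is the histogram intersection
#' (sum of bin-wise minima of the two normalized histograms). A patient
#' "fails" a factor when its median pairwise overlap with the other
#' patients falls below `overlap_threshold`; the factor is excluded when at
#' least `min_patients` patients fail. Setting `min_patients = 1` gives the
#' stricter variant that drops a factor as soon as any single patient
#' separates from the rest.
#'
#' @param model an \code{nnmf_fit}.
#' @param patient per-cell patient labels (defaults to those in `model`).
#' @param overlap_threshold minimum median pairwise overlap.
#' @param min_patients failing patients required for exclusion.
#' @param n_bins shared histogram bins.
#' @return Integer vector of retained factor indices, with attribute
#'   `"overlap"` (factor x patient matrix of median pairwise overlaps) and
#'   `"excluded"`.
#' @export
filter_patient_specific_factors <- function(model, patient = NULL,
                                            overlap_threshold = 0.5,
                                            min_patients = 5L,
                                            n_bins = 50L) {
  stopifnot(inherits(model, "nnmf_fit"))
  patient <- if (is.null(patient)) model$patient else as.character(patient)
  if (is.null(patient)) stop("patient labels required")
  if (length(patient) != ncol(model$H))
    stop("patient labels must match cell count")
  pats <- unique(patient)
  if (length(pats) < 2L) stop("need at least 2 patients")
  if (length(pats) < min_patients) {
    warning("fewer patients than 'min_patients'; exclusion rule ",
            "inapplicable, all factors retained")
    return(structure(seq_len(model$k),
                     overlap = NULL, excluded = integer(0)))
  }
  med_overlap <- matrix(NA_real_, model$k, length(pats),
                        dimnames = list(rownames(model$H), pats))
  for (f in seq_len(model$k)) {
    s <- model$H[f, ]
    rng <- range(s)
    if (rng[1] == rng[2]) { med_overlap[f, ] <- 1; next }
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    by_pat <- split(s, factor(patient, levels = pats))
    ov <- matrix(1, length(pats), length(pats))
    for (a in seq_along(pats)) for (b in seq_along(pats)) {
      if (a < b) {
        o <- hist_overlap(by_pat[[a]], by_pat[[b]], breaks)
        ov[a, b] <- o; ov[b, a] <- o
      }
    }
    med_overlap[f, ] <- vapply(seq_along(pats), function(a)
      median(ov[a, -a]), numeric(1))
  }
  failing <- rowSums(med_overlap < overlap_threshold)
  excluded <- which(failing >= min_patients)
  retained <- setdiff(seq_len(model$k), excluded)
  structure(retained, overlap = med_overlap, excluded = excluded)
}

#' Top-gene signature of a factor
#'
#' Ranks genes by their loading on one factor (descending, ties broken by
#' gene identifier for stability) and returns the top `top_n` as a
#' [signature()]. If the factor has fewer than `top_n` strictly positive
#' loadings the signature is padded by tie order and flagged degenerate
#' (attribute `"degenerate"`, with `"n_positive"` recording the meaningful
#' prefix length).
#'
#' @param model an \code{nnmf_fit}.
#' @param factor_id factor index.
#' @param top_n signature length.
#' @return A [signature()].
#' @export
extract_signature <- function(model, factor_id, top_n = 200L) {
  stopifnot(inherits(model, "nnmf_fit"))
  if (factor_id < 1L || factor_id > model$k) stop("no such factor")
  w <- model$W[, factor_id]
  if (top_n > length(w)) stop("top_n exceeds gene count")
  ord <- order(-w, names(w))
  genes <- names(w)[ord][seq_len(top_n)]
  sig <- signature(name = paste0("factor", factor_id), genes = genes,
                   source_factor = as.integer(factor_id))
  n_pos <- sum(w[genes] > 0)
  if (n_pos < top_n) {
    attr(sig, "degenerate") <- TRUE
    attr(sig, "n_positive") <- n_pos
  }
  sig
}
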