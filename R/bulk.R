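#' Mean-expression signature scores for a bulk cohort
#'
#' For each sample, the score of a signature is the mean log expression
#' over the signature genes present in the cohort. A signature with fewer
#' than `min_present` of its genes present raises an error; the fraction
#' of missing genes per signature is recorded.
#'
#' @param cohort a [bulk_cohort()].
#' @param sigs list of [signature()] objects.
#' @param min_present minimum fraction of signature genes that must be
#'   present.
#' @return Numeric matrix samples x signatures with attribute
#'   `"missing_fraction"`.
#' @export
score_bulk <- function(cohort, sigs, min_present = 0.5) {
  stopifnot(inherits(cohort, "bulk_cohort"), length(sigs) >= 1L)
  genes <- colnames(cohort$expr)
  out <- matrix(NA_real_, nrow(cohort$expr), length(sigs))
  miss <- numeric(length(sigs))
  nm <- vapply(sigs, function(s) s$name, character(1))
  for (i in seq_along(sigs)) {
    present <- intersect(sigs[[i]]$genes, genes)
    miss[i] <- 1 - length(present) / length(sigs[[i]]$genes)
    if (length(present) < min_present * length(sigs[[i]]$genes))
      stop(sprintf("signature '%s': only %d/%d genes present", nm[i],
                   length(present), length(sigs[[i]]$genes)))
    out[, i] <- rowMeans(cohort$expr[, present, drop = FALSE])
  }
  dimnames(out) <- list(rownames(cohort$expr), nm)
  attr(out, "missing_fraction") <- setNames(miss, nm)
  out
}

# Binary split of a score submatrix: complete-linkage hierarchical
# clustering cut at two branches, then (for Euclidean splits) a
# nearest-centroid consolidation seeded from the branch centroids. The
# consolidation leaves clean cuts untouched but repairs the occasional
# complete-linkage cut that isolates a handful of extreme samples as one
# branch. Returns a logical vector, TRUE for the branch with the higher
# mean score over `label_by` columns.
split2 <- function(scores, cols, method = c("euclidean", "correlation"),
                   label_by = cols) {
  method <- match.arg(method)
  if (nrow(scores) < 2L) stop("a split received fewer than 2 samples")
  x <- scores[, cols, drop = FALSE]
  d <- if (method == "euclidean") {
    dist(x)
  } else {
    r <- suppressWarnings(cor(t(x)))
    r[!is.finite(r)] <- 0
    as.dist(1 - r)
  }
  grp <- cutree(hclust(d, method = "complete"), k = 2L)
  if (method == "euclidean") {
    cen <- rbind(colMeans(x[grp == 1L, , drop = FALSE]),
                 colMeans(x[grp == 2L, , drop = FALSE]))
    if (nrow(unique(cen)) == 2L)
      grp <- suppressWarnings(kmeans(x, centers = cen)$cluster)
  }
  m1 <- mean(scores[grp == 1L, label_by])
  m2 <- mean(scores[grp == 2L, label_by])
  if (m1 >= m2) grp == 1L else grp == 2L
}

#' Progressive six-cluster stratification of bulk samples
#'
#' Subdivides the sample space in five sequential binary splits on
#' signature scores, yielding clusters cl1-cl6. Each split is a
#' complete-linkage hierarchical clustering cut at two branches:
#' \enumerate{
#'   \item `OXPHOS_1`, `G1S`, `G2M`, `stem` (Euclidean): the high branch is
#'     \{cl2, cl3\}, the rest continues.
#'   \item `hypoxia_glycolysis_1`, `TNFA_2` (Euclidean) within the high
#'     branch: low = cl2, high = cl3.
#'   \item `fatty_acid`, `TNFA_1` (Euclidean) within the rest: high = cl1.
#'   \item `stem`, `TA` (correlation distance between samples) within the
#'     remainder: the branch with the lower mean stem score is cl6.
#'   \item `G1S`, `G2M`, `OXPHOS_1` (Euclidean) within \{cl4, cl5\}:
#'     medium = cl4, low = cl5.
#' }
#'
#' @param scores samples x signatures score matrix; must contain columns
#'   `stem`, `TA`, `OXPHOS_1`, `G1S`, `G2M`, `hypoxia_glycolysis_1`,
#'   `TNFA_1`, `TNFA_2`, `fatty_acid`.
#' @return An object of class \code{cluster_assignment}: data.frame with
#'   `sample` and `cluster` (factor cl1-cl6), plus attribute `"profile"`
#'   with per-cluster mean signature scores.
#' @export
progressive_cluster <- function(scores) {
  needed <- c("stem", "TA", "OXPHOS_1", "G1S", "G2M",
              "hypoxia_glycolysis_1", "TNFA_1", "TNFA_2", "fatty_acid")
  if (!all(needed %in% colnames(scores)))
    stop("missing signature columns: ",
         paste(setdiff(needed, colnames(scores)), collapse = ", "))
  n <- nrow(scores)
  lab <- rep(NA_character_, n)
  idx <- seq_len(n)

  s1_cols <- c("OXPHOS_1", "G1S", "G2M", "stem")
  hi <- split2(scores, s1_cols)                      # {cl2, cl3}
  hi_idx <- idx[hi]; rest_idx <- idx[!hi]

  cl3 <- split2(scores[hi_idx, , drop = FALSE],
                c("hypoxia_glycolysis_1", "TNFA_2"))  # high = cl3
  lab[hi_idx[cl3]] <- "cl3"
  lab[hi_idx[!cl3]] <- "cl2"

  cl1 <- split2(scores[rest_idx, , drop = FALSE],
                c("fatty_acid", "TNFA_1"))            # high = cl1
  lab[rest_idx[cl1]] <- "cl1"
  low_idx <- rest_idx[!cl1]

  stem_hi <- split2(scores[low_idx, , drop = FALSE], c("stem", "TA"),
                    method = "correlation", label_by = "stem")
  lab[low_idx[!stem_hi]] <- "cl6"
  c45_idx <- low_idx[stem_hi]

  cl4 <- split2(scores[c45_idx, , drop = FALSE],
                c("G1S", "G2M", "OXPHOS_1"))          # medium = cl4
  lab[c45_idx[cl4]] <- "cl4"
  lab[c45_idx[!cl4]] <- "cl5"

  cluster <- factor(lab, levels = paste0("cl", 1:6))
  profile <- t(vapply(levels(cluster), function(cl)
    colMeans(scores[cluster == cl, , drop = FALSE]),
    numeric(ncol(scores))))
  res <- data.frame(sample = rownames(scores) %||% idx, cluster = cluster,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("cluster_assignment", "data.frame")
  attr(res, "profile") <- profile
  res
}

#' Kaplan-Meier curves and log-rank comparison
#'
#' Fits per-group Kaplan-Meier survival estimates with 95% confidence
#' intervals and compares the groups by the log-rank test. Any grouping
#' vector is accepted, so merged contrasts (e.g., cl4+cl5+cl6 versus
#' cl1+cl2+cl3) are formed by relabeling before the call.
#'
#' @param group per-sample group labels (>= 2 distinct values).
#' @param time survival/progression times.
#' @param event 0/1 event indicators (>= 1 event overall).
#' @return List with `fit` (a \code{survfit} object), `chisq`, `df`, `p`.
#' @export
km_logrank <- function(group, time, event) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) stop("need at least 2 groups")
  if (sum(event) < 1L) stop("need at least 1 event")
  s <- survival::Surv(time, event)
  fit <- survival::survfit(s ~ group, conf.int = 0.95)
  sd_ <- survival::survdiff(s ~ group)
  df <- length(sd_$n) - 1L
  p <- pchisq(sd_$chisq, df = df, lower.tail = FALSE)
  list(fit = fit, chisq = unname(sd_$chisq), df = df, p = p)
}

#' Likelihood-ratio comparison of nested Cox models
#'
#' Fits proportional-hazards models with and without the cluster labels on
#' top of the base covariates and compares them by the likelihood-ratio
#' chi-square on the partial log-likelihood difference (df = parameters
#' added by the cluster term). Constant covariate columns are dropped with
#' a warning; non-convergence of either fit is raised as an error rather
#' than silently ignored.
#'
#' @param time,event survival outcome.
#' @param base data.frame of base covariates (may be NULL for a null base
#'   model).
#' @param cluster per-sample cluster labels.
#' @return List with `chisq`, `df`, `p`, `fit_base`, `fit_full`.
#' @export
cox_model_comparison <- function(time, event, base = NULL, cluster) {
  cluster <- droplevels(as.factor(cluster))
  if (nlevels(cluster) < 2L) stop("need at least 2 cluster levels")
  dat <- data.frame(.time = time, .event = event, .cluster = cluster)
  base_terms <- character(0)
  if (!is.null(base)) {
    base <- as.data.frame(base)
    keep <- vapply(base, function(x) length(unique(x)) > 1L, logical(1))
    if (any(!keep))
      warning("constant covariate(s) dropped: ",
              paste(names(base)[!keep], collapse = ", "))
    base <- base[, keep, drop = FALSE]
    if (ncol(base) > 0L) {
      names(base) <- make.names(names(base))
      dat <- cbind(dat, base)
      base_terms <- names(base)
    }
  }
  rhs_base <- if (length(base_terms)) paste(base_terms, collapse = " + ")
              else "1"
  f0 <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs_base))
  f1 <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                rhs_base, "+ .cluster"))
  fit0 <- survival::coxph(f0, data = dat)
  fit1 <- survival::coxph(f1, data = dat)
  for (f in list(fit1)) {
    if (!is.null(f$info) && grepl("did not converge", paste(f$info)))
      stop("Cox model did not converge")
  }
  ll0 <- if (length(fit0$loglik) == 2L) fit0$loglik[2L] else fit0$loglik[1L]
  ll1 <- fit1$loglik[2L]
  df <- sum(!is.na(coef(fit1))) -
    (if (rhs_base == "1") 0L else sum(!is.na(coef(fit0))))
  chisq <- 2 * (ll1 - ll0)
  list(chisq = chisq, df = df,
       p = pchisq(chisq, df = df, lower.tail = FALSE),
       fit_base = fit0, fit_full = fit1)
}
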