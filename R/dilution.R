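# Single-hit Poisson log-likelihood of frequency f for a dose/response
# table: each well of dose d is negative with probability exp(-f*d).
ld_loglik <- function(f, assay) {
  if (f < 0) return(-Inf)
  d <- assay$dose; n <- assay$tested; r <- assay$positive
  if (f == 0) return(if (sum(r) > 0) -Inf else 0)
  p_neg <- exp(-f * d)
  sum(r * log1p(-p_neg) + (n - r) * (-f * d))
}

#' Single-hit Poisson frequency estimation from a limiting-dilution assay
#'
#' Under the single-hit model a well seeded with `d` cells stays negative
#' with probability `exp(-f * d)`, where `f` is the frequency of
#' sphere-forming (or tumor-initiating) cells. The maximum-likelihood
#' estimate of `f` is found by Brent optimization on `log f`
#' (tolerance 1e-10), and the 95% confidence interval by likelihood-ratio
#' inversion at the chi-square(1) 0.95 quantile (3.841). Boundary cases
#' are flagged: all wells negative gives `f = 0` with a one-sided upper
#' bound; all wells positive gives `f = 1` (the domain's upper edge) with
#' a one-sided lower bound.
#'
#' @param assay a [dilution_assay()].
#' @param conf.level confidence level for the likelihood-ratio interval.
#' @return An object of class \code{frequency_estimate}: list with `f`
#'   (cells^-1), `one_over` (1/f), `ci` (lower, upper on f), `loglik`,
#'   `boundary` (`"none"`, `"all_negative"` or `"all_positive"`), and the
#'   input `assay`.
#' @export
estimate_frequency <- function(assay, conf.level = 0.95) {
  stopifnot(inherits(assay, "dilution_assay"))
  crit <- qchisq(conf.level, df = 1L)
  r_tot <- sum(assay$positive)
  n_tot <- sum(assay$tested)

  ll_at <- function(f) ld_loglik(f, assay)

  if (r_tot == 0L) {
    # all negative: likelihood maximal at f = 0
    upper <- uniroot(function(f) -2 * (ll_at(f) - 0) - crit,
                     lower = 1e-12, upper = 1, tol = 1e-12)$root
    return(new_frequency_estimate(0, c(0, upper), 0, "all_negative", assay))
  }
  if (r_tot == n_tot) {
    # all positive: likelihood increases monotonically in f
    f_hat <- 1
    ll_hat <- ll_at(1)
    lower <- uniroot(function(f) 2 * (ll_hat - ll_at(f)) - crit,
                     lower = 1e-12, upper = 1, tol = 1e-12)$root
    return(new_frequency_estimate(f_hat, c(lower, 1), ll_hat,
                                  "all_positive", assay))
  }

  opt <- optimize(function(lf) ll_at(exp(lf)),
                  interval = c(log(1e-12), 0), maximum = TRUE,
                  tol = 1e-10)
  f_hat <- min(exp(opt$maximum), 1)
  # Newton polish of the score equation for closed-form-grade precision
  d <- assay$dose; n <- assay$tested; rr <- assay$positive
  for (it in 1:8) {
    em <- exp(-f_hat * d)
    score <- sum(rr * d * em / (1 - em)) - sum((n - rr) * d)
    hess <- -sum(rr * d^2 * em / (1 - em)^2)
    if (!is.finite(score) || !is.finite(hess) || hess >= 0) break
    step <- score / hess
    f_new <- f_hat - step
    if (f_new <= 0 || f_new > 1) break
    f_hat <- f_new
    if (abs(step) < 1e-14 * f_hat) break
  }
  ll_hat <- ll_at(f_hat)
  g <- function(f) 2 * (ll_hat - ll_at(f)) - crit
  lower <- if (g(1e-12) > 0)
    uniroot(g, lower = 1e-12, upper = f_hat, tol = 1e-14)$root else 0
  upper <- if (f_hat < 1 && g(1) > 0)
    uniroot(g, lower = f_hat, upper = 1, tol = 1e-14)$root else 1
  new_frequency_estimate(f_hat, c(lower, upper), ll_hat, "none", assay)
}

new_frequency_estimate <- function(f, ci, loglik, boundary, assay) {
  structure(list(f = f, one_over = if (f > 0) 1 / f else Inf,
                 ci = setNames(ci, c("lower", "upper")), loglik = loglik,
                 boundary = boundary, assay = assay),
            class = "frequency_estimate")
}

#' @export
print.frequency_estimate <- function(x, ...) {
  fmt1 <- function(f) if (f <= 0) "0" else sprintf("1/%.1f", 1 / f)
  cat(sprintf("frequency_estimate: f = %s (95%% CI %s - %s)%s\n",
              fmt1(x$f), fmt1(x$ci[1L]), fmt1(x$ci[2L]),
              if (x$boundary != "none")
                paste0(" [boundary: ", x$boundary, "]") else ""))
  invisible(x)
}

#' @export
confint.frequency_estimate <- function(object, parm, level = 0.95, ...) {
  if (!missing(level) && level != 0.95)
    return(estimate_frequency(object$assay, conf.level = level)$ci)
  object$ci
}

#' @export
coef.frequency_estimate <- function(object, ...) c(f = object$f)

#' @export
logLik.frequency_estimate <- function(object, ...) {
  structure(object$loglik, df = 1L, class = "logLik")
}

#' Likelihood-ratio test of equal frequency between two assays
#'
#' Compares the hypothesis of a shared sphere-forming frequency against
#' separate frequencies for the two assays: the statistic is
#' `2 * (ll_a + ll_b - ll_pooled)`, referred to chi-square with 1 df.
#'
#' @param a,b [dilution_assay()] objects.
#' @return List with `statistic`, `p`, `estimate_a`, `estimate_b`,
#'   `ratio` (f_a / f_b).
#' @export
compare_frequencies <- function(a, b) {
  stopifnot(inherits(a, "dilution_assay"), inherits(b, "dilution_assay"))
  if (sum(a$positive) == 0L && sum(b$positive) == 0L)
    stop("both assays all-negative: frequencies are not identifiable")
  ea <- estimate_frequency(a)
  eb <- estimate_frequency(b)
  pooled <- dilution_assay(c(a$dose, b$dose), c(a$tested, b$tested),
                           c(a$positive, b$positive))
  ep <- estimate_frequency(pooled)
  stat <- max(0, 2 * (ea$loglik + eb$loglik - ep$loglik))
  list(statistic = stat, p = pchisq(stat, df = 1L, lower.tail = FALSE),
       estimate_a = ea, estimate_b = eb,
       ratio = if (eb$f > 0) ea$f / eb$f else Inf)
}

#' Normalize frequency estimates to a bulk reference
#'
#' Expresses each estimate as a ratio to the bulk population's frequency.
#' The ratio's confidence interval is propagated on the log scale as the
#' ratio of bounds: `lower = lower_a / upper_bulk`,
#' `upper = upper_a / lower_bulk`.
#'
#' @param estimates list of \code{frequency_estimate} objects (or a single
#'   one).
#' @param bulk the bulk \code{frequency_estimate}; must have `f > 0`.
#' @return A data.frame with `ratio`, `ci_lower`, `ci_upper` per estimate.
#' @export
normalize_to_bulk <- function(estimates, bulk) {
  stopifnot(inherits(bulk, "frequency_estimate"))
  if (bulk$f <= 0) stop("bulk frequency must be positive")
  if (inherits(estimates, "frequency_estimate"))
    estimates <- list(estimates)
  rows <- lapply(estimates, function(e) {
    data.frame(ratio = e$f / bulk$f,
               ci_lower = e$ci[1L] / bulk$ci[2L],
               ci_upper = e$ci[2L] / max(bulk$ci[1L], .Machine$double.xmin))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
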