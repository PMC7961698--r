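test_that("NNMF recovers an exact rank-1 factorization", {
  set.seed(1)
  u <- runif(40, 0.5, 2); v <- runif(25, 0.5, 2)
  m <- outer(u, v)
  fit <- fit_nnmf(m, k = 1, seed = 1, n_restarts = 2, max_iter = 200,
                  tol = 1e-12)
  expect_lt(fit$reconstruction_error / sqrt(sum(m^2)), 1e-6)
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
})

test_that("negative inputs are clipped before factorization", {
  set.seed(2)
  m <- matrix(rnorm(30 * 20), 30, 20)
  f1 <- fit_nnmf(m, k = 3, seed = 5, n_restarts = 2)
  f2 <- fit_nnmf(pmax(m, 0), k = 3, seed = 5, n_restarts = 2)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)
})

test_that("error trace is non-increasing and best restart wins", {
  set.seed(3)
  m <- pmax(matrix(rnorm(60 * 40, 1), 60, 40), 0)
  fit <- fit_nnmf(m, k = 4, seed = 2, n_restarts = 5)
  expect_true(all(diff(fit$error_trace) <= 1e-12))
  expect_true(all(fit$reconstruction_error <= fit$restart_errors + 1e-12))
  # deterministic given the seed
  fit2 <- fit_nnmf(m, k = 4, seed = 2, n_restarts = 5)
  expect_identical(fit$W, fit2$W)
  expect_error(fit_nnmf(m, k = 100), "k must not exceed")
  expect_error(fit_nnmf(matrix(0, 5, 5), k = 2), "all-zero")
})

test_that("planted programs surface as factors with high top-gene overlap", {
  cfg <- spheroid_sim_config(n_patients = 3, cells_per_patient = 200,
                             n_genes = 500, seed = 4)
  sim <- generate_spheroid_cohort(cfg)
  e <- filter_low_expression(normalize_cpm_log(sim$counts))
  ctr <- mean_center_by_patient(e)
  fit <- fit_nnmf(ctr, k = 10, seed = 1, n_restarts = 2, max_iter = 200)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  for (pn in c("stem", "TA", "Paneth", "Tdiff")) {
    planted <- intersect(sim$truth$programs[[pn]], rownames(e$values))
    best <- max(vapply(seq_len(fit$k), function(f)
      jac(extract_signature(fit, f, top_n = 50)$genes, planted),
      numeric(1)))
    expect_gte(best, 0.5)
  }
})

test_that("signature extraction ranks stably and flags degeneracy", {
  w <- matrix(0, 6, 2, dimnames = list(c("gB", "gA", "gD", "gC", "gE",
                                         "gF"), NULL))
  w[, 1] <- c(5, 5, 3, 3, 1, 0)
  w[2, 2] <- 7   # single non-zero loading
  fit <- make_fake_fit(matrix(1, 2, 4), rep("P1", 4))
  fit$W <- w; fit$k <- 2L
  sig <- extract_signature(fit, 1, top_n = 4)
  # descending loading, ties broken by gene identifier
  expect_equal(sig$genes, c("gA", "gB", "gC", "gD"))
  deg <- extract_signature(fit, 2, top_n = 3)
  expect_true(isTRUE(attr(deg, "degenerate")))
  expect_equal(attr(deg, "n_positive"), 1)
  expect_equal(deg$genes[1], "gA")
  expect_error(extract_signature(fit, 1, top_n = 99), "top_n")

  # permuting gene order leaves the signature set unchanged (exact
  # rank-3 block matrix, so the factorization is essentially unique)
  set.seed(9)
  wb <- matrix(0, 42, 3, dimnames = list(sprintf("g%02d", 1:42), NULL))
  for (b in 1:3) wb[(b - 1) * 14 + 1:14, b] <- 1 + 0.05 * (1:14)
  hb <- matrix(0, 3, 30)
  for (b in 1:3) hb[b, (b - 1) * 10 + 1:10] <- runif(10, 1, 2)
  m <- wb %*% hb
  perm <- sample(42)
  f1 <- fit_nnmf(m, k = 3, seed = 7, n_restarts = 3, tol = 1e-10)
  f2 <- fit_nnmf(m[perm, ], k = 3, seed = 7, n_restarts = 3, tol = 1e-10)
  s1 <- sort(vapply(1:3, function(f)
    paste(sort(extract_signature(f1, f, 10)$genes), collapse = ","),
    character(1)))
  s2 <- sort(vapply(1:3, function(f)
    paste(sort(extract_signature(f2, f, 10)$genes), collapse = ","),
    character(1)))
  expect_identical(s1, s2)
})

test_that("histogram-intersection overlap behaves at the extremes", {
  breaks <- seq(0, 1, length.out = 51)
  x <- runif(500, 0, 0.4); y <- runif(500, 0.6, 1)
  expect_equal(spheroprog:::hist_overlap(x, y, breaks), 0)
  expect_equal(spheroprog:::hist_overlap(x, x, breaks), 1)
})

test_that("patient-specific factor exclusion follows the printed rule", {
  set.seed(5)
  npat <- 8; ncell <- 40
  pat <- rep(paste0("P", 1:npat), each = ncell)
  n <- npat * ncell
  H <- rbind(shared = rnorm(n, 5, 1),           # same law everywhere
             private = c(rnorm(ncell, 20, 0.5), # only P1 expresses it
                         abs(rnorm(n - ncell, 0.1, 0.05))))
  fit <- make_fake_fit(H, pat)
  fit$k <- 2L

  # identical distributions -> retained; a single failing patient does not
  # reach the five-patient bar under the literal rule
  kept_default <- filter_patient_specific_factors(fit, min_patients = 5)
  expect_setequal(as.integer(kept_default), 1:2)
  ov <- attr(kept_default, "overlap")
  expect_lt(ov["private", "P1"], 0.05)

  # the strict variant (any single failing patient) excludes it
  kept_strict <- filter_patient_specific_factors(fit, min_patients = 1)
  expect_equal(as.integer(kept_strict), 1L)
  expect_equal(unname(attr(kept_strict, "excluded")), 2L)

  # relabeling patients and affine rescaling of H rows change nothing
  relab <- setNames(sample(paste0("Q", 1:npat)), paste0("P", 1:npat))
  kept_relab <- filter_patient_specific_factors(
    fit, patient = unname(relab[pat]), min_patients = 1)
  expect_equal(as.integer(kept_relab), as.integer(kept_strict))
  fit_scaled <- fit
  fit_scaled$H[2, ] <- 100 * fit_scaled$H[2, ] + 7
  kept_scaled <- filter_patient_specific_factors(fit_scaled,
                                                 min_patients = 1)
  expect_equal(as.integer(kept_scaled), as.integer(kept_strict))

  # fewer patients than the bar -> rule inapplicable, warning
  fit2 <- make_fake_fit(H[, 1:(2 * ncell), drop = FALSE], pat[1:(2 * ncell)])
  fit2$k <- 2L
  expect_warning(res <- filter_patient_specific_factors(fit2,
                                                        min_patients = 5),
                 "inapplicable")
  expect_setequal(as.integer(res), 1:2)
})
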