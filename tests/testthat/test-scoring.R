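test_that("a constant expression matrix scores exactly zero", {
  vals <- matrix(3, 50, 20,
                 dimnames = list(paste0("g", 1:50), paste0("c", 1:20)))
  e <- make_em(vals)
  sc <- score_cells(e, signature("s", paste0("g", 1:10)), n_bins = 5)
  expect_equal(sc$corrected, rep(0, 20))
})

test_that("scores are null for a bin-matched random signature", {
  set.seed(21)
  ng <- 200; nc <- 1000
  # homogeneous cells: every gene has one expression level shared by all
  lev <- runif(ng, 0, 8)
  vals <- matrix(lev, ng, nc,
                 dimnames = list(paste0("g", 1:ng), paste0("c", 1:nc))) +
    matrix(rnorm(ng * nc, 0, 0.1), ng, nc)
  vals <- pmax(vals, 0)
  e <- make_em(vals)
  bins <- spheroprog:::expression_bins(e, 25)
  pool <- paste0("g", which(bins == 13L))
  sig <- signature("null_sig", sample(pool, min(8, length(pool))))
  sc <- score_cells(e, sig, n_bins = 25, seed = 3)
  expect_lt(abs(mean(sc$corrected)), 0.05)
})

test_that("a planted program separates its cells with high AUROC", {
  set.seed(22)
  ng <- 300; nc <- 400
  vals <- matrix(rnorm(ng * nc, 4, 0.5), ng, nc,
                 dimnames = list(paste0("g", 1:ng), paste0("c", 1:nc)))
  inset <- 1:80
  vals[1:30, inset] <- vals[1:30, inset] + 2  # program up in a subset
  vals <- pmax(vals, 0)
  e <- make_em(vals)
  sc <- score_cells(e, signature("prog", paste0("g", 1:30)), seed = 5)
  pos <- sc$corrected[inset]; neg <- sc$corrected[-inset]
  auroc <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_gte(auroc, 0.9)
})

test_that("background subtraction cancels a bin-wide constant shift", {
  set.seed(23)
  ng <- 60; nc <- 50
  # three widely separated expression strata -> stable bin membership
  lev <- rep(c(1, 4, 8), each = 20)
  vals <- matrix(lev, ng, nc,
                 dimnames = list(paste0("g", 1:ng), paste0("c", 1:nc))) +
    matrix(runif(ng * nc, 0, 0.05), ng, nc)
  e <- make_em(vals)
  sig <- signature("s", paste0("g", 21:30))  # all from stratum 2
  s1 <- score_cells(e, sig, n_bins = 3, seed = 9)
  shifted <- vals
  shifted[21:40, ] <- shifted[21:40, ] + 0.01  # whole bin shifted
  s2 <- score_cells(make_em(shifted), sig, n_bins = 3, seed = 9)
  expect_equal(s2$corrected, s1$corrected, tolerance = 1e-10)
})

test_that("score_cells enforces signature presence", {
  e <- make_em(matrix(1:20, 4, 5,
                      dimnames = list(paste0("g", 1:4), NULL)) * 1.0)
  expect_error(score_cells(e, signature("s", c("x", "y"))), "no signature")
  expect_error(score_cells(e, signature("s", c("g1", "x", "y"))), "present")
})

test_that("meta-signature combination merges by score correlation", {
  set.seed(24)
  n <- 300
  base <- rnorm(n)
  scores <- cbind(a = base + rnorm(n, 0, 0.2),
                  b = base + rnorm(n, 0, 0.2),   # near-duplicate of a
                  c = -base + rnorm(n, 0, 0.2),  # anti-correlated
                  d = rnorm(n))                  # independent
  sigs <- list(signature("a", paste0("x", 1:5)),
               signature("b", c("x3", "x4", "y1", "y2", "y3")),
               signature("c", paste0("z", 1:5)),
               signature("d", paste0("w", 1:5)))
  metas <- combine_meta_signatures(scores, sigs, r_threshold = 0.6)
  members <- lapply(metas, attr, "members")
  merged <- members[[which(vapply(members, function(m) "a" %in% m,
                                  logical(1)))]]
  expect_setequal(merged, c("a", "b"))
  expect_false(any(vapply(members, function(m)
    all(c("a", "c") %in% m), logical(1))))
  # union gene list keeps best-rank order
  ms <- metas[[which(vapply(members, function(m) "a" %in% m, logical(1)))]]
  expect_setequal(ms$genes, c(paste0("x", 1:5), "y1", "y2", "y3"))
  expect_equal(ms$genes[1], "x1")

  # a duplicated signature always collapses into one meta-signature
  dup <- cbind(a = base, b = base)
  m2 <- combine_meta_signatures(dup, sigs[1:2], r_threshold = 0.6)
  expect_length(m2, 1)
})

test_that("state co-activation drives merging at oracle-derived thresholds", {
  # Cell-cycle and OXPHOS co-activated in TA cells at coupling 0.9. The
  # planted activation patterns correlate at ~0.68, which count noise,
  # CPM compositional coupling and background sampling attenuate to a
  # score correlation of ~0.43 (simulation oracle): the pair merges at a
  # permissive threshold and stays distinct at a strict one.
  coup <- matrix(c(0.05, 0.05, 0.05,
                   0.90, 0.90, 0.05,
                   0.05, 0.05, 0.05,
                   0.05, 0.05, 0.80),
                 nrow = 4, byrow = TRUE,
                 dimnames = list(c("stem", "TA", "Paneth", "Tdiff"),
                                 c("cell_cycle", "OXPHOS",
                                   "hypoxia_glycolysis")))
  cfg <- spheroid_sim_config(n_patients = 2, cells_per_patient = 300,
                             n_genes = 400, state_coupling = coup,
                             seed = 12)
  sim <- generate_spheroid_cohort(cfg)
  e <- filter_low_expression(normalize_cpm_log(sim$counts))
  sigs <- lapply(c("cell_cycle", "OXPHOS"), function(pn)
    signature(pn, intersect(sim$truth$programs[[pn]], rownames(e$values))))
  sc <- score_signatures(e, sigs, seed = 2)
  m_loose <- combine_meta_signatures(sc, sigs, r_threshold = 0.35)
  m_tight <- combine_meta_signatures(sc, sigs, r_threshold = 0.95)
  expect_length(m_loose, 1)
  expect_length(m_tight, 2)
})

test_that("activity threshold uses mean + 1 population SD, strictly", {
  sc <- cbind(sig = c(0, 0, 0, 0, 10))
  rownames(sc) <- paste0("c", 1:5)
  asg <- assign_cell_types(sc)
  act <- attr(asg, "active")
  # mean 2, population SD 4 -> threshold 6: only the 10-score cell active
  expect_equal(unname(attr(asg, "thresholds")), 6)
  expect_equal(unname(which(act[, 1])), 5L)
  expect_equal(asg$assigned, c(rep("unassigned", 4), "sig"))

  # constant scores: SD 0, nothing active
  flat <- cbind(s1 = rep(3, 6), s2 = rep(1, 6))
  asg2 <- assign_cell_types(flat)
  expect_true(all(asg2$assigned == "unassigned"))
})

test_that("assigned type is always among the cell's active programs", {
  set.seed(25)
  sc <- matrix(rnorm(200 * 3), 200, 3,
               dimnames = list(NULL, c("A", "B", "C")))
  asg <- assign_cell_types(sc)
  act <- attr(asg, "active")
  ok <- vapply(seq_len(nrow(sc)), function(i)
    asg$assigned[i] == "unassigned" || act[i, asg$assigned[i]],
    logical(1))
  expect_true(all(ok))
})

test_that("state comparisons report exact Mann-Whitney results", {
  asg <- structure(data.frame(cell = paste0("c", 1:6),
                              assigned = rep(c("TA", "Tdiff"), each = 3)),
                   class = c("cell_type_assignment", "data.frame"))
  ss <- cbind(state = c(1, 2, 3, 4, 5, 6))
  rownames(ss) <- paste0("c", 1:6)
  res <- compare_states_across_types(asg, ss)
  # groups (1,2,3) vs (4,5,6): U = 0, exact two-tailed p = 2/20 = 0.1
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)
  expect_equal(res$median_a, 2)
  expect_equal(res$median_b, 5)

  # identical groups -> p = 1
  ss2 <- cbind(state = rep(c(1, 2, 3), 2))
  rownames(ss2) <- paste0("c", 1:6)
  res2 <- compare_states_across_types(asg, ss2)
  expect_equal(res2$p, 1)
})
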