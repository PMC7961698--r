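test_that("CPM/10 log2 normalization matches hand-computed values", {
  counts <- matrix(c(10, 999990,
                     20, 499980,
                     0, 1000), nrow = 2,
                   dimnames = list(c("gA", "gB"), c("c1", "c2", "c3")))
  cm <- make_cm(counts, rep("P1", 3))
  e <- normalize_cpm_log(cm)
  # 10 counts in a 1e6-count cell -> CPM 10 -> E = log2(2) = 1
  expect_equal(e$values["gA", "c1"], 1)
  # 20 counts in a 5e5-count cell -> CPM 40 -> E = log2(5)
  expect_equal(e$values["gA", "c2"], log2(5))
  # zero count -> E = 0
  expect_equal(e$values["gA", "c3"], 0)
})

test_that("per-cell CPM mass is recovered from E when no genes dropped", {
  set.seed(42)
  counts <- matrix(rpois(50 * 20, 30), 50, 20)
  counts[1, ] <- counts[1, ] + 1  # guard against zero-count cells
  cm <- make_cm(counts, rep("P1", 20))
  e <- normalize_cpm_log(cm)
  recovered <- colSums(2^e$values - 1) * 10
  expect_equal(recovered, rep(1e6, 20), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("normalization refuses zero-count cells", {
  counts <- matrix(c(1, 0), 1, 2)
  expect_error(normalize_cpm_log(make_cm(counts, c("P1", "P1"))),
               "zero-count")
})

test_that("aggregate-expression filter respects the strict boundary", {
  # log-scale aggregation: gene kept iff mean(E) >= 2^3.5 - 1
  b <- 2^3.5 - 1
  vals <- rbind(exact = rep(b, 4), below = rep(b - 1e-6, 4),
                above = rep(b + 1, 4), zero = rep(0, 4))
  e <- make_em(vals)
  kept <- filter_low_expression(e, min_ea = 3.5, aggregate = "log")
  expect_setequal(rownames(kept$values), c("exact", "above"))
  expect_equal(unname(kept$ea["exact"]), 3.5)
})

test_that("linear aggregation thresholds the mean CPM/10 scale", {
  b <- 2^3.5 - 1
  vals <- rbind(hi = log2(rep(b, 4) + 1), lo = log2(rep(b - 1e-4, 4) + 1))
  e <- make_em(vals)
  kept <- filter_low_expression(e, min_ea = 3.5, aggregate = "linear")
  expect_equal(rownames(kept$values), "hi")
  # an all-zero gene has Ea = 0 and is removed under both conventions
  e0 <- make_em(rbind(z = rep(0, 4), hi = log2(rep(b, 4) + 1)))
  expect_false("z" %in%
    rownames(filter_low_expression(e0, aggregate = "linear")$values))
})

test_that("per-patient centering zeroes patient means and is idempotent", {
  set.seed(7)
  vals <- matrix(rnorm(30 * 12, 5, 2), 30, 12)
  vals <- pmax(vals, 0)
  pat <- rep(c("A", "B", "C"), each = 4)
  e <- make_em(vals, pat)
  ctr <- mean_center_by_patient(e)
  for (p in unique(pat)) {
    expect_true(all(abs(rowMeans(ctr$values[, pat == p])) < 1e-9))
  }
  # two cells with E = (1, 3) -> Er = (-1, +1)
  e2 <- make_em(matrix(c(1, 3), 1, 2), c("A", "A"))
  expect_equal(as.numeric(mean_center_by_patient(e2)$values), c(-1, 1))
  # a one-cell patient centers to all zeros
  e1 <- make_em(matrix(c(1, 3, 2), 1, 3), c("A", "A", "B"))
  expect_equal(as.numeric(mean_center_by_patient(e1)$values[, 3]), 0)
  # idempotence
  ctr2 <- mean_center_by_patient(
    structure(list(values = ctr$values, patient = ctr$patient),
              class = "expression_matrix"))
  expect_equal(ctr2$values, ctr$values)
})

test_that("QC thresholds are strict and the top-read rule is per patient", {
  n <- 10
  counts <- matrix(5L, 20, n,
                   dimnames = list(paste0("g", 1:20), paste0("c", 1:n)))
  reads <- rep(2e5, n)
  reads[1] <- 99999    # below
  reads[2] <- 100000   # exactly at the bound: removed (strict >)
  mito <- rep(0.05, n)
  mito[3] <- 0.15      # exactly at the bound: removed (strict <)
  cm <- make_cm(counts, rep("P1", n), reads, mito)
  kept <- qc_filter(cm, min_reads = 1e5, min_genes = 10, max_mito = 0.15,
                    top_read_quantile = 0)
  expect_setequal(kept$cells, paste0("c", 4:10))

  # 100 identical-read cells per patient -> the 5% rule removes exactly 5,
  # ties broken by stable cell order (first five cells go)
  n2 <- 200
  cm2 <- make_cm(matrix(5L, 20, n2), rep(c("P1", "P2"), each = 100),
                 rep(3e5, n2), rep(0.01, n2))
  kept2 <- qc_filter(cm2, min_reads = 1e5, min_genes = 10,
                     max_mito = 0.15, top_read_quantile = 0.05)
  expect_equal(ncol(kept2$counts), 190)
  summ <- attr(kept2, "qc_summary")
  expect_equal(summ$removed[summ$rule == "top_reads"], 10)
  expect_false(any(c(cm2$cells[1:5], cm2$cells[101:105]) %in% kept2$cells))
})

test_that("QC is an intersection of criteria plus the survivor top-read rule", {
  set.seed(11)
  n <- 60
  counts <- matrix(rpois(20 * n, 8), 20, n)
  reads <- runif(n, 5e4, 5e5)
  mito <- runif(n, 0, 0.3)
  cm <- make_cm(counts, rep(c("P1", "P2"), each = 30), reads, mito)
  kept <- qc_filter(cm, min_genes = 3)
  pass <- reads > 1e5 & colSums(counts > 0) > 3 & mito < 0.15
  manual <- which(pass)
  for (p in c("P1", "P2")) {
    idx <- manual[cm$patient[manual] == p]
    drop_n <- floor(0.05 * length(idx))
    if (drop_n > 0) {
      ord <- idx[order(-reads[idx], idx)]
      manual <- setdiff(manual, ord[seq_len(drop_n)])
    }
  }
  expect_setequal(kept$cells, cm$cells[manual])
  expect_error(qc_filter(cm, min_reads = 1e9), "all cells")
  no_reads <- cm
  no_reads$total_reads <- NULL
  expect_error(qc_filter(no_reads), "total_reads")
})

test_that("marker gating is strict at the threshold", {
  counts <- matrix(0L, 2, 7,
                   dimnames = list(c("LGR5", "other"), paste0("c", 1:7)))
  counts["LGR5", 1:4] <- c(3L, 0L, 1L, 0L)   # patient A: 4 cells, total 4
  counts["other", ] <- 5L
  cm <- make_cm(counts, c(rep("A", 4), rep("B", 3)))
  g <- lgr5_score(cm)
  expect_equal(g$score[g$patient == "A"], 1.0)
  expect_false(g$positive[g$patient == "A"])  # score 1 is not > 1
  expect_equal(g$score[g$patient == "B"], 0)
  expect_false(g$positive[g$patient == "B"])
  expect_warning(lgr5_score(cm, gene = "ABSENT"), "not present")
})

test_that("per-patient DE reports planted genes and respects BH", {
  set.seed(3)
  ng <- 40; npat <- 3; ncell <- 100
  hits <- 0
  reps <- 20
  for (r in seq_len(reps)) {
    vals <- matrix(rnorm(ng * npat * ncell, 5, 1), ng)
    pat <- rep(paste0("P", 1:npat), each = ncell)
    vals[1, pat == "P1"] <- vals[1, pat == "P1"] + 2  # planted marker
    vals <- pmax(vals, 0)
    e <- make_em(vals, pat)
    de <- de_genes_per_patient(e, top_n = 10)
    if ("g1" %in% de$gene[de$patient == "P1"]) hits <- hits + 1
    if (r == 1) {
      expect_true(all(de$adj_p >= de$p))
      expect_false("g2" %in% de$gene[de$patient == "P1" & de$rank == 1])
    }
  }
  expect_gte(hits / reps, 0.95)
  # a constant gene is never reported
  vals <- matrix(rnorm(5 * 60, 5, 1), 5)
  vals[3, ] <- 4
  vals <- pmax(vals, 0)
  de <- de_genes_per_patient(make_em(vals, rep(c("A", "B"), each = 30)))
  expect_false("g3" %in% de$gene)
})
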