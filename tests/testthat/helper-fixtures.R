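# Small in-code fixtures shared across test files.

# A count_matrix with fully controlled metadata.
make_cm <- function(counts, patient, total_reads = NULL,
                    mito_fraction = NULL) {
  if (is.null(total_reads)) total_reads <- rep(2e5, ncol(counts))
  if (is.null(mito_fraction)) mito_fraction <- rep(0.05, ncol(counts))
  count_matrix(counts, patient, total_reads, mito_fraction)
}

# Deterministic expression_matrix from a plain matrix.
make_em <- function(values, patient = rep("P1", ncol(values))) {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("c", seq_len(ncol(values)))
  expression_matrix(values, patient)
}

# Minimal hand-built nnmf_fit for factor-filter tests.
make_fake_fit <- function(H, patient) {
  k <- nrow(H)
  structure(list(W = matrix(1, 4, k,
                            dimnames = list(paste0("g", 1:4),
                                            paste0("factor", 1:k))),
                 H = H, k = k, reconstruction_error = 0,
                 error_trace = 0, restart_errors = 0, seed = 1L,
                 n_restarts = 1L, patient = patient),
            class = "nnmf_fit")
}

# Shared settings for the end-to-end planted-program recovery run: the
# default synthetic cohort (8 patients x 200 cells, 4 type + 3 state
# programs at effect 2.0) analyzed with parameters scaled to the
# 1000-gene panel (k = 12, 50-gene signatures, 300-gene detection floor).
e2e_recovery <- function(sim_seed = 1L) {
  sim <- generate_spheroid_cohort(spheroid_sim_config(seed = sim_seed))
  cfg <- pipeline_config(min_genes = 300L, k = 12L, n_restarts = 3L,
                         max_iter = 300L, signature_top_n = 50L)
  res <- run_pipeline(sim$counts, cfg, lgr5_gate = TRUE)
  list(sim = sim, result = res,
       eval = evaluate_program_recovery(res, sim$truth))
}

# Memoized so the acceptance and integration tests share one run.
e2e_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- e2e_recovery(1L)
    cache
  }
})
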