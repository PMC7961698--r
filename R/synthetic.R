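#' Configuration for the synthetic spheroid cohort generator
#'
#' Defines the generative conditions for a multi-patient single-cell count
#' matrix with planted cell-type and cell-state expression programs.
#' Counts for gene i in cell j are drawn from a negative binomial with
#' mean `lib_j * 2^(b_i + o_{p(j),i} + sum of active program effects)`,
#' where `b_i` is a per-gene baseline (log2 scale), `o` a per-patient
#' per-gene offset (the dominant inter-patient structure of real
#' spheroid cohorts), `lib_j` a log-normal library-size factor, and the
#' negative-binomial shape captures scRNA-seq overdispersion
#' (`dispersion = Inf` gives the Poisson limit).
#'
#' Each cell has exactly one cell type (multinomial over
#' `cell_type_proportions`); the type's own program is active in the cell,
#' and each state program is activated by an independent Bernoulli draw
#' with probability `state_coupling[type, state]`, mirroring the observed
#' coupling of proliferation/metabolic states to cell types (e.g.,
#' transit-amplifying cells are enriched for cell-cycle and OXPHOS
#' activity, terminally differentiated cells for hypoxia/glycolysis).
#'
#' @param n_patients number of patients (cultures).
#' @param cells_per_patient cells per patient.
#' @param n_genes total genes.
#' @param programs named list; each element is a list with `genes`
#'   (integer indices into 1..n_genes) and `effect` (log2 shift when
#'   active). `NULL` builds the default four 50-gene type programs (stem,
#'   TA, Paneth, Tdiff) and three 50-gene state programs (cell_cycle,
#'   OXPHOS, hypoxia_glycolysis), all at effect `effect`.
#' @param effect log2 effect size used by the default program set.
#' @param patient_offset_sd SD (log2 units) of per-patient per-gene
#'   offsets.
#' @param library_size_log_mean,library_size_log_sd parameters of the
#'   log-normal library-size factor.
#' @param dispersion negative-binomial shape (`Inf` = Poisson).
#' @param cell_type_proportions simplex over the four cell types.
#' @param state_coupling matrix cell types x state programs of activation
#'   probabilities.
#' @param seed integer seed.
#' @return A list of class \code{spheroid_sim_config}.
#' @export
spheroid_sim_config <- function(n_patients = 8L, cells_per_patient = 200L,
                                n_genes = 1000L, programs = NULL,
                                effect = 2.0, patient_offset_sd = 0.5,
                                library_size_log_mean = 0,
                                library_size_log_sd = 0.3,
                                dispersion = 2,
                                cell_type_proportions = c(
                                  stem = 0.3, TA = 0.4,
                                  Paneth = 0.1, Tdiff = 0.2),
                                state_coupling = NULL,
                                seed = 1L) {
  if (n_patients < 1L || cells_per_patient < 1L || n_genes < 1L)
    stop("dimensions must be positive")
  if (is.null(programs)) {
    if (n_genes < 350L)
      stop("default program set needs at least 350 genes")
    nm <- c("stem", "TA", "Paneth", "Tdiff",
            "cell_cycle", "OXPHOS", "hypoxia_glycolysis")
    programs <- lapply(seq_along(nm), function(i)
      list(genes = ((i - 1L) * 50L + 1L):(i * 50L), effect = effect))
    names(programs) <- nm
  }
  for (nm in names(programs)) {
    p <- programs[[nm]]
    if (length(p$genes) == 0L) stop("empty program gene set: ", nm)
    if (length(p$genes) < 10L)
      stop("program '", nm, "' needs >= 10 member genes")
    if (!is.finite(p$effect)) stop("non-finite effect size: ", nm)
    if (any(p$genes < 1L | p$genes > n_genes))
      stop("program '", nm, "' references genes outside 1..n_genes")
  }
  if (abs(sum(cell_type_proportions) - 1) > 1e-8)
    stop("cell_type_proportions must sum to 1")
  types <- names(cell_type_proportions)
  states <- setdiff(names(programs), types)
  if (is.null(state_coupling)) {
    # graded activation across all compartments: states are enriched in,
    # not exclusive to, particular cell types, so every planted
    # program-pair activation correlation stays well below the default
    # meta-signature merge threshold (the programs remain distinct)
    state_coupling <- matrix(
      c(0.50, 0.70, 0.20,   # stem:   some cycling, OXPHOS-leaning
        0.75, 0.80, 0.10,   # TA:     proliferative, OXPHOS-high
        0.10, 0.40, 0.30,   # Paneth
        0.20, 0.10, 0.70),  # Tdiff:  hypoxia/glycolysis-high
      nrow = 4L, byrow = TRUE,
      dimnames = list(c("stem", "TA", "Paneth", "Tdiff"),
                      c("cell_cycle", "OXPHOS", "hypoxia_glycolysis")))
    state_coupling <- state_coupling[types, intersect(
      colnames(state_coupling), states), drop = FALSE]
  }
  if (length(states) > 0L &&
      (!all(types %in% rownames(state_coupling)) ||
       !all(states %in% colnames(state_coupling))))
    stop("state_coupling must cover all cell types and state programs")
  structure(list(n_patients = as.integer(n_patients),
                 cells_per_patient = as.integer(cells_per_patient),
                 n_genes = as.integer(n_genes), programs = programs,
                 patient_offset_sd = patient_offset_sd,
                 library_size_log_mean = library_size_log_mean,
                 library_size_log_sd = library_size_log_sd,
                 dispersion = dispersion,
                 cell_type_proportions = cell_type_proportions,
                 state_coupling = state_coupling,
                 seed = as.integer(seed)),
            class = "spheroid_sim_config")
}

#' Generate a synthetic multi-patient spheroid cohort
#'
#' Draws a count matrix and full ground truth from the generative model
#' described in [spheroid_sim_config()]. Reproducible: the same config
#' (including seed) always yields the same cohort, and the global RNG
#' state is untouched.
#'
#' @param config a [spheroid_sim_config()].
#' @return List with `counts` (a [count_matrix()]) and `truth` (list with
#'   `cells` data.frame of per-cell patient/type labels, `states` logical
#'   cells x state-programs matrix, `programs` mapping program name to
#'   member gene identifiers, and the drawn generative parameters
#'   `gene_baseline`, `patient_offsets`, `library_factor` so marginal
#'   moments can be checked against the generative formula).
#' @export
generate_spheroid_cohort <- function(config) {
  stopifnot(inherits(config, "spheroid_sim_config"))
  with_seed(config$seed, {
    np <- config$n_patients; nc <- config$cells_per_patient
    ng <- config$n_genes
    n_cells <- np * nc
    gene_ids <- sprintf("gene%04d", seq_len(ng))
    # the stem program carries the canonical stem marker so culture
    # gating can be exercised on synthetic cohorts
    if ("stem" %in% names(config$programs))
      gene_ids[config$programs$stem$genes[1L]] <- "LGR5"
    cell_ids <- sprintf("cell%05d", seq_len(n_cells))
    patient <- rep(sprintf("P%02d", seq_len(np)), each = nc)

    types <- names(config$cell_type_proportions)
    states <- setdiff(names(config$programs), types)
    prog_member <- sapply(config$programs, function(p)
      seq_len(ng) %in% p$genes)  # genes x programs logical

    # gene baselines: program members drawn from a tighter, higher stratum
    # so planted biology sits in the intermediate-to-high expression range
    in_any <- rowSums(prog_member) > 0
    baseline <- numeric(ng)
    baseline[in_any] <- rnorm(sum(in_any), 3.5, 1.0)
    baseline[!in_any] <- rnorm(sum(!in_any), 3.0, 1.5)

    offsets <- matrix(rnorm(np * ng, 0, config$patient_offset_sd), ng, np,
                      dimnames = list(gene_ids,
                                      sprintf("P%02d", seq_len(np))))

    cell_type <- sample(types, n_cells, replace = TRUE,
                        prob = config$cell_type_proportions)
    state_active <- matrix(FALSE, n_cells, length(states),
                           dimnames = list(cell_ids, states))
    for (s in states) {
      p_act <- config$state_coupling[cell_type, s]
      state_active[, s] <- runif(n_cells) < p_act
    }

    lib <- rlnorm(n_cells, config$library_size_log_mean,
                  config$library_size_log_sd)

    counts <- matrix(0L, ng, n_cells, dimnames = list(gene_ids, cell_ids))
    prog_names <- names(config$programs)
    effects <- vapply(config$programs, function(p) p$effect, numeric(1))
    for (j in seq_len(n_cells)) {
      active <- c(cell_type[j],
                  states[state_active[j, , drop = TRUE]])
      shift <- numeric(ng)
      for (a in active) {
        if (a %in% prog_names)
          shift[prog_member[, a]] <- shift[prog_member[, a]] + effects[[a]]
      }
      mu <- lib[j] * 2^(baseline + offsets[, match(patient[j],
                                                   colnames(offsets))] +
                          shift)
      counts[, j] <- if (is.infinite(config$dispersion)) rpois(ng, mu)
                     else rnbinom(ng, mu = mu, size = config$dispersion)
    }

    total_reads <- round(colSums(counts) * 25)  # reads per counted molecule
    mito_fraction <- rbeta(n_cells, 2, 31)

    cm <- count_matrix(counts, patient, total_reads = total_reads,
                       mito_fraction = mito_fraction)
    truth <- list(
      cells = data.frame(cell = cell_ids, patient = patient,
                         cell_type = cell_type, stringsAsFactors = FALSE),
      states = state_active,
      programs = lapply(config$programs, function(p) gene_ids[p$genes]),
      gene_baseline = setNames(baseline, gene_ids),
      patient_offsets = offsets,
      library_factor = setNames(lib, cell_ids))
    list(counts = cm, truth = truth)
  })
}

#' Default archetype shifts for the six bulk clusters
#'
#' Per-cluster mean shifts of the nine stratifying signatures, scaled by
#' `shift`. The profiles encode the relative high/medium/low levels that
#' define cl1-cl6: cl2/cl3 high in OXPHOS_1, G1/S, G2/M and stem (cl3
#' additionally high in hypoxia/glycolysis and TNFA_2), cl1 high in fatty
#' acid and TNFA_1, cl4/cl5 stem-high relative to TA (TA mildly below the
#' cohort average) with medium versus below-average proliferation/OXPHOS,
#' and cl6 stem-low. Magnitudes were fixed once so that the six archetypes
#' are well separated under the progressive splitting scheme at the
#' default noise scale.
#'
#' @param shift scale of the planted shifts (log2 expression units).
#' @return 6 x 9 numeric matrix, rows cl1-cl6.
#' @export
bulk_archetype_effects <- function(shift = 2) {
  sigs <- c("stem", "TA", "OXPHOS_1", "G1S", "G2M",
            "hypoxia_glycolysis_1", "TNFA_1", "TNFA_2", "fatty_acid")
  m <- rbind(
    cl1 = c(0,      0,     0,     0,     0,    0,   1, 0, 1),
    cl2 = c(1,      1,     1,     1,     1,    0,   0, 0, 0),
    cl3 = c(1,      1,     1,     1,     1,    1,   0, 1, 0),
    cl4 = c(0.5, -0.35,  0.4,   0.4,   0.4,    0,   0, 0, 0),
    cl5 = c(0.5, -0.35, -0.65, -0.65, -0.65,   0,   0, 0, 0),
    cl6 = c(0,      1,     0,     0,     0,    0,   0, 0, 0))
  colnames(m) <- sigs
  m * shift
}

#' Synthetic gene signatures for the bulk stratification
#'
#' Builds nine disjoint synthetic signatures matching the columns of
#' [bulk_archetype_effects()].
#'
#' @param genes_per_sig genes per signature.
#' @return Named list of [signature()] objects.
#' @export
bulk_signature_set <- function(genes_per_sig = 20L) {
  sigs <- colnames(bulk_archetype_effects())
  out <- lapply(seq_along(sigs), function(i) {
    signature(sigs[i], sprintf("%s_g%03d", sigs[i], seq_len(genes_per_sig)))
  })
  names(out) <- sigs
  out
}

#' Generate a synthetic bulk cohort with cluster-dependent survival
#'
#' Log expression of each signature gene is a gene baseline plus the
#' sample's cluster shift for that signature plus Gaussian noise.
#' Survival times are exponential with cluster-specific hazard
#' `base_hazard * hazard_ratios[cluster]`; censoring is an independent
#' exponential clock.
#'
#' @param n_samples total samples; clusters are assigned round-robin.
#' @param sigs named list of [signature()] objects (default
#'   [bulk_signature_set()]).
#' @param cluster_effects clusters x signatures shift matrix (default
#'   [bulk_archetype_effects()]).
#' @param hazard_ratios positive named vector, one per cluster; default
#'   gives the stem-low / low-proliferation clusters the poorer outcome.
#' @param noise_sd per-gene Gaussian noise SD.
#' @param base_hazard baseline exponential hazard (events per time unit).
#' @param censor_rate independent exponential censoring rate.
#' @param seed integer seed.
#' @return A [bulk_cohort()]; the generating cluster labels are stored in
#'   `$cluster`.
#' @export
generate_bulk_cohort <- function(n_samples = 328L,
                                 sigs = bulk_signature_set(),
                                 cluster_effects = bulk_archetype_effects(),
                                 hazard_ratios = c(cl1 = 1, cl2 = 1,
                                                   cl3 = 1, cl4 = 2,
                                                   cl5 = 2.5, cl6 = 3),
                                 noise_sd = 0.5, base_hazard = 0.1,
                                 censor_rate = 0.04, seed = 1L) {
  if (n_samples < 2L) stop("degenerate cohort: need >= 2 samples")
  clusters <- rownames(cluster_effects)
  if (length(clusters) < 2L) stop("need at least 2 clusters")
  if (any(hazard_ratios <= 0)) stop("hazard ratios must be positive")
  if (!all(clusters %in% names(hazard_ratios)))
    stop("hazard_ratios must name every cluster")
  with_seed(seed, {
    cl <- rep(clusters, length.out = n_samples)
    genes <- unlist(lapply(sigs, function(s) s$genes), use.names = FALSE)
    if (anyDuplicated(genes)) stop("bulk signatures must be disjoint")
    gene_sig <- rep(names(sigs), vapply(sigs, function(s)
      length(s$genes), integer(1)))
    baseline <- rnorm(length(genes), 5, 1)
    shift <- cluster_effects[cl, gene_sig, drop = FALSE]
    expr <- sweep(shift, 2, baseline, "+") +
      matrix(rnorm(n_samples * length(genes), 0, noise_sd),
             n_samples, length(genes))
    dimnames(expr) <- list(sprintf("S%04d", seq_len(n_samples)), genes)
    haz <- base_hazard * hazard_ratios[cl]
    t_event <- rexp(n_samples, rate = haz)
    t_cens <- rexp(n_samples, rate = censor_rate)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    bulk_cohort(expr, time, event, cluster = cl)
  })
}

#' Generate a limiting-dilution assay under the single-hit model
#'
#' Each well seeded with `d` cells turns positive independently with
#' probability `1 - exp(-true_freq * d)`.
#'
#' @param true_freq true active-cell frequency, in (0, 1); values
#'   approaching 0 produce all-negative assays.
#' @param doses cell doses per well (default: the in vitro layout of 10,
#'   100 and 1000 cells).
#' @param wells_per_dose wells tested at each dose (default 48, 24, 16).
#' @param seed integer seed.
#' @return A [dilution_assay()].
#' @export
generate_dilution_assay <- function(true_freq,
                                    doses = c(10, 100, 1000),
                                    wells_per_dose = c(48L, 24L, 16L),
                                    seed = 1L) {
  if (true_freq < 0 || true_freq >= 1)
    stop("true_freq must lie in [0, 1)")
  if (length(doses) != length(wells_per_dose))
    stop("doses and wells_per_dose must have equal length")
  if (any(doses <= 0)) stop("doses must be positive")
  with_seed(seed, {
    p <- 1 - exp(-true_freq * doses)
    pos <- rbinom(length(doses), wells_per_dose, p)
    dilution_assay(doses, wells_per_dose, pos)
  })
}
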