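#' Evaluate planted-program recovery of a pipeline run
#'
#' Compares a [run_pipeline()] result against the ground truth of a
#' synthetic cohort from [generate_spheroid_cohort()]: matches every
#' planted program to the meta-signature with the highest Jaccard index
#' between the planted genes (restricted to genes that survived
#' filtering) and the meta-signature's equally long top-gene prefix;
#' re-assigns cell types from the four matched type meta-signatures only;
#' and tests the planted state-program directions between assigned types
#' with two-tailed Mann-Whitney tests.
#'
#' @param result a \code{pipeline_result}.
#' @param truth the `truth` element of [generate_spheroid_cohort()].
#' @param type_programs names of the planted cell-type programs.
#' @return List with `jaccard` (named, per planted program), `match`
#'   (program -> meta-signature index), `accuracy` (cell-type assignment
#'   accuracy over analyzed cells), `assignment`, and `state_tests` (the
#'   [compare_states_across_types()] table for the state programs).
#' @export
evaluate_program_recovery <- function(result, truth,
                                      type_programs = c("stem", "TA",
                                                        "Paneth",
                                                        "Tdiff")) {
  stopifnot(inherits(result, "pipeline_result"))
  kept <- rownames(result$expression$values)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  progs <- names(truth$programs)
  match_idx <- integer(length(progs)); names(match_idx) <- progs
  jaccard <- numeric(length(progs)); names(jaccard) <- progs
  for (pn in progs) {
    pg <- intersect(truth$programs[[pn]], kept)
    js <- vapply(result$meta_signatures, function(ms)
      jac(pg, head(ms$genes, length(pg))), numeric(1))
    match_idx[pn] <- which.max(js)
    jaccard[pn] <- max(js)
  }
  type_programs <- intersect(type_programs, progs)
  type_scores <- result$meta_scores[, match_idx[type_programs],
                                    drop = FALSE]
  colnames(type_scores) <- type_programs
  assignment <- assign_cell_types(type_scores)
  truth_type <- truth$cells$cell_type[match(rownames(type_scores),
                                            truth$cells$cell)]
  accuracy <- mean(assignment$assigned == truth_type)

  state_programs <- setdiff(progs, type_programs)
  state_tests <- NULL
  if (length(state_programs) > 0L) {
    ss <- result$meta_scores[, match_idx[state_programs], drop = FALSE]
    colnames(ss) <- state_programs
    state_tests <- compare_states_across_types(assignment, ss)
  }
  list(jaccard = jaccard, match = match_idx, accuracy = accuracy,
       assignment = assignment, state_tests = state_tests)
}
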