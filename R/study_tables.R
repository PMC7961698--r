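#' Per-culture sequencing summary of the 12 spheroid cultures
#'
#' The published per-culture quality-control summary of the twelve
#' patient-derived colorectal cancer spheroid cultures: mean sequenced
#' reads per cell, cell number after QC, mean detected genes per cell,
#' and the stem-marker score (total LGR5 transcript counts divided by
#' cell number). Shipped as a plain fixture so the table arithmetic
#' (cohort totals, culture gating) can be recomputed by package code.
#'
#' @return A data.frame with columns `patient`, `mean_reads`,
#'   `cells_post_qc`, `mean_genes`, `lgr5_score`.
#' @export
spheroid_qc_table <- function() {
  data.frame(
    patient = paste0("P", 1:12),
    mean_reads = c(348016, 261595, 460471, 1061813, 334099, 1276856,
                   359362, 190170, 527407, 391680, 505439, 454258),
    cells_post_qc = c(325L, 309L, 551L, 263L, 502L, 141L, 434L, 197L,
                      464L, 736L, 308L, 433L),
    mean_genes = c(3535L, 4072L, 4537L, 4186L, 3943L, 5116L, 4335L,
                   4174L, 4354L, 3418L, 4036L, 3977L),
    lgr5_score = c(12.85, 0.23, 6.43, 87.72, 4.61, 0.03, 10.18, 3.38,
                   0.00, 3.35, 1.43, 0.00),
    stringsAsFactors = FALSE)
}

#' Per-sample sequencing summary of organoids, xenografts and tumors
#'
#' Companion summary for the patient-derived organoids (O1-O3),
#' xenografts (X1, X2; human cells) and primary tumor samples (T1-T3).
#' For the tumors, `epithelial_cells` is the subset of post-QC cells
#' identified as epithelial and used for the merged-tumor analysis.
#'
#' @return A data.frame with columns `sample`, `mean_reads`,
#'   `cells_post_qc`, `epithelial_cells` (NA where not applicable).
#' @export
sample_qc_table <- function() {
  data.frame(
    sample = c("O1", "O2", "O3", "X1", "X2", "T1", "T2", "T3"),
    mean_reads = c(120218, 169086, 73415, 238836, 237891, 1333884,
                   847472, 623942),
    cells_post_qc = c(5550L, 3003L, 8785L, 1475L, 1070L, 362L, 538L,
                      724L),
    epithelial_cells = c(NA, NA, NA, NA, NA, 136L, 77L, 40L),
    stringsAsFactors = FALSE)
}

#' Patient and culture overview
#'
#' Clinical overview of the cultures: origin (primary tumor or
#' metastasis), site, stage, microsatellite status and driver-gene
#' mutation status (TRUE = mutated, FALSE = wild type, NA = not
#' available).
#'
#' @return A data.frame with one row per culture.
#' @export
patient_overview_table <- function() {
  data.frame(
    patient = paste0("P", 1:12),
    sex = c("m", "m", "f", "f", "f", "f", "m", "m", "m", "m", "m", "m"),
    origin = c("liver met", "lung met", "liver met", "liver met",
               "primary", "primary", "liver met", "liver met",
               "primary", "primary", "primary", "primary"),
    site = c("Rectum", "Caecum", "Rectum", "Ascending colon",
             "Transverse colon", "Caecum", "Sigmoid", "Caecum",
             "Rectum", "Sigmoid", "Rectum and caecum",
             "Rectum and transverse colon"),
    stage = c("IV", "IV", "IV", "IV", "IV", "IV", "IV", "IV", "IV",
              "IIIB", "IIIB", "II"),
    ms_status = c("MSS", "MSS", "MSS", "MSI", "MSS", "MSS", "MSS",
                  "MSS", "MSS", "MSS", "MSS", "MSI"),
    tp53 = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE,
             NA, FALSE, TRUE),
    apc = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE,
            NA, FALSE, TRUE),
    kras = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE,
             NA, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

#' Arithmetic summaries of the culture tables
#'
#' Recomputes, from the shipped fixtures, the cohort-level quantities the
#' study reports: total and mean post-QC cell counts across the twelve
#' spheroid cultures, the number of marker-positive and excluded cultures
#' under the strict gating rule, the pooled epithelial cell count of the
#' merged primary tumors, and the number of metastasis-derived cultures.
#'
#' @return A named list of numbers.
#' @export
study_table_summaries <- function() {
  qc <- spheroid_qc_table()
  sm <- sample_qc_table()
  ov <- patient_overview_table()
  pos <- lgr5_positive(qc$lgr5_score)
  list(total_cells_post_qc = sum(qc$cells_post_qc),
       mean_cells_post_qc = round(mean(qc$cells_post_qc)),
       lgr5_positive_cultures = sum(pos),
       lgr5_excluded_cultures = sum(!pos),
       tumor_epithelial_cells = sum(sm$epithelial_cells, na.rm = TRUE),
       metastasis_derived_cultures = sum(grepl("met", ov$origin)))
}
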