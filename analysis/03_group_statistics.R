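#!/usr/bin/env Rscript
# Stage 3 — result tables in the layout of the study's Tables 1-3.
#
# Re-derives the statistics tables from the stage-2 cohort table:
#   table1_mean_pli.tsv      group descriptives + Mann-Whitney + Cohen's d
#                            for global mean PLI, per band, BH-FDR over bands
#   table2_pli_correlation.tsv  Spearman rho between mean PLI and disability
#   table3_beta_mst.tsv      post-hoc beta-band group tests for the four MST
#                            metrics and the MST dissimilarity
#   mst_correlations.tsv     beta-band MST metrics vs disability, subject and
#                            single-epoch level

suppressPackageStartupMessages({
  library(eegmst)
  library(dplyr)
  library(readr)
})

ct_path <- "results/pipeline/cohort_table.tsv"
if (!file.exists(ct_path))
  stop("run analysis/02_network_pipeline.R first (missing ", ct_path, ")")
cohort <- read_tsv(ct_path, show_col_types = FALSE)
epochs <- read_tsv("results/pipeline/epoch_table.tsv", show_col_types = FALSE)
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

t1 <- group_comparison_table(cohort, "mean_pli")
write_tsv(t1, "results/tables/table1_mean_pli.tsv")

t2 <- correlation_table(cohort, "mean_pli")
write_tsv(t2, "results/tables/table2_pli_correlation.tsv")

t3 <- bind_rows(lapply(
  c("dissimilarity", "leaf_fraction", "diameter", "hierarchy", "kappa"),
  function(oc) group_comparison_table(cohort, oc))) |>
  filter(band == "beta")
write_tsv(t3, "results/tables/table3_beta_mst.tsv")

mst_cor <- bind_rows(lapply(
  c("leaf_fraction", "diameter", "hierarchy", "kappa"),
  function(oc) correlation_table(cohort, oc))) |>
  filter(band == "beta") |>
  mutate(level = "subject")
epo_cor <- epochs |>
  filter(band == "beta", group == "patient") |>
  (\(d) bind_rows(lapply(c("leaf_fraction", "diameter", "hierarchy", "kappa"),
    function(oc) {
      r <- epoch_level_correlation(d[[oc]], d$subject_id,
                                   setNames(d$disability, d$subject_id))
      tibble::tibble(outcome = oc, band = "beta", rho = r$rho,
                     p_value = r$p_value, n = r$n_points, computable = TRUE,
                     level = "single_epoch")
    })))()
write_tsv(bind_rows(mst_cor, epo_cor), "results/tables/mst_correlations.tsv")

cat("Mean PLI by band (patients vs controls):\n")
print(as.data.frame(t1[, c("band", "mean_patient", "mean_control", "p_value",
                           "fdr_significant", "cohens_d")]), digits = 3)
cat("\nBeta-band MST post-hoc tests:\n")
print(as.data.frame(t3[, c("outcome", "mean_patient", "mean_control", "u",
                           "p_value", "cohens_d")]), digits = 3)
cat("\nBeta-band MST metrics vs disability:\n")
print(as.data.frame(bind_rows(mst_cor, epo_cor)[, c("outcome", "level", "rho",
                                                    "p_value")]), digits = 3)
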