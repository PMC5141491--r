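#!/usr/bin/env Rscript
# Stage 4 — figures: beta-band MST parameters by group (strip plots) and
# against the disability score (subject-level and single-epoch scatter).

suppressPackageStartupMessages({
  library(dplyr)
  library(tidyr)
  library(ggplot2)
  library(readr)
})

cohort <- read_tsv("results/pipeline/cohort_table.tsv", show_col_types = FALSE)
epochs <- read_tsv("results/pipeline/epoch_table.tsv", show_col_types = FALSE)
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

metrics <- c("leaf_fraction", "diameter", "hierarchy", "kappa")
beta <- cohort |> filter(band == "beta") |>
  pivot_longer(all_of(metrics), names_to = "metric")

p1 <- ggplot(beta, aes(group, value, colour = group)) +
  geom_jitter(width = 0.12, alpha = 0.8) +
  stat_summary(fun = mean, geom = "crossbar", width = 0.35, linewidth = 0.3) +
  facet_wrap(~metric, scales = "free_y") +
  labs(title = "Beta-band MST parameters by group",
       x = NULL, y = NULL) +
  theme_minimal() + theme(legend.position = "none")
ggsave("results/figures/fig1_beta_mst_by_group.png", p1, width = 7, height = 5, dpi = 150)

pat <- beta |> filter(group == "patient")
p2 <- ggplot(pat, aes(disability, value)) +
  geom_point(alpha = 0.8) +
  geom_smooth(method = "lm", se = FALSE, linewidth = 0.4) +
  facet_wrap(~metric, scales = "free_y") +
  labs(title = "Beta-band MST parameters vs disability (patients)",
       x = "disability score (48 - ALSFRS-R)", y = NULL) +
  theme_minimal()
ggsave("results/figures/fig2_beta_mst_vs_disability.png", p2, width = 7, height = 5, dpi = 150)

epo <- epochs |> filter(band == "beta", group == "patient") |>
  pivot_longer(all_of(metrics), names_to = "metric")
p3 <- ggplot(epo, aes(disability, value)) +
  geom_point(alpha = 0.4, size = 0.8) +
  geom_smooth(method = "lm", se = FALSE, linewidth = 0.4) +
  facet_wrap(~metric, scales = "free_y") +
  labs(title = "Beta-band MST parameters vs disability, single epochs",
       x = "disability score (48 - ALSFRS-R)", y = NULL) +
  theme_minimal()
ggsave("results/figures/fig3_beta_mst_vs_disability_epochs.png", p3, width = 7, height = 5, dpi = 150)

cat("Figures written under results/figures/\n")
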