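#' Pipeline run configuration
#'
#' Collects every convention the pipeline uses — montage handling, epoching,
#' filter realization, Welch settings, MST conventions, statistics settings —
#' with defaults equal to the package's documented choices. The full
#' configuration is echoed into the run manifest so a run is reproducible
#' from its outputs.
#'
#' @param cohort a [cohort_spec()] (data are simulated) or a path to a cohort
#'   manifest (data are read from disk, see [read_cohort_manifest()]).
#' @param bands named list of [band_definition()]s (default the four
#'   canonical bands).
#' @param n_epochs,epoch_length epoching of each recording.
#' @param bad_channels labels dropped before connectivity.
#' @param reference_exclusions labels excluded from the common-average
#'   reference.
#' @param filter_order Butterworth design order ([bandpass_filter()]).
#' @param edge_discard samples dropped at each epoch edge after filtering.
#' @param welch_segment,welch_overlap Welch PSD settings ([welch_psd()]).
#' @param power_total_range denominator range for relative power.
#' @param diameter_normalized normalize tree diameter by `N - 1`?
#' @param aggregation subject-level MST aggregation
#'   ([subject_mst_summary()]).
#' @param q FDR level over the frequency bands.
#' @param exact_max_n exact-test threshold for [mann_whitney()].
#' @param out_dir optional output directory; when set, [run_pipeline()]
#'   writes all result tables and the run manifest there.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort,
                       bands = eeg_bands(),
                       n_epochs = 4L, epoch_length = 2048L,
                       bad_channels = character(),
                       reference_exclusions = character(),
                       filter_order = 4L, edge_discard = 0L,
                       welch_segment = 512L, welch_overlap = 0.5,
                       power_total_range = c(1, 30),
                       diameter_normalized = TRUE,
                       aggregation = c("metric_mean", "mean_matrix"),
                       q = 0.05, exact_max_n = 8L,
                       out_dir = NULL) {
  aggregation <- match.arg(aggregation)
  if (!(inherits(cohort, "cohort_spec") ||
        (is.character(cohort) && length(cohort) == 1L)))
    stop("`cohort` must be a cohort_spec or a manifest path")
  if (is.character(cohort) && !file.exists(cohort))
    stop("cohort manifest not found: ", cohort)
  structure(as.list(environment()), class = "run_config")
}

#' Per-subject connectivity processing
#'
#' Re-references to the common average, drops bad channels, cuts epochs,
#' then per band: zero-phase band-pass filtering, analytic-signal phases and
#' per-epoch PLI matrices. Relative band power is computed from the
#' broadband epochs.
#'
#' @param rec an [eeg_recording()].
#' @param config a [run_config()].
#' @return A list: `matrices` (band -> list of per-epoch PLI matrices),
#'   `mean_pli` (named per band), `rel_power` (named per band), `n_channels`.
#' @export
process_subject <- function(rec, config) {
  rec$bad_channels <- union(rec$bad_channels, config$bad_channels)
  rec$reference_exclusions <- union(rec$reference_exclusions,
                                    intersect(config$reference_exclusions, rec$labels))
  rec <- rereference_common_average(rec)
  rec <- drop_bad_channels(rec)
  broadband <- extract_epochs(rec, config$n_epochs, config$epoch_length)
  matrices <- lapply(config$bands, function(b) {
    filtered <- bandpass_filter(broadband, b, order = config$filter_order,
                                edge_discard = config$edge_discard)
    pli_matrix(filtered)
  })
  rel_power <- subject_band_power(broadband, config$bands,
                                  segment = config$welch_segment,
                                  overlap = config$welch_overlap,
                                  total_range = config$power_total_range)
  list(matrices = matrices,
       mean_pli = vapply(matrices, global_mean_pli, numeric(1)),
       rel_power = rel_power,
       n_channels = nrow(rec$data))
}

#' Run the full analysis pipeline
#'
#' simulate/read -> preprocess -> PLI connectivity -> MST topology and
#' dissimilarity against the control reference tree -> relative band power
#' -> group statistics and disability correlations. Deterministic for a
#' fixed configuration (the cohort seed lives in the [cohort_spec()]).
#'
#' @param config a [run_config()].
#' @return A list of class `pipeline_result`: `cohort_table` (wide tibble,
#'   one row per subject x band), `epoch_table` (per subject x band x
#'   epoch), `group_tests` (per outcome x band), `correlations`
#'   (patients-only Spearman per outcome x band), `epoch_correlations`,
#'   `reference_trees` (per band), `manifest` (all conventions in force).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- if (inherits(config$cohort, "cohort_spec")) {
    generate_cohort(config$cohort)
  } else {
    read_cohort_manifest(config$cohort,
                         bad_channels = config$bad_channels,
                         reference_exclusions = config$reference_exclusions)
  }
  subjects <- cohort$subjects
  processed <- lapply(subjects, function(s) process_subject(s$recording, config))
  band_names <- names(config$bands)
  is_control <- vapply(subjects, function(s) s$group == "control", logical(1))
  if (!any(is_control)) stop("cohort has no control subjects: reference tree undefined")
  if (all(is_control)) warning("cohort has no patients: group tests not computable")

  ref_trees <- lapply(band_names, function(b) {
    mats <- unlist(lapply(processed[is_control], function(p) p$matrices[[b]]),
                   recursive = FALSE)
    reference_tree(mats)
  })
  names(ref_trees) <- band_names

  n_sub <- length(subjects)
  n_band <- length(band_names)
  wide <- vector("list", n_sub * n_band)
  long <- vector("list", n_sub * n_band)
  k <- 0L
  for (i in seq_len(n_sub)) {
    s <- subjects[[i]]
    for (b in band_names) {
      k <- k + 1L
      ms <- subject_mst_summary(processed[[i]]$matrices[[b]], ref_trees[[b]],
                                aggregation = config$aggregation,
                                normalized = config$diameter_normalized)
      wide[[k]] <- c(list(subject_id = s$subject_id, group = s$group,
                          disability = s$disability, band = b,
                          mean_pli = processed[[i]]$mean_pli[[b]]),
                     ms$subject[c("leaf_fraction", "diameter", "kappa",
                                  "hierarchy", "dissimilarity")],
                     list(relative_power = processed[[i]]$rel_power[[b]]))
      ep <- ms$epoch
      long[[k]] <- data.frame(subject_id = s$subject_id, group = s$group,
                              disability = s$disability, band = b, ep)
    }
  }
  cohort_table <- tibble::as_tibble(do.call(rbind.data.frame, wide))
  epoch_table <- tibble::as_tibble(do.call(rbind, long))

  outcomes <- c("mean_pli", "leaf_fraction", "diameter", "kappa",
                "hierarchy", "dissimilarity", "relative_power")
  group_tests <- dplyr::bind_rows(lapply(outcomes, function(oc)
    group_comparison_table(cohort_table, oc, q = config$q,
                           exact_max_n = config$exact_max_n)))
  correlations <- dplyr::bind_rows(lapply(outcomes, function(oc)
    correlation_table(cohort_table, oc)))
  epoch_correlations <- dplyr::bind_rows(lapply(
    c("leaf_fraction", "diameter", "kappa", "hierarchy"), function(oc)
      epoch_correlation_table(epoch_table, oc)))

  manifest <- config_manifest(config, n_subjects = length(subjects),
                              n_channels = processed[[1]]$n_channels)
  result <- structure(
    list(cohort_table = cohort_table, epoch_table = epoch_table,
         group_tests = group_tests, correlations = correlations,
         epoch_correlations = epoch_correlations,
         reference_trees = ref_trees, manifest = manifest),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_results(result, config$out_dir)
  result
}

#' Per-band group comparison for one outcome
#'
#' Mann-Whitney patients vs controls in every band, Benjamini-Hochberg
#' flags across the bands, and pooled-SD Cohen's d.
#'
#' @param cohort_table wide table from [run_pipeline()].
#' @param outcome column name to test.
#' @param q FDR level.
#' @param exact_max_n passed to [mann_whitney()].
#' @return tibble: outcome, band, group means/SDs, `u`, `w_rank_sum`,
#'   `p_value`, `fdr_significant`, `cohens_d`.
#' @export
group_comparison_table <- function(cohort_table, outcome, q = 0.05,
                                   exact_max_n = 8L) {
  bands <- unique(cohort_table$band)
  rows <- lapply(bands, function(b) {
    sub <- cohort_table[cohort_table$band == b, ]
    a <- sub[[outcome]][sub$group == "patient"]
    ctl <- sub[[outcome]][sub$group == "control"]
    if (!length(a) || !length(ctl))
      return(tibble::tibble(outcome = outcome, band = b,
                            n_patient = length(a), n_control = length(ctl),
                            mean_patient = NA_real_, sd_patient = NA_real_,
                            mean_control = NA_real_, sd_control = NA_real_,
                            u = NA_real_, w_rank_sum = NA_real_,
                            p_value = NA_real_, cohens_d = NA_real_))
    mw <- mann_whitney(a, ctl, exact_max_n = exact_max_n)
    tibble::tibble(outcome = outcome, band = b,
                   n_patient = length(a), n_control = length(ctl),
                   mean_patient = mean(a), sd_patient = stats::sd(a),
                   mean_control = mean(ctl), sd_control = stats::sd(ctl),
                   u = mw$u, w_rank_sum = mw$w_rank_sum, p_value = mw$p_value,
                   cohens_d = tryCatch(cohens_d(a, ctl), error = function(e) NA_real_))
  })
  out <- dplyr::bind_rows(rows)
  out$fdr_significant <- if (all(is.na(out$p_value))) NA else fdr_bh(out$p_value, q)
  out
}

#' Patients-only disability correlation per band for one outcome
#'
#' Spearman rank correlation between the subject-level outcome and the
#' disability score, patients only (controls carry no ALSFRS-R). Bands where
#' the correlation is not computable (fewer than 3 patients, or constant
#' values) are reported with `computable = FALSE` rather than dropped.
#'
#' @inheritParams group_comparison_table
#' @return tibble: outcome, band, rho, p_value, n, computable.
#' @export
correlation_table <- function(cohort_table, outcome) {
  bands <- unique(cohort_table$band)
  rows <- lapply(bands, function(b) {
    sub <- cohort_table[cohort_table$band == b & cohort_table$group == "patient", ]
    res <- tryCatch(spearman_rank(sub[[outcome]], sub$disability),
                    error = function(e) NULL)
    if (is.null(res))
      tibble::tibble(outcome = outcome, band = b, rho = NA_real_,
                     p_value = NA_real_, n = nrow(sub), computable = FALSE)
    else
      tibble::tibble(outcome = outcome, band = b, rho = res$rho,
                     p_value = res$p_value, n = res$n, computable = TRUE)
  })
  dplyr::bind_rows(rows)
}

epoch_correlation_table <- function(epoch_table, outcome) {
  bands <- unique(epoch_table$band)
  rows <- lapply(bands, function(b) {
    sub <- epoch_table[epoch_table$band == b & epoch_table$group == "patient", ]
    res <- tryCatch(
      epoch_level_correlation(sub[[outcome]], sub$subject_id,
                              stats::setNames(sub$disability, sub$subject_id)),
      error = function(e) NULL)
    if (is.null(res))
      tibble::tibble(outcome = outcome, band = b, rho = NA_real_,
                     p_value = NA_real_, n_points = nrow(sub),
                     n_subjects = length(unique(sub$subject_id)),
                     computable = FALSE)
    else
      tibble::tibble(outcome = outcome, band = b, rho = res$rho,
                     p_value = res$p_value, n_points = res$n_points,
                     n_subjects = res$n_subjects, computable = TRUE)
  })
  dplyr::bind_rows(rows)
}

config_manifest <- function(config, n_subjects, n_channels) {
  bands <- lapply(config$bands, function(b) list(low = b$low, high = b$high))
  list(
    package = "eegmst",
    cohort = if (inherits(config$cohort, "cohort_spec"))
      config$cohort[setdiff(names(config$cohort), "")] else config$cohort,
    n_subjects = n_subjects, n_channels_retained = n_channels,
    bands = bands,
    epoching = list(n_epochs = config$n_epochs,
                    epoch_length = config$epoch_length),
    preprocessing = list(reference = "common average",
                         reference_exclusions = config$reference_exclusions,
                         bad_channels = config$bad_channels,
                         filter = "butterworth",
                         filter_order = config$filter_order,
                         zero_phase = TRUE,
                         edge_discard = config$edge_discard),
    welch = list(segment = config$welch_segment,
                 overlap = config$welch_overlap, taper = "hamming",
                 power_total_range = config$power_total_range),
    mst = list(weight = "1 - PLI", algorithm = "kruskal",
               tie_rule = "weight, then smaller, then larger node index",
               diameter_normalized = config$diameter_normalized,
               aggregation = config$aggregation),
    statistics = list(test = "mann-whitney two-sided", fdr = "benjamini-hochberg",
                      q = config$q, exact_max_n = config$exact_max_n,
                      correlations = "spearman, patients only")
  )
}

#' Write pipeline results to disk
#'
#' Tab-separated tables (`cohort_table.tsv`, `epoch_table.tsv`,
#' `group_tests.tsv`, `correlations.tsv`, `epoch_correlations.tsv`,
#' per-band reference-tree edge lists) and the JSON run manifest.
#'
#' @param result a `pipeline_result`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  wt(result$cohort_table, "cohort_table.tsv")
  wt(result$epoch_table, "epoch_table.tsv")
  wt(result$group_tests, "group_tests.tsv")
  wt(result$correlations, "correlations.tsv")
  wt(result$epoch_correlations, "epoch_correlations.tsv")
  for (b in names(result$reference_trees)) {
    tr <- result$reference_trees[[b]]
    lab <- if (is.null(tr$labels)) as.character(seq_len(tr$n_nodes)) else tr$labels
    wt(data.frame(ch_i = lab[tr$edges[, 1]], ch_j = lab[tr$edges[, 2]]),
       sprintf("reference_tree_%s.tsv", b))
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
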