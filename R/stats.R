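#' Disability score from the ALSFRS-R scale
#'
#' The revised ALS Functional Rating Scale runs 0-48 with higher scores
#' meaning better function; the disability score inverts it,
#' `48 - ALSFRS-R`, so 0 is healthy and 48 maximal disability.
#'
#' @param alsfrs_r integer(ish) values in `[0, 48]`.
#' @return `48 - alsfrs_r`.
#' @export
disability_score <- function(alsfrs_r) {
  if (any(alsfrs_r < 0 | alsfrs_r > 48)) stop("ALSFRS-R must lie in [0, 48]")
  48 - alsfrs_r
}

#' Mann-Whitney (Wilcoxon rank-sum) group comparison
#'
#' Two-sided test. Exact enumeration when the smaller group has at most
#' `exact_max_n` observations and there are no ties; otherwise the normal
#' approximation with continuity and tie correction. Both the U statistic
#' and the first group's rank sum W are reported, since statistics software
#' differs in which it prints.
#'
#' @param a,b numeric samples (first group, second group).
#' @param exact_max_n largest min-group size for the exact path.
#' @return A list: `u` (Mann-Whitney U of group `a`), `w_rank_sum`
#'   (rank sum of group `a`), `p_value`, `n` (c(n_a, n_b)), `exact`.
#' @export
mann_whitney <- function(a, b, exact_max_n = 8L) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- min(length(a), length(b)) <= exact_max_n && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  u <- unname(wt$statistic)                    # R's W is the U of group a
  list(u = u, w_rank_sum = u + length(a) * (length(a) + 1) / 2,
       p_value = wt$p.value, n = c(length(a), length(b)), exact = exact)
}

#' Benjamini-Hochberg FDR flags
#'
#' Step-up procedure at level `q`: with ordered p-values `p(1) <= ... <=
#' p(m)`, find the largest `k` with `p(k) <= k q / m` and flag the `k`
#' smallest. Implemented through `stats::p.adjust(method = "BH")`, whose
#' adjusted values are `<= q` exactly for the step-up-flagged tests.
#'
#' @param p_values numeric vector of p-values.
#' @param q FDR level (default 0.05).
#' @return Logical vector of significance flags, same order as `p_values`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Spearman rank correlation with two-sided p-value
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return A list: `rho`, `p_value`, `n`.
#' @export
spearman_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0)
    stop("degenerate input: zero rank variance")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", alternative = "two.sided")
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean(a) - mean(b)) / s_p` with the usual `n - 1` pooled variance.
#' Antisymmetric in its arguments.
#'
#' @param a,b numeric samples of size >= 2 each.
#' @return scalar effect size.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("both samples need at least 2 observations")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) stop("degenerate input: zero pooled variance")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Epoch-level brain-behaviour correlation
#'
#' Spearman correlation over all (epoch value, subject disability) pairs,
#' each epoch contributing one point. Epochs of one subject share its
#' disability score and are not independent, so while the rank correlation
#' itself is well defined, the p-value is computed at the inflated n; the
#' result carries an explicit caveat flag.
#'
#' @param epoch_values numeric vector, one value per epoch.
#' @param subject_of integer/character subject index per epoch.
#' @param disability named or positionally matching per-subject disability.
#' @return A list: `rho`, `p_value`, `n_points`, `n_subjects`,
#'   `nonindependent_epochs = TRUE`.
#' @export
epoch_level_correlation <- function(epoch_values, subject_of, disability) {
  subj <- as.character(subject_of)
  dis <- if (!is.null(names(disability))) disability[subj]
         else disability[as.integer(factor(subj, levels = unique(subj)))]
  res <- spearman_rank(epoch_values, as.numeric(dis))
  list(rho = res$rho, p_value = res$p_value,
       n_points = length(epoch_values), n_subjects = length(unique(subj)),
       nonindependent_epochs = TRUE)
}
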