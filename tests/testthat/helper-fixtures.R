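# Shared fixtures and independent oracles, all built in code.

# epoch_set wrapping a single channels x samples matrix
one_epoch <- function(mat, fs = 256, band = NULL) {
  epoch_set(list(mat), fs = fs,
            labels = sprintf("c%02d", seq_len(nrow(mat))), band = band)
}

# sinusoid recording: one row per (freq, phase) pair
sine_recording <- function(freqs, phases = rep(0, length(freqs)),
                           fs = 256, n = 2048, amp = 1) {
  t <- (seq_len(n) - 1) / fs
  data <- t(mapply(function(f, p) amp * cos(2 * pi * f * t + p), freqs, phases))
  eeg_recording(data, fs = fs)
}

# random symmetric PLI-like matrix with zero diagonal
random_pli_matrix <- function(n, labels = NULL) {
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- stats::runif(n * (n - 1) / 2)
  w <- w + t(w)
  if (!is.null(labels)) dimnames(w) <- list(labels, labels)
  w
}

# exhaustive-minimum spanning tree weight via Pruefer enumeration (oracle)
exhaustive_mst_weight <- function(similarity) {
  n <- nrow(similarity)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  min(apply(grid, 1L, function(s) {
    e <- prufer_tree(s)$edges
    sum(1 - similarity[e])
  }))
}

# exact two-sided Mann-Whitney p by enumerating all group assignments (oracle)
brute_force_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  u_of <- function(x, y) sum(rank(c(x, y))[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  u_obs <- u_of(a, b)
  mu <- n1 * length(b) / 2
  us <- apply(idx, 2L, function(i) u_of(pooled[i], pooled[-i]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

edge_key <- function(edges) paste(pmin(edges[, 1], edges[, 2]),
                                  pmax(edges[, 1], edges[, 2]))

# reduced-size cohort specification used by simulation-heavy tests
small_cohort_spec <- function(seed, ...) {
  cohort_spec(n_patients = 21L, n_controls = 16L, n_channels = 12L, fs = 128,
              n_epochs = 4L, epoch_length = 256L, seed = seed, ...)
}

small_run_config <- function(sp, ...) {
  run_config(sp, n_epochs = sp$n_epochs, epoch_length = sp$epoch_length,
             welch_segment = min(256L, sp$epoch_length), ...)
}
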