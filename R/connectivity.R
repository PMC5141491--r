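#' Analytic signal via the frequency-domain Hilbert construction
#'
#' Zeroes negative frequencies and doubles positive ones so that the real
#' part reproduces the input and the imaginary part is its Hilbert transform.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stop("analytic signal needs at least 2 samples")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase of every channel in an epoch set
#'
#' Phase of the analytic signal, per channel and epoch, wrapped to
#' \eqn{(-\pi, \pi]}. Channels with zero variance have no defined phase; they
#' are set to 0 with a warning so that their PLI against anything is 0.
#'
#' @param epochs a band-limited [epoch_set()].
#' @return A list with one channels x samples phase matrix per epoch, plus
#'   attributes `labels`, `band`, `fs`.
#' @export
instantaneous_phase <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  phases <- lapply(epochs$epochs, function(ep) {
    flat <- apply(ep, 1L, stats::var) == 0
    if (any(flat))
      warning("flat (zero-variance) channel(s): ",
              paste(epochs$labels[flat], collapse = ", "),
              "; phase set to 0")
    ph <- analytic_phase_matrix(ep)
    ph[flat, ] <- 0
    ph
  })
  structure(phases, labels = epochs$labels, band = epochs$band, fs = epochs$fs)
}

# Analytic-signal phase of every row of a channels x samples matrix in one
# batched FFT (stats::mvfft over columns of the transpose).
analytic_phase_matrix <- function(ep) {
  n <- ncol(ep)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  X <- stats::mvfft(t(ep)) * h
  t(Arg(stats::mvfft(X, inverse = TRUE)))
}

#' Phase lag index of a channel pair
#'
#' \eqn{PLI = | \langle sign(sin(\Delta\phi)) \rangle |} over samples, where
#' \eqn{\Delta\phi} is the instantaneous phase difference. Phase differences
#' of exactly 0 or \eqn{\pi} have `sign(sin) = 0` and contribute nothing, so
#' the index discards zero-lag (volume-conduction) coupling; values lie in
#' `[0, 1]`.
#'
#' @param phase_x,phase_y phase vectors in radians, equal length >= 2.
#' @return PLI in `[0, 1]`.
#' @export
pli_pair <- function(phase_x, phase_y) {
  if (length(phase_x) != length(phase_y))
    stop("phase vectors must have equal length")
  if (length(phase_x) < 2L) stop("need at least 2 samples")
  abs(mean(sign(sin(phase_x - phase_y))))
}

#' Per-epoch PLI adjacency matrices
#'
#' All unordered channel pairs of every epoch; each matrix is symmetric with
#' zero diagonal and entries in `[0, 1]`.
#'
#' @param epochs a band-limited [epoch_set()], or the output of
#'   [instantaneous_phase()].
#' @return List of n x n PLI matrices, one per epoch, with channel labels as
#'   dimnames and attributes `band` and `labels`.
#' @export
pli_matrix <- function(epochs) {
  phases <- if (inherits(epochs, "epoch_set")) instantaneous_phase(epochs) else epochs
  labels <- attr(phases, "labels")
  mats <- lapply(phases, function(ph) {
    n <- nrow(ph)
    if (n < 2L) stop("PLI needs at least 2 channels")
    ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
    v <- pli_pairs_cpp(ph)   # upper-triangle, column-major pair order
    w <- matrix(0, n, n, dimnames = list(labels, labels))
    w[ut] <- v
    w[ut[, c(2L, 1L)]] <- v
    w
  })
  structure(mats, band = attr(phases, "band"), labels = labels)
}

#' Long-format edge table of per-epoch PLI matrices
#'
#' One row per epoch and unordered channel pair — the interchange format for
#' downstream tools: `subject_id`, `epoch`, `band`, `ch_i`, `ch_j`, `pli`.
#'
#' @param matrices list of per-epoch PLI matrices as returned by
#'   [pli_matrix()].
#' @param subject_id subject identifier stamped on every row.
#' @param band band name; taken from the matrices' band attribute when `NULL`.
#' @return A tibble in long format.
#' @export
pli_edge_table <- function(matrices, subject_id = NA_character_, band = NULL) {
  if (!length(matrices)) stop("need at least one connectivity matrix")
  if (is.null(band)) {
    b <- attr(matrices, "band")
    band <- if (is.null(b)) NA_character_ else b$name
  }
  n <- nrow(matrices[[1]])
  labels <- rownames(matrices[[1]])
  if (is.null(labels)) labels <- as.character(seq_len(n))
  ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
  dplyr::bind_rows(lapply(seq_along(matrices), function(k)
    tibble::tibble(subject_id = subject_id, epoch = k, band = band,
                   ch_i = labels[ut[, 1L]], ch_j = labels[ut[, 2L]],
                   pli = matrices[[k]][ut])))
}

#' Global mean PLI across epochs and channel pairs
#'
#' Mean of the strictly-upper-triangle entries within each epoch, then the
#' mean across epochs.
#'
#' @param matrices list of square symmetric PLI matrices of equal dimension.
#' @return scalar mean PLI.
#' @export
global_mean_pli <- function(matrices) {
  if (!length(matrices)) stop("need at least one connectivity matrix")
  dims <- vapply(matrices, nrow, integer(1))
  if (any(dims != dims[1])) stop("matrices must share dimensions")
  mean(vapply(matrices, function(m) mean(m[upper.tri(m)]), numeric(1)))
}
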