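#' Canonical EEG frequency bands
#'
#' Band edges are half-open `[low, high)` so that the shared 4, 8 and 13 Hz
#' boundaries belong to exactly one band.
#'
#' @param name band name.
#' @param low,high band edges in Hz, `0 < low < high`.
#' @return `band_definition()` returns a `band_definition` object; `eeg_bands()`
#'   the named list of the four canonical bands: delta `[1,4)`, theta `[4,8)`,
#'   alpha `[8,13)`, beta `[13,30)`.
#' @export
band_definition <- function(name, low, high) {
  if (!(is.numeric(low) && is.numeric(high) && low > 0 && high > low))
    stop("band edges must satisfy 0 < low < high")
  structure(list(name = as.character(name), low = low, high = high),
            class = "band_definition")
}

#' @rdname band_definition
#' @export
eeg_bands <- function() {
  list(delta = band_definition("delta", 1, 4),
       theta = band_definition("theta", 4, 8),
       alpha = band_definition("alpha", 8, 13),
       beta  = band_definition("beta", 13, 30))
}

#' Set of equal-length epochs cut from a recording
#'
#' @param epochs list of channels x samples matrices, all the same dimension.
#' @param fs sampling rate in Hz.
#' @param labels channel labels.
#' @param band a [band_definition()] or `NULL` for broadband.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, fs, labels, band = NULL) {
  stopifnot(is.list(epochs), length(epochs) >= 1L)
  dims <- vapply(epochs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all epochs must share the same channels x samples dimension")
  structure(list(epochs = epochs, fs = fs, labels = labels, band = band),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  bd <- if (is.null(x$band)) "broadband" else
    sprintf("%s [%g,%g) Hz", x$band$name, x$band$low, x$band$high)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz, %s\n",
              length(x$epochs), nrow(x$epochs[[1]]), ncol(x$epochs[[1]]),
              x$fs, bd))
  invisible(x)
}

#' Common-average re-referencing
#'
#' Subtracts, at every sample, the mean over the channels *not* listed in
#' `reference_exclusions` from **every** channel (including the excluded
#' ones). After the operation the mean over included channels is zero at each
#' sample. Idempotent.
#'
#' @param rec an [eeg_recording()].
#' @return The re-referenced [eeg_recording()].
#' @export
rereference_common_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  keep <- !(rec$labels %in% rec$reference_exclusions)
  if (sum(keep) < 2L)
    stop("common-average reference needs at least 2 non-excluded channels")
  ref <- colMeans(rec$data[keep, , drop = FALSE])
  rec$data <- sweep(rec$data, 2L, ref, "-")
  rec
}

#' Remove bad channels from a recording
#'
#' Channels listed in `bad_channels` are dropped from the data and label set.
#' Labels not present are ignored with a warning.
#'
#' @param rec an [eeg_recording()].
#' @return The reduced [eeg_recording()] (with `bad_channels` cleared).
#' @export
drop_bad_channels <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  bad <- rec$bad_channels
  if (!length(bad)) return(rec)
  missing <- setdiff(bad, rec$labels)
  if (length(missing))
    warning("bad channels not present in recording, ignored: ",
            paste(missing, collapse = ", "))
  keep <- !(rec$labels %in% bad)
  rec$data <- rec$data[keep, , drop = FALSE]
  rec$labels <- rec$labels[keep]
  rec$bad_channels <- character()
  rec$reference_exclusions <- intersect(rec$reference_exclusions, rec$labels)
  rec
}

#' Cut consecutive non-overlapping epochs from the start of a recording
#'
#' @param rec an [eeg_recording()].
#' @param n_epochs number of epochs.
#' @param epoch_length epoch length in samples.
#' @return An [epoch_set()] (broadband).
#' @export
extract_epochs <- function(rec, n_epochs = 4L, epoch_length = 2048L) {
  stopifnot(inherits(rec, "eeg_recording"))
  need <- n_epochs * epoch_length
  have <- ncol(rec$data)
  if (have < need)
    stop(sprintf("recording too short: %d samples required (%d epochs x %d), %d available",
                 need, n_epochs, epoch_length, have))
  eps <- lapply(seq_len(n_epochs), function(k) {
    idx <- ((k - 1L) * epoch_length + 1L):(k * epoch_length)
    rec$data[, idx, drop = FALSE]
  })
  epoch_set(eps, fs = rec$fs, labels = rec$labels, band = NULL)
}

# Cache of Butterworth designs keyed by (order, low, high, fs).
.filter_cache <- new.env(parent = emptyenv())

butter_bandpass <- function(low, high, fs, order = 4L) {
  key <- sprintf("%d|%.8g|%.8g|%.8g", order, low, high, fs)
  flt <- .filter_cache[[key]]
  if (is.null(flt)) {
    flt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
    .filter_cache[[key]] <- flt
  }
  flt
}

#' Zero-phase band-pass filtering of an epoch set
#'
#' A Butterworth band-pass (default order 4) is applied forward and backward
#' (`signal::filtfilt`), giving zero phase distortion — essential before
#' phase-based connectivity — at an effective magnitude order of twice the
#' design order. Epochs are filtered independently.
#'
#' @param epochs an [epoch_set()].
#' @param band a [band_definition()].
#' @param order Butterworth design order.
#' @param edge_discard samples to drop at each epoch edge after filtering
#'   (mitigates filter transients; default 0).
#' @return A band-limited [epoch_set()].
#' @export
bandpass_filter <- function(epochs, band, order = 4L, edge_discard = 0L) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(band, "band_definition"))
  if (band$high >= epochs$fs / 2)
    stop(sprintf("band upper edge %g Hz is at or above Nyquist (%g Hz)",
                 band$high, epochs$fs / 2))
  flt <- butter_bandpass(band$low, band$high, epochs$fs, order)
  ns <- ncol(epochs$epochs[[1]])
  keep <- if (edge_discard > 0L) (edge_discard + 1L):(ns - edge_discard) else seq_len(ns)
  # epochs are filtered independently but in one batched call: the filter
  # runs column-wise, so epochs are stacked side by side as extra columns
  nc <- nrow(epochs$epochs[[1]])
  wide <- do.call(cbind, lapply(epochs$epochs, t))
  out <- filtfilt_ba(flt$b, flt$a, wide)
  filtered <- lapply(seq_along(epochs$epochs), function(k) {
    ep <- t(out[, ((k - 1L) * nc + 1L):(k * nc), drop = FALSE])
    dimnames(ep) <- dimnames(epochs$epochs[[k]])
    ep[, keep, drop = FALSE]
  })
  epoch_set(filtered, fs = epochs$fs, labels = epochs$labels, band = band)
}

# Single-pass direct-form IIR filter down every column of a samples x
# channels matrix (compiled kernel).
iir_filter <- function(b, a, x) {
  iir_filter_cpp(as.numeric(b), as.numeric(a), x)
}

# Zero-phase (forward-backward) filtering, columns of a samples x channels
# matrix, with odd reflection padding at both ends to suppress transients.
filtfilt_ba <- function(b, a, x) {
  if (is.null(dim(x))) return(drop(filtfilt_ba(b, a, matrix(x, ncol = 1L))))
  n <- nrow(x)
  npad <- min(n - 1L, 12L * (max(length(a), length(b)) - 1L))
  first <- x[rep(1L, npad), , drop = FALSE]
  last <- x[rep(n, npad), , drop = FALSE]
  xp <- rbind(2 * first - x[(npad + 1L):2L, , drop = FALSE],
              x,
              2 * last - x[(n - 1L):(n - npad), , drop = FALSE])
  y <- iir_filter(b, a, xp)
  y <- iir_filter(b, a, y[nrow(y):1L, , drop = FALSE])
  # y is still time-reversed: undo the reversal and strip the padding
  y[(nrow(y) - npad):(npad + 1L), , drop = FALSE]
}
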