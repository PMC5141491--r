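#' Welch power spectral density of one epoch
#'
#' Averaged modified periodogram: the signal is split into overlapping
#' Hamming-tapered segments, each segment's periodogram is scaled to a
#' one-sided density (power per Hz), and the segments are averaged. With the
#' defaults a 2048-sample epoch at 256 Hz yields 7 half-overlapping 2-s
#' segments and 0.5 Hz resolution.
#'
#' @param x numeric matrix (channels x samples) or vector.
#' @param fs sampling rate in Hz.
#' @param segment segment length in samples (<= epoch length).
#' @param overlap fractional segment overlap in `[0, 1)`.
#' @return A list of class `power_spectrum`: `frequencies` (Hz, 0..fs/2),
#'   `density` (channels x frequencies, power/Hz), `welch_params`.
#' @export
welch_psd <- function(x, fs, segment = 512L, overlap = 0.5) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  ns <- ncol(x)
  segment <- as.integer(segment)
  if (segment > ns)
    stop(sprintf("Welch segment (%d) longer than epoch (%d samples)", segment, ns))
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  step <- max(1L, as.integer(round(segment * (1 - overlap))))
  starts <- seq(1L, ns - segment + 1L, by = step)
  w <- signal::hamming(segment)
  scale <- fs * sum(w^2)
  nf <- segment %/% 2L + 1L
  freqs <- (0:(nf - 1L)) * fs / segment
  dens <- matrix(0, nrow(x), nf)
  for (s in starts) {
    seg <- x[, s:(s + segment - 1L), drop = FALSE]
    seg <- sweep(seg, 1L, rowMeans(seg), "-")       # detrend (mean removal)
    seg <- sweep(seg, 2L, w, "*")
    spec <- abs(stats::mvfft(t(seg)))^2 / scale     # two-sided density
    p <- t(spec[seq_len(nf), , drop = FALSE])
    # fold negative frequencies into the one-sided density
    interior <- 2:(nf - 1L + segment %% 2L)
    p[, interior] <- 2 * p[, interior]
    dens <- dens + p
  }
  dens <- dens / length(starts)
  rownames(dens) <- rownames(x)
  structure(list(frequencies = freqs, density = dens,
                 welch_params = list(segment = segment, overlap = overlap,
                                     taper = "hamming", fs = fs)),
            class = "power_spectrum")
}

#' Relative power in a frequency band
#'
#' Power integrated over `[band.low, band.high)` divided by the power over
#' the denominator range — by default `[1, 30)` Hz, the union of the four
#' canonical bands, so the four canonical relative powers sum to 1.
#' Invariant to global amplitude rescaling of the signal.
#'
#' @param psd a `power_spectrum` from [welch_psd()].
#' @param band a [band_definition()].
#' @param total_range length-2 numeric, denominator frequency range in Hz.
#' @return Scalar relative power (averaged over channels if multichannel).
#' @export
relative_band_power <- function(psd, band, total_range = c(1, 30)) {
  stopifnot(inherits(psd, "power_spectrum"), inherits(band, "band_definition"))
  f <- psd$frequencies
  if (band$high > max(f))
    stop("band exceeds the analysed frequency range")
  in_band <- f >= band$low & f < band$high
  in_total <- f >= total_range[1] & f < total_range[2]
  num <- sum(psd$density[, in_band, drop = FALSE])
  den <- sum(psd$density[, in_total, drop = FALSE])
  if (den <= 0) stop("degenerate input: zero total power in the analysis range")
  num / den
}

#' Per-subject relative band powers
#'
#' Relative power of each canonical band, computed per epoch on the
#' broadband epochs and averaged over epochs.
#'
#' @param epochs a broadband [epoch_set()].
#' @param bands list of [band_definition()]s.
#' @param segment,overlap Welch settings ([welch_psd()]); the segment is
#'   shortened to the epoch length if needed.
#' @param total_range denominator range ([relative_band_power()]).
#' @return Named numeric vector of relative powers, one per band.
#' @export
subject_band_power <- function(epochs, bands = eeg_bands(),
                               segment = 512L, overlap = 0.5,
                               total_range = c(1, 30)) {
  stopifnot(inherits(epochs, "epoch_set"))
  segment <- min(segment, ncol(epochs$epochs[[1]]))
  per_epoch <- vapply(epochs$epochs, function(ep) {
    psd <- welch_psd(ep, epochs$fs, segment = segment, overlap = overlap)
    vapply(bands, function(b) relative_band_power(psd, b, total_range), numeric(1))
  }, numeric(length(bands)))
  rowMeans(matrix(per_epoch, nrow = length(bands),
                  dimnames = list(names(bands), NULL)))
}
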