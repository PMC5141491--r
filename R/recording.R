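#' Multichannel EEG recording
#'
#' Lightweight container for a labelled multichannel time series in physical
#' units (microvolts by convention). `bad_channels` and `reference_exclusions`
#' are channel-label subsets consumed by [drop_bad_channels()] and
#' [rereference_common_average()] respectively.
#'
#' @param data numeric matrix, channels x samples.
#' @param labels character vector of unique channel names, one per row of `data`.
#' @param fs sampling rate in Hz (> 0).
#' @param bad_channels labels of channels to exclude from analysis.
#' @param reference_exclusions labels excluded from the common-average reference.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, labels = NULL, fs,
                          bad_channels = character(),
                          reference_exclusions = character()) {
  data <- as.matrix(data)
  if (is.null(labels)) labels <- default_labels(nrow(data))
  if (length(labels) != nrow(data))
    stop("`labels` must have one entry per channel (row of `data`)")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("`fs` must be a positive scalar")
  unknown <- setdiff(c(bad_channels, reference_exclusions), labels)
  if (length(unknown) && length(setdiff(reference_exclusions, labels)))
    stop("reference_exclusions not in labels: ", paste(unknown, collapse = ", "))
  rownames(data) <- labels
  structure(
    list(data = data, labels = labels, fs = fs,
         bad_channels = as.character(bad_channels),
         reference_exclusions = as.character(reference_exclusions)),
    class = "eeg_recording"
  )
}

default_labels <- function(n) sprintf("E%02d", seq_len(n))

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (length(x$bad_channels))
    cat("  bad channels:", paste(x$bad_channels, collapse = ", "), "\n")
  if (length(x$reference_exclusions))
    cat("  reference exclusions:", paste(x$reference_exclusions, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a recording as delimited text
#'
#' One column per channel with a header row of channel labels; the sampling
#' rate is stored in a `# fs=<Hz>` comment on the first line so a file is
#' self-describing.
#'
#' @param rec an [eeg_recording()].
#' @param path file path.
#' @return `write_recording_txt()` returns `path` invisibly;
#'   `read_recording_txt()` returns an [eeg_recording()].
#' @export
write_recording_txt <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", rec$fs), con)
  utils::write.table(t(rec$data), con, sep = "\t", row.names = FALSE,
                     col.names = rec$labels, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording_txt
#' @param bad_channels,reference_exclusions passed to [eeg_recording()]
#'   (not stored in the file).
#' @export
read_recording_txt <- function(path, bad_channels = character(),
                               reference_exclusions = character()) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!grepl("^# fs=", first))
    stop("malformed recording file (missing '# fs=' header line): ", path)
  fs <- as.numeric(sub("^# fs=", "", first))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                           check.names = FALSE)
  eeg_recording(t(as.matrix(tab)), labels = colnames(tab), fs = fs,
                bad_channels = bad_channels,
                reference_exclusions = reference_exclusions)
}
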