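## Recording and EpochedData containers plus delimited-matrix I/O.

#' Continuous multichannel recording
#'
#' @param data Channels x samples numeric matrix (microvolts).
#' @param fs Sampling rate in Hz.
#' @param channel_labels Optional character vector, one per channel.
#' @return An object of class `recording`.
#' @export
recording <- function(data, fs, channel_labels = NULL) {
  data <- as.matrix(data)
  if (fs <= 0) stop_tinnpac("fs must be positive")
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("CH%03d", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop_tinnpac("channel_labels length must match channel count")
  }
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 history = character(0)),
            class = "recording")
}

append_history <- function(rec, msg) {
  rec$history <- c(rec$history, msg)
  rec
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (length(x$history)) cat("history:", paste(x$history, collapse = " -> "), "\n")
  invisible(x)
}

#' Epoched multichannel data
#'
#' Stored as a 3-d array `epochs x channels x samples`. `kept_mask` records,
#' for every epoch of the original segmentation, whether it survived
#' rejection.
#'
#' @param data Epochs x channels x samples array.
#' @param fs Sampling rate in Hz.
#' @param epoch_len_s Epoch length in seconds; `samples == fs * epoch_len_s`.
#' @param kept_mask Logical vector over the original epochs.
#' @param channel_labels Optional channel labels.
#' @return An object of class `epoched_data`.
#' @export
epoched_data <- function(data, fs, epoch_len_s, kept_mask = NULL,
                         channel_labels = NULL) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[3] != round(fs * epoch_len_s)) {
    stop_tinnpac("samples per epoch must equal fs * epoch_len_s")
  }
  if (is.null(kept_mask)) kept_mask <- rep(TRUE, dim(data)[1])
  structure(list(data = data, fs = fs, epoch_len_s = epoch_len_s,
                 kept_mask = kept_mask,
                 channel_labels = channel_labels %||%
                   sprintf("CH%03d", seq_len(dim(data)[2]))),
            class = "epoched_data")
}

#' @export
print.epoched_data <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_data> %d epochs x %d channels x %d samples @ %g Hz (%g s epochs, %d/%d kept)\n",
              d[1], d[2], d[3], x$fs, x$epoch_len_s, sum(x$kept_mask),
              length(x$kept_mask)))
  invisible(x)
}

#' Read a recording from disk
#'
#' Supported formats: `"edf"` (16-bit European Data Format) and
#' `"delimited"` (tab-separated matrix, channels as rows, first column the
#' channel label, with a header line `fs <Hz>`).
#'
#' @param path File path.
#' @param format `"edf"` or `"delimited"`; default guesses from the
#'   extension.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "delimited")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_tinnpac("file not found: ", path)
  if (file.size(path) == 0) stop_tinnpac("empty recording file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  }
  rec <- switch(format,
                edf = read_edf(path),
                delimited = read_delimited_recording(path))
  append_history(rec, sprintf("read %s (%s)", basename(path), format))
}

#' Write a recording to disk
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @param format `"edf"` or `"delimited"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "delimited")) {
  stopifnot(inherits(rec, "recording"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  }
  switch(format,
         edf = write_edf(rec, path),
         delimited = write_delimited_recording(rec, path))
  invisible(path)
}

read_delimited_recording <- function(path) {
  lines <- readLines(path)
  if (!grepl("^fs\t", lines[1])) {
    stop_tinnpac("delimited recording must start with a 'fs<TAB><Hz>' line: ", path)
  }
  fs <- as.numeric(strsplit(lines[1], "\t", fixed = TRUE)[[1]][2])
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  lens <- lengths(rows)
  if (length(unique(lens)) != 1) {
    stop_tinnpac("inconsistent row lengths in delimited recording: ", path)
  }
  labels <- vapply(rows, `[[`, character(1), 1L)
  data <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(lens[1] - 1L)))
  recording(data, fs = fs, channel_labels = labels)
}

write_delimited_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("fs\t%.10g", rec$fs), con)
  body <- apply(rec$data, 1, function(r) paste(sprintf("%.7g", r), collapse = "\t"))
  writeLines(paste(rec$channel_labels, body, sep = "\t"), con)
}
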