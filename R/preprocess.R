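## Preprocessing chain: band-pass + notch filtering, polyphase resampling,
## fixed-length epoching, and amplitude-based epoch rejection.

# Zero-phase FIR filtering: the windowed-sinc kernel is applied forward and
# backward by multiplying the spectrum with |H(f)|^2 (FFT convolution).
# Identical response to filtfilt with the same kernel, at FFT cost.
fir_apply_zerophase <- function(x, h) {
  n <- length(x)
  L <- length(h)
  nfft <- next_fast_len(n + 2L * L)
  H <- stats::fft(c(h, numeric(nfft - L)))
  X <- stats::fft(c(x, numeric(nfft - n)))
  y <- Re(stats::fft(X * (H * Conj(H)), inverse = TRUE)) / nfft
  y[seq_len(n)]
}

# eegfilt-style FIR order: 3 cycles of the lowest frequency of interest,
# capped so the kernel stays shorter than the signal.
fir_order <- function(fs, low_edge, n) {
  ord <- 3L * round(fs / low_edge)
  ord <- min(ord, n - 1L)
  if (ord < 8L) stop_tinnpac("signal too short for the requested band")
  if (ord %% 2L == 1L) ord <- ord - 1L   # even order -> symmetric kernel
  ord
}

#' Band-pass and notch filter a recording
#'
#' Zero-phase windowed-sinc FIR band-pass (default 0.5-150 Hz) followed by a
#' zero-phase second-order IIR notch (default 50 Hz mains). Zero-phase
#' application keeps instantaneous-phase estimates downstream undistorted.
#'
#' @param rec A [recording()].
#' @param low,high Band-pass edges in Hz.
#' @param notch Notch centre frequency in Hz (`NA` to skip).
#' @param notch_halfwidth Half-width of the notch stop band in Hz.
#' @return The filtered [recording()].
#' @export
bandpass_notch <- function(rec, low = 0.5, high = 150, notch = 50,
                           notch_halfwidth = 2) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$fs / 2
  if (high >= nyq) stop_tinnpac("high edge must be below Nyquist (", nyq, " Hz)")
  n <- ncol(rec$data)
  ord <- fir_order(rec$fs, low, n)
  h <- signal::fir1(ord, c(low, high) / nyq, type = "pass")
  for (i in seq_len(nrow(rec$data))) {
    rec$data[i, ] <- fir_apply_zerophase(rec$data[i, ], h)
  }
  if (!is.na(notch)) {
    bt <- signal::butter(2, c(notch - notch_halfwidth, notch + notch_halfwidth) / nyq,
                         type = "stop")
    for (i in seq_len(nrow(rec$data))) {
      rec$data[i, ] <- signal::filtfilt(bt, rec$data[i, ])
    }
  }
  append_history(rec, sprintf("bandpass %g-%g Hz%s", low, high,
                              if (is.na(notch)) "" else sprintf(" + notch %g Hz", notch)))
}

# Rational zero-phase resampling: zero-stuff by p, apply a zero-phase
# anti-alias FIR at the target Nyquist, keep every q-th sample. Zero-phase
# application avoids the group delay a causal polyphase filter would add.
resample_zerophase <- function(x, p, q) {
  if (p == q) return(x)
  if (p > 1) {
    up <- numeric(length(x) * p)
    up[seq(1, length(up), by = p)] <- x
    x <- up
  }
  w <- min(1, p / q)                     # cutoff relative to upsampled Nyquist
  ord <- 30L * max(p, q)
  h <- signal::fir1(ord, 0.9 * w, type = "low")
  y <- p * fir_apply_zerophase(x, h)
  y[seq(1, length(y), by = q)]
}

#' Resample and segment into fixed-length epochs
#'
#' Rational resampling to `fs_target` (zero-stuffing + zero-phase
#' anti-alias FIR + decimation) followed by segmentation into
#' non-overlapping epochs of `epoch_len_s`; a trailing partial epoch is
#' discarded. Upsampling is refused.
#'
#' @param rec A [recording()].
#' @param fs_target Target sampling rate in Hz (default 500).
#' @param epoch_len_s Epoch length in seconds (default 2).
#' @return An [epoched_data()].
#' @export
resample_epoch <- function(rec, fs_target = 500, epoch_len_s = 2) {
  stopifnot(inherits(rec, "recording"))
  if (fs_target > rec$fs) stop_tinnpac("upsampling refused (fs_target > fs)")
  if (fs_target == rec$fs) {
    data <- rec$data
  } else {
    g <- gcd_int(round(fs_target), round(rec$fs))
    p <- round(fs_target) / g
    q <- round(rec$fs) / g
    data <- t(apply(rec$data, 1, resample_zerophase, p = p, q = q))
  }
  spe <- round(fs_target * epoch_len_s)
  n_ep <- floor(ncol(data) / spe)
  if (n_ep == 0) {
    warning("recording shorter than one epoch; returning 0 epochs")
  }
  arr <- array(0, dim = c(n_ep, nrow(data), spe))
  for (e in seq_len(n_ep)) {
    arr[e, , ] <- data[, (e - 1) * spe + seq_len(spe), drop = FALSE]
  }
  epoched_data(arr, fs = fs_target, epoch_len_s = epoch_len_s,
               channel_labels = rec$channel_labels)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Reject epochs by peak-to-peak amplitude
#'
#' A deterministic stand-in for manual artifact screening: an epoch is kept
#' only if every channel's peak-to-peak amplitude lies within
#' `[flatline_threshold_uv, abs_threshold_uv]`. Large excursions flag
#' movement/muscle artifacts; near-zero excursions flag flat (disconnected)
#' channels.
#'
#' @param ep An [epoched_data()].
#' @param abs_threshold_uv Upper peak-to-peak bound in microvolts.
#' @param flatline_threshold_uv Lower peak-to-peak bound in microvolts.
#' @return An [epoched_data()] containing only kept epochs, with
#'   `kept_mask` over the input epochs.
#' @export
reject_epochs <- function(ep, abs_threshold_uv = 100, flatline_threshold_uv = 1e-6) {
  stopifnot(inherits(ep, "epoched_data"))
  if (abs_threshold_uv <= 0 || flatline_threshold_uv <= 0) {
    stop_tinnpac("thresholds must be positive")
  }
  d <- dim(ep$data)
  keep <- logical(d[1])
  for (e in seq_len(d[1])) {
    ptp <- apply(ep$data[e, , , drop = FALSE], 2, function(ch) diff(range(ch)))
    keep[e] <- all(ptp <= abs_threshold_uv) && all(ptp >= flatline_threshold_uv)
  }
  if (!any(keep)) {
    stop_tinnpac("all epochs rejected; reconsider the amplitude thresholds")
  }
  epoched_data(ep$data[keep, , , drop = FALSE], fs = ep$fs,
               epoch_len_s = ep$epoch_len_s, kept_mask = keep,
               channel_labels = ep$channel_labels)
}
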