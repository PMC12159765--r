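## Spectral power and power-power / amplitude-amplitude coupling.

#' Frequency band scheme
#'
#' Canonical analysis bands: theta 4-8 Hz, beta 13-30 Hz, gamma 30-70 Hz,
#' plus the broadband range used as the normalization denominator.
#'
#' @param theta,beta,gamma,broadband Numeric `c(lo, hi)` edges in Hz.
#' @return Named list of band edges, class `band_scheme`.
#' @export
band_scheme <- function(theta = c(4, 8), beta = c(13, 30), gamma = c(30, 70),
                        broadband = c(0.5, 150)) {
  bands <- list(theta = theta, beta = beta, gamma = gamma, broadband = broadband)
  for (b in bands) {
    if (b[1] <= 0 || b[2] <= b[1]) stop_tinnpac("band edges must be positive and increasing")
  }
  structure(bands, class = "band_scheme")
}

#' Power spectral density from epoched data
#'
#' Welch-style estimate: each epoch is Hann-windowed, Fourier transformed,
#' and the one-sided periodograms are averaged over epochs. The scaling
#' satisfies Parseval: integrating the PSD over frequency recovers the
#' signal variance. Frequency resolution is `1 / epoch_len`.
#'
#' @param ep Epochs x samples numeric matrix (one channel), or a vector
#'   (treated as one epoch).
#' @param fs Sampling rate (Hz).
#' @return A `spectrum_psd`: list with `freqs` (Hz), `power`
#'   (units^2 / Hz), `epoch_count`, `window`.
#' @export
psd <- function(ep, fs) {
  if (is.vector(ep)) ep <- matrix(ep, 1)
  if (!all(is.finite(ep))) stop_tinnpac("non-finite samples in input")
  n <- ncol(ep)
  w <- hann_window(n)
  norm <- fs * sum(w^2)
  n_keep <- floor(n / 2) + 1
  pow <- numeric(n_keep)
  for (e in seq_len(nrow(ep))) {
    X <- stats::fft(ep[e, ] * w)[seq_len(n_keep)]
    p <- (Mod(X)^2) / norm
    # one-sided: double everything except DC (and Nyquist when n is even)
    dbl <- rep(2, n_keep)
    dbl[1] <- 1
    if (n %% 2 == 0) dbl[n_keep] <- 1
    pow <- pow + p * dbl
  }
  structure(list(freqs = (seq_len(n_keep) - 1) * fs / n,
                 power = pow / nrow(ep),
                 epoch_count = nrow(ep), window = "hann"),
            class = "spectrum_psd")
}

#' Band-integrated power
#'
#' Integrates the PSD over each scheme band (trapezoid-free bin sum times
#' frequency step). With `normalize = TRUE` each band is expressed relative
#' to the broadband total, giving values in `[0, 1]`.
#'
#' @param spec A [psd()] result.
#' @param scheme A [band_scheme()].
#' @param normalize Normalize to broadband power?
#' @return Named numeric of per-band values (`theta`, `beta`, `gamma`).
#' @export
band_power <- function(spec, scheme = band_scheme(), normalize = TRUE) {
  df <- diff(spec$freqs[1:2])
  integrate_band <- function(b) {
    sel <- spec$freqs >= b[1] & spec$freqs <= b[2]
    if (!any(sel)) stop_tinnpac("band [", b[1], ", ", b[2], "] has no PSD grid points")
    sum(spec$power[sel]) * df
  }
  vals <- vapply(scheme[c("theta", "beta", "gamma")], integrate_band, numeric(1))
  if (normalize) vals <- vals / integrate_band(scheme$broadband)
  vals
}

#' Power-power coupling (Spearman correlation)
#'
#' Spearman rank correlation between two band-power series (e.g. theta and
#' gamma power across epochs or subjects). The p-value uses the exact
#' permutation null for n <= 10 and the t-approximation otherwise.
#'
#' @param band_a,band_b Paired numeric vectors (>= 4 observations).
#' @return List with `rho`, `p`, `n`.
#' @export
power_power_coupling <- function(band_a, band_b) {
  if (length(band_a) != length(band_b)) stop_tinnpac("length mismatch")
  n <- length(band_a)
  if (n < 4) stop_tinnpac("need at least 4 paired observations")
  if (stats::sd(band_a) == 0 || stats::sd(band_b) == 0) {
    stop_tinnpac("constant input: Spearman correlation undefined")
  }
  ct <- suppressWarnings(
    stats::cor.test(band_a, band_b, method = "spearman", exact = n <= 10))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Amplitude-amplitude coupling matrix
#'
#' Correlates spectral power across epochs between every pair of
#' frequencies: each 2-s epoch is Hann-windowed and Fourier transformed;
#' the squared moduli at two frequencies are correlated across epochs
#' (Pearson by default, on the cited power-correlation approach; Spearman
#' optional).
#'
#' @param ep Epochs x samples matrix (one channel/ROI).
#' @param fs Sampling rate (Hz).
#' @param fmin,fmax Frequency range (Hz), defaults 2-70.
#' @param step Frequency step (Hz), default 0.5; must be a multiple of the
#'   epoch frequency resolution.
#' @param method `"pearson"` or `"spearman"`.
#' @return An `aac_matrix`: list with `freqs` and `values` (symmetric
#'   correlation matrix, unit diagonal).
#' @export
aac <- function(ep, fs, fmin = 2, fmax = 70, step = 0.5,
                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.vector(ep)) ep <- matrix(ep, 1)
  if (nrow(ep) < 8) stop_tinnpac("AAC needs at least 8 epochs")
  n <- ncol(ep)
  res <- fs / n
  if (abs(step / res - round(step / res)) > 1e-9) {
    stop_tinnpac("frequency step ", step, " Hz is not a multiple of the epoch resolution ",
                 res, " Hz (use longer epochs)")
  }
  freqs <- seq(fmin, fmax, by = step)
  bins <- round(freqs / res) + 1L
  w <- hann_window(n)
  pow <- t(apply(ep, 1, function(x) Mod(stats::fft(x * w)[bins])^2))
  values <- suppressWarnings(stats::cor(pow, method = method))
  values[!is.finite(values)] <- 0
  diag(values) <- 1
  values <- (values + t(values)) / 2
  dimnames(values) <- list(freqs, freqs)
  structure(list(freqs = freqs, values = values, method = method,
                 epoch_count = nrow(ep)),
            class = "aac_matrix")
}
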