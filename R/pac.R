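## Phase-amplitude coupling core: FIR filter bank, Hilbert phase/amplitude
## extraction, 18-bin Kullback-Leibler modulation index, comodulograms and
## band-averaged theta-beta / theta-gamma PAC.

# Analytic signal by the FFT method: negative frequencies zeroed, positive
# doubled. Real part is the input; modulus/argument give amplitude/phase.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase and amplitude via the Hilbert transform
#'
#' @param x Narrowband real signal.
#' @return List with `phase` (radians in `(-pi, pi]`) and `amplitude`
#'   (analytic-signal modulus, >= 0).
#' @export
hilbert_phase_amp <- function(x) {
  if (!all(is.finite(x))) stop_tinnpac("input must be finite")
  z <- analytic_signal(x)
  list(phase = Arg(z), amplitude = Mod(z))
}

#' Narrowband FIR filter (one filter-bank band)
#'
#' Windowed-sinc band-pass of `bandwidth` Hz around `center`, applied
#' zero-phase (forward-backward). Filter order follows the three-cycle
#' convention `3 * round(fs / lower_edge)` (eegfilt-style). For
#' high-frequency bands this gives a short kernel with a gentle roll-off —
#' deliberately so: amplitude-modulation sidebands sit at the modulating
#' frequency away from the carrier, outside a sharply-filtered 2-Hz band,
#' and a shallow transition keeps them in the effective passband so the
#' extracted envelope still carries the coupling.
#'
#' @param x Real signal.
#' @param fs Sampling rate (Hz).
#' @param center Band centre frequency (Hz).
#' @param bandwidth Band width (Hz), default 2.
#' @return Filtered signal, same length as `x`.
#' @export
fir_band <- function(x, fs, center, bandwidth = 2) {
  lo <- center - bandwidth / 2
  hi <- center + bandwidth / 2
  if (lo <= 0) stop_tinnpac("band lower edge must be positive")
  if (hi >= fs / 2) stop_tinnpac("band upper edge must be below Nyquist")
  ord <- fir_order(fs, lo, length(x))
  h <- signal::fir1(ord, c(lo, hi) / (fs / 2), type = "pass")
  fir_apply_zerophase(x, h)
}

# Map phase in (-pi, pi] to bin 1..n_bins (20-degree bins for n_bins = 18).
phase_bin_index <- function(phase, n_bins = 18L) {
  idx <- ceiling((phase + pi) / (2 * pi / n_bins))
  idx[idx < 1L] <- 1L
  idx[idx > n_bins] <- n_bins
  as.integer(idx)
}

#' Kullback-Leibler modulation index
#'
#' Phases are sorted into `n_bins` bins (default 18, i.e. 20-degree width),
#' amplitudes are averaged per bin and normalized into a distribution
#' \eqn{P}; the index is the KL divergence of \eqn{P} from uniform,
#' normalized to `[0, 1]`:
#' \deqn{MI = \frac{\log n_{bins} - H(P)}{\log n_{bins}}.}
#' 0 means amplitude is independent of phase; 1 means all amplitude mass
#' concentrates in a single phase bin.
#'
#' @param phase Phase series in radians.
#' @param amplitude Non-negative amplitude series, same length.
#' @param n_bins Number of phase bins (default 18).
#' @return Scalar MI in `[0, 1]`.
#' @export
kl_mi <- function(phase, amplitude, n_bins = 18L) {
  if (length(phase) != length(amplitude)) stop_tinnpac("length mismatch")
  if (any(amplitude < 0)) stop_tinnpac("amplitudes must be non-negative")
  if (all(amplitude == 0)) stop_tinnpac("all-zero amplitude: MI undefined")
  idx <- phase_bin_index(phase, n_bins)
  counts <- tabulate(idx, n_bins)
  if (any(counts == 0L)) {
    stop_tinnpac("empty phase bin; signal too short for ", n_bins,
                 "-bin occupancy (need several phase cycles)")
  }
  mi_from_binned(as.vector(rowsum(amplitude, idx)) / counts)
}

# MI from per-bin mean amplitudes.
mi_from_binned <- function(binmean) {
  n_bins <- length(binmean)
  P <- binmean / sum(binmean)
  nz <- P > 0
  H <- -sum(P[nz] * log(P[nz]))
  (log(n_bins) - H) / log(n_bins)
}

# Extract pooled phase-bin indices (per phase band) and amplitude series
# (per amplitude band) from a signal, following the epoch policy: filter the
# concatenated record, split back into epochs, trim `edge_trim_s` from each
# epoch edge, pool. `x` is a vector (one segment) or an epochs-by-samples
# matrix cut from a continuous record.
pac_extract <- function(x, fs, phase_lower_edges, amp_lower_edges,
                        bandwidth = 2, n_bins = 18L, edge_trim_s = 0.25) {
  if (is.matrix(x)) {
    n_ep <- nrow(x)
    spe <- ncol(x)
    sig <- as.vector(t(x))
  } else {
    n_ep <- 1L
    spe <- length(x)
    sig <- x
  }
  trim <- round(edge_trim_s * fs)
  if (2 * trim >= spe) stop_tinnpac("epochs too short for edge trimming")
  keep_in_epoch <- (trim + 1L):(spe - trim)
  keep <- as.vector(outer(keep_in_epoch, (seq_len(n_ep) - 1L) * spe, `+`))

  phase_bins <- lapply(phase_lower_edges, function(lo) {
    nb <- fir_band(sig, fs, center = lo + bandwidth / 2, bandwidth = bandwidth)
    phase_bin_index(Arg(analytic_signal(nb))[keep], n_bins)
  })
  amp_mat <- vapply(amp_lower_edges, function(lo) {
    nb <- fir_band(sig, fs, center = lo + bandwidth / 2, bandwidth = bandwidth)
    Mod(analytic_signal(nb))[keep]
  }, numeric(length(keep)))
  list(phase_bins = phase_bins, amp_mat = amp_mat,
       phase_centers = phase_lower_edges + bandwidth / 2,
       amp_centers = amp_lower_edges + bandwidth / 2,
       phase_upper = phase_lower_edges + bandwidth,
       amp_lower = amp_lower_edges, n_bins = n_bins)
}

mi_grid <- function(ext) {
  n_p <- length(ext$phase_centers)
  n_a <- length(ext$amp_centers)
  mi <- matrix(NA_real_, n_p, n_a,
               dimnames = list(ext$phase_centers, ext$amp_centers))
  for (i in seq_len(n_p)) {
    counts <- tabulate(ext$phase_bins[[i]], ext$n_bins)
    if (any(counts == 0L)) stop_tinnpac("empty phase bin in comodulogram")
    sums <- rowsum(ext$amp_mat, ext$phase_bins[[i]])
    means <- sums / counts
    for (j in seq_len(n_a)) {
      if (ext$phase_upper[i] < ext$amp_lower[j]) {
        mi[i, j] <- mi_from_binned(means[, j])
      }
    }
  }
  mi
}

#' Comodulogram: KL-MI over a (phase x amplitude) frequency grid
#'
#' Filters the signal through a phase bank (default lower edges 1-7 Hz in
#' 2-Hz steps, 2-Hz bandwidth) and an amplitude bank (default 7-149 Hz
#' lower edges), extracts Hilbert phase/amplitude, and computes the KL
#' modulation index for every admissible pair (phase band entirely below
#' the amplitude band's lower edge). Epoched input is filtered as the
#' concatenated record, then re-split with 0.25-s epoch-edge trimming
#' before pooling bin statistics.
#'
#' @param x Signal vector, or epochs-by-samples matrix cut from a
#'   continuous record.
#' @param fs Sampling rate (Hz).
#' @param phase_lower_edges,amp_lower_edges Filter-bank band lower edges
#'   (Hz); bands span `[edge, edge + bandwidth]`.
#' @param bandwidth Band width (Hz), default 2.
#' @param n_bins Phase bins, default 18.
#' @param edge_trim_s Seconds trimmed from each epoch edge before pooling.
#' @return An object of class `comodulogram`: `mi` matrix
#'   (phase centres x amplitude centres, `NA` where inadmissible),
#'   `phase_centers`, `amp_centers`.
#' @export
comodulogram <- function(x, fs,
                         phase_lower_edges = seq(1, 7, by = 2),
                         amp_lower_edges = seq(7, min(149, floor(fs / 2) - 3), by = 2),
                         bandwidth = 2, n_bins = 18L, edge_trim_s = 0.25) {
  n <- if (is.matrix(x)) length(x) else length(x)
  if (n < 10 * fs / min(phase_lower_edges)) {
    stop_tinnpac("signal must cover at least 10 cycles of the lowest phase band")
  }
  ext <- pac_extract(x, fs, phase_lower_edges, amp_lower_edges,
                     bandwidth, n_bins, edge_trim_s)
  structure(list(mi = mi_grid(ext),
                 phase_centers = ext$phase_centers,
                 amp_centers = ext$amp_centers,
                 bandwidth = bandwidth, n_bins = n_bins),
            class = "comodulogram")
}

#' @export
print.comodulogram <- function(x, ...) {
  cat(sprintf("<comodulogram> %d phase x %d amplitude bands; max MI %.4g at (%s, %s) Hz\n",
              length(x$phase_centers), length(x$amp_centers),
              max(x$mi, na.rm = TRUE),
              rownames(x$mi)[which(x$mi == max(x$mi, na.rm = TRUE), arr.ind = TRUE)[1, 1]],
              colnames(x$mi)[which(x$mi == max(x$mi, na.rm = TRUE), arr.ind = TRUE)[1, 2]]))
  invisible(x)
}

#' Location of the comodulogram maximum
#'
#' @param com A [comodulogram()].
#' @return Named numeric `c(phase, amp, mi)`.
#' @export
comodulogram_argmax <- function(com) {
  ij <- which(com$mi == max(com$mi, na.rm = TRUE), arr.ind = TRUE)[1, ]
  c(phase = com$phase_centers[ij[1]], amp = com$amp_centers[ij[2]],
    mi = max(com$mi, na.rm = TRUE))
}

#' Surrogate null for the comodulogram maximum
#'
#' Builds a phase-shuffled null by circularly shifting the amplitude series
#' against the phase series (shift at least 1 s), recomputing the grid
#' maximum MI for each surrogate. Observed coupling exceeding the 95th
#' percentile of this null is considered above chance.
#'
#' @inheritParams comodulogram
#' @param n_surrogates Number of surrogates (default 200).
#' @param seed Integer seed for the shifts.
#' @return List with `observed_max`, `surrogate_max` (vector),
#'   `threshold95`.
#' @export
pac_surrogate_max <- function(x, fs,
                              phase_lower_edges = seq(1, 7, by = 2),
                              amp_lower_edges = seq(7, min(149, floor(fs / 2) - 3), by = 2),
                              bandwidth = 2, n_bins = 18L, edge_trim_s = 0.25,
                              n_surrogates = 200, seed = 1) {
  ext <- pac_extract(x, fs, phase_lower_edges, amp_lower_edges,
                     bandwidth, n_bins, edge_trim_s)
  observed <- mi_grid(ext)
  n <- nrow(ext$amp_mat)
  admissible <- outer(ext$phase_upper, ext$amp_lower, `<`)
  surr <- with_seed(seed, {
    shifts <- sample(seq(round(fs), n - round(fs)), n_surrogates, replace = TRUE)
    vapply(shifts, function(o) {
      idx <- c((o + 1L):n, 1L:o)
      best <- 0
      for (i in seq_along(ext$phase_bins)) {
        sb <- ext$phase_bins[[i]][idx]
        counts <- tabulate(sb, ext$n_bins)
        means <- rowsum(ext$amp_mat, sb) / counts
        mis <- apply(means[, admissible[i, ], drop = FALSE], 2, mi_from_binned)
        best <- max(best, mis)
      }
      best
    }, numeric(1))
  })
  list(observed_max = max(observed, na.rm = TRUE), surrogate_max = surr,
       threshold95 = stats::quantile(surr, 0.95, names = FALSE))
}

#' Band-averaged PAC from a comodulogram
#'
#' Arithmetic mean of the admissible MI cells whose phase centre lies in
#' `phase_band` and amplitude centre in `amp_band` (edges inclusive).
#'
#' @param com A [comodulogram()].
#' @param phase_band Numeric `c(lo, hi)` in Hz, default theta 4-8.
#' @param amp_band Numeric `c(lo, hi)` in Hz, e.g. beta `c(13, 30)` or
#'   gamma `c(30, 70)`.
#' @return Scalar mean MI.
#' @export
band_pac <- function(com, phase_band = c(4, 8), amp_band = c(13, 30)) {
  pi_ <- com$phase_centers >= phase_band[1] & com$phase_centers <= phase_band[2]
  ai <- com$amp_centers >= amp_band[1] & com$amp_centers <= amp_band[2]
  cells <- com$mi[pi_, ai, drop = FALSE]
  cells <- cells[!is.na(cells)]
  if (!length(cells)) stop_tinnpac("no admissible comodulogram cells in the band box")
  mean(cells)
}

#' Per-ROI band PAC for one subject
#'
#' Computes, for every ROI time series, the band-averaged theta-beta and
#' theta-gamma KL-MI (one PAC value per ROI per band). Only the filter-bank
#' bands needed for the two band boxes are computed.
#'
#' @param roi A `roi_series` (see [aggregate_rois()]).
#' @param subject_id,group Metadata carried into the output rows.
#' @param phase_band Theta phase box, default `c(4, 8)`.
#' @param beta_band,gamma_band Amplitude boxes, defaults `c(13, 30)` and
#'   `c(30, 70)`.
#' @return A `pac_table` data.frame: `subject_id`, `group`, `roi`,
#'   `theta_beta_mi`, `theta_gamma_mi`.
#' @export
pac_pipeline <- function(roi, subject_id = "sub-001", group = NA_character_,
                         phase_band = c(4, 8), beta_band = c(13, 30),
                         gamma_band = c(30, 70)) {
  stopifnot(inherits(roi, "roi_series"))
  bw <- 2
  # bank lower edges whose centres fall inside the requested boxes
  phase_edges <- seq(1, 7, by = 2)
  phase_edges <- phase_edges[phase_edges + bw / 2 >= phase_band[1] &
                               phase_edges + bw / 2 <= phase_band[2]]
  amp_all <- seq(7, min(149, floor(roi$fs / 2) - 3), by = 2)
  amp_edges <- amp_all[amp_all + bw / 2 >= beta_band[1] &
                         amp_all + bw / 2 <= gamma_band[2]]
  d <- dim(roi$data)
  rows <- lapply(seq_len(d[2]), function(r) {
    x <- matrix(roi$data[, r, ], d[1], d[3])
    com <- comodulogram(x, roi$fs, phase_lower_edges = phase_edges,
                        amp_lower_edges = amp_edges, bandwidth = bw)
    data.frame(subject_id = subject_id, group = group,
               roi = roi$roi_labels[r],
               theta_beta_mi = band_pac(com, phase_band, beta_band),
               theta_gamma_mi = band_pac(com, phase_band, gamma_band),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pac_table", "data.frame")
  out
}
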