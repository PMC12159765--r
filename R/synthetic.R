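## Synthetic cohort generator: sensor- and source-level EEG with known
## cross-frequency coupling, so every downstream stage has a ground-truth
## recovery test.

#' Specification of a single planted phase-amplitude coupling
#'
#' Describes one coupled oscillator pair: a low-frequency phase oscillation
#' whose phase modulates the amplitude of a high-frequency carrier, embedded
#' in 1/f background noise. The generative model is
#' \deqn{x(t) = \sin(2\pi f_p t) + [1 + m\cos(2\pi f_p t)]\,c\,\sin(2\pi f_a t) + \epsilon(t)}
#' with modulation depth \eqn{m \in [0,1]}, carrier amplitude \eqn{c} and
#' 1/f noise \eqn{\epsilon} of standard deviation `noise_sd`.
#'
#' @param phase_freq Phase (modulating) frequency in Hz.
#' @param amp_freq Amplitude (carrier) frequency in Hz; must exceed
#'   `phase_freq`.
#' @param modulation_depth Modulation depth in `[0, 1]`; 0 plants no coupling.
#' @param carrier_amplitude Carrier amplitude in signal units.
#' @param noise_sd Standard deviation of the 1/f background noise.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(phase_freq = 6, amp_freq = 40, modulation_depth = 0.5,
                          carrier_amplitude = 0.3, noise_sd = 1.5) {
  if (modulation_depth < 0 || modulation_depth > 1) {
    stop_tinnpac("modulation_depth must lie in [0, 1]")
  }
  if (phase_freq >= amp_freq) {
    stop_tinnpac("phase_freq must be below amp_freq")
  }
  if (noise_sd < 0) stop_tinnpac("noise_sd must be non-negative")
  structure(list(phase_freq = phase_freq, amp_freq = amp_freq,
                 modulation_depth = modulation_depth,
                 carrier_amplitude = carrier_amplitude, noise_sd = noise_sd),
            class = "coupling_spec")
}

#' 1/f (pink) Gaussian noise
#'
#' Gaussian noise whose power spectrum falls off as 1/f, matching the
#' broadband background of resting EEG. Generated by spectral shaping of
#' white noise; the output is standardized to unit standard deviation
#' before scaling by `sd`.
#'
#' @param n Number of samples.
#' @param sd Target standard deviation.
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, sd = 1) {
  if (sd == 0 || n == 0) return(numeric(n))
  nfft <- next_fast_len(n)
  white <- stats::rnorm(nfft)
  spec <- stats::fft(white)
  f <- c(1, seq_len(nfft - 1))            # avoid the DC singularity
  f <- pmin(f, nfft - f + 1)              # mirror for negative frequencies
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
  x <- x - mean(x)
  sd * x / stats::sd(x)
}

#' Generate a signal with planted phase-amplitude coupling
#'
#' @param spec A [coupling_spec()].
#' @param duration_s Duration in seconds; must cover at least 10 cycles of
#'   the phase frequency.
#' @param fs Sampling rate in Hz; must exceed twice the carrier frequency.
#' @param seed Integer seed for the noise stream.
#' @return Numeric vector of length `round(duration_s * fs)`.
#' @export
generate_coupled_signal <- function(spec, duration_s, fs, seed = 1) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (fs < 2 * spec$amp_freq) {
    stop_tinnpac("fs must be at least twice amp_freq (", 2 * spec$amp_freq,
                 " Hz) to avoid aliasing")
  }
  n <- round(duration_s * fs)
  if (duration_s * spec$phase_freq < 10) {
    stop_tinnpac("signal must cover at least 10 cycles of phase_freq")
  }
  t <- (seq_len(n) - 1L) / fs
  phase <- 2 * pi * spec$phase_freq * t
  carrier <- (1 + spec$modulation_depth * cos(phase)) *
    spec$carrier_amplitude * sin(2 * pi * spec$amp_freq * t)
  noise <- if (spec$noise_sd > 0) {
    with_seed(seed, pink_noise(n, spec$noise_sd))
  } else numeric(n)
  sin(phase) + carrier + noise
}

#' Per-ROI coupling profile
#'
#' Planted theta-beta and theta-gamma modulation depths for one region,
#' plus relative amplitudes of the three oscillatory components. The theta
#' oscillation provides the modulating phase; beta (default 20 Hz) and
#' gamma (default 40 Hz) carriers are amplitude-modulated by it.
#'
#' @param roi_label ROI label (AAL short code, e.g. `"HES.L"`).
#' @param theta_beta_depth,theta_gamma_depth Modulation depths in `[0, 1]`.
#' @param base_power Named numeric of component amplitudes
#'   (`theta`, `beta`, `gamma`).
#' @param noise_sd Standard deviation of the ROI's 1/f background.
#' @return An object of class `roi_profile`.
#' @export
roi_profile <- function(roi_label, theta_beta_depth = 0, theta_gamma_depth = 0,
                        base_power = c(theta = 1, beta = 0.4, gamma = 0.3),
                        noise_sd = 1.5) {
  depths <- c(theta_beta_depth, theta_gamma_depth)
  if (any(depths < 0 | depths > 1)) {
    stop_tinnpac("modulation depths must lie in [0, 1]")
  }
  if (!all(c("theta", "beta", "gamma") %in% names(base_power))) {
    stop_tinnpac("base_power needs named entries theta, beta, gamma")
  }
  structure(list(roi_label = roi_label,
                 theta_beta_depth = theta_beta_depth,
                 theta_gamma_depth = theta_gamma_depth,
                 base_power = base_power, noise_sd = noise_sd),
            class = "roi_profile")
}

# One ROI's source time course: theta phase oscillation plus beta and gamma
# carriers amplitude-modulated by the theta phase, plus pink background.
# Random initial phases decorrelate subjects; the RNG state is the caller's.
roi_source_signal <- function(profile, n, fs,
                              theta_freq = 6, beta_freq = 20, gamma_freq = 40) {
  t <- (seq_len(n) - 1L) / fs
  phi0 <- stats::runif(3, 0, 2 * pi)
  theta_phase <- 2 * pi * theta_freq * t + phi0[1]
  bp <- profile$base_power
  x <- bp[["theta"]] * sin(theta_phase) +
    (1 + profile$theta_beta_depth * cos(theta_phase)) *
      bp[["beta"]] * sin(2 * pi * beta_freq * t + phi0[2]) +
    (1 + profile$theta_gamma_depth * cos(theta_phase)) *
      bp[["gamma"]] * sin(2 * pi * gamma_freq * t + phi0[3])
  if (profile$noise_sd > 0) x <- x + pink_noise(n, profile$noise_sd)
  x
}

#' Generate a synthetic leadfield (sensor mixing matrix)
#'
#' An abstract full-rank gain matrix standing in for a forward head model,
#' plus a source-to-ROI assignment in which every ROI owns at least one
#' source. Entries are i.i.d. Gaussian; no electrode or cortical geometry
#' is modelled.
#'
#' @param n_sensors,n_sources Matrix dimensions.
#' @param roi_labels Character vector of ROI labels (`n_rois <= n_sources`).
#' @param seed Integer seed.
#' @return An object of class `leadfield` with elements `gain`
#'   (`n_sensors x n_sources`) and `roi_map` (character, one label per
#'   source).
#' @export
generate_leadfield <- function(n_sensors, n_sources, roi_labels, seed = 1) {
  n_rois <- length(roi_labels)
  if (n_rois < 1 || n_sources < n_rois) {
    stop_tinnpac("need n_sources >= n_rois >= 1")
  }
  gain <- with_seed(seed, {
    repeat {
      g <- matrix(stats::rnorm(n_sensors * n_sources), n_sensors, n_sources)
      if (qr(g)$rank == min(n_sensors, n_sources)) break
    }
    g
  })
  # round-robin assignment guarantees >= 1 source per ROI
  roi_map <- roi_labels[((seq_len(n_sources) - 1L) %% n_rois) + 1L]
  structure(list(gain = gain, roi_map = roi_map, roi_labels = roi_labels),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %d sensors x %d sources, %d ROIs\n",
              nrow(x$gain), ncol(x$gain), length(x$roi_labels)))
  invisible(x)
}

#' Generate one synthetic subject
#'
#' Builds source time courses from per-ROI coupling profiles, mixes them to
#' the sensors through the leadfield, adds sensor noise at a given SNR, and
#' returns both the sensor recording and the ground-truth ROI time series.
#' Sources within an ROI share the ROI signal plus independent pink noise.
#'
#' @param profiles List of [roi_profile()] objects, one per ROI.
#' @param leadfield A [generate_leadfield()] result covering those ROIs.
#' @param duration_s,fs Signal duration (s) and sampling rate (Hz).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param sensor_snr_db Sensor-level SNR in dB (signal RMS over added white
#'   noise RMS); `Inf` for noiseless sensors.
#' @param source_noise_sd Within-ROI per-source independent noise SD.
#' @return List with `recording` (a [recording()]), `truth` (ROI x samples
#'   matrix of ground-truth ROI series) and `roi_labels`.
#' @export
generate_subject <- function(profiles, leadfield, duration_s, fs, seed = 1,
                             sensor_snr_db = 20, source_noise_sd = 0.2) {
  labels <- vapply(profiles, function(p) p$roi_label, character(1))
  if (!all(labels %in% leadfield$roi_map)) {
    stop_tinnpac("profile ROI(s) missing from leadfield roi_map: ",
                 paste(setdiff(labels, leadfield$roi_map), collapse = ", "))
  }
  n <- round(duration_s * fs)
  n_sources <- ncol(leadfield$gain)
  with_seed(seed, {
    roi_sig <- matrix(0, length(profiles), n)
    for (i in seq_along(profiles)) {
      roi_sig[i, ] <- roi_source_signal(profiles[[i]], n, fs)
    }
    src <- matrix(0, n_sources, n)
    for (j in seq_len(n_sources)) {
      i <- match(leadfield$roi_map[j], labels)
      base <- if (is.na(i)) numeric(n) else roi_sig[i, ]
      extra <- if (source_noise_sd > 0) pink_noise(n, source_noise_sd) else 0
      src[j, ] <- base + extra
    }
    sensors <- leadfield$gain %*% src
    if (is.finite(sensor_snr_db)) {
      sig_rms <- sqrt(mean(sensors^2))
      noise_sd <- sig_rms / 10^(sensor_snr_db / 20)
      sensors <- sensors + matrix(stats::rnorm(length(sensors), sd = noise_sd),
                                  nrow(sensors), ncol(sensors))
    }
    # ground truth = signed mean over each ROI's sources (matches the
    # aggregation the inverse stage applies)
    truth <- rowsum(src, group = leadfield$roi_map)
    truth <- truth / as.vector(table(leadfield$roi_map)[rownames(truth)])
    truth <- truth[labels, , drop = FALSE]
    rec <- recording(sensors, fs = fs,
                     channel_labels = sprintf("S%03d", seq_len(nrow(sensors))))
    rec <- append_history(rec, sprintf("synthetic subject (seed %d)", seed))
    list(recording = rec, truth = truth, roi_labels = labels)
  })
}

#' Cohort specification
#'
#' Study-design parameters for a synthetic cohort: group sizes, recording
#' geometry, per-group ROI coupling profiles, and the THI (Tinnitus
#' Handicap Inventory, 0-100) score model. Group membership follows the
#' 36-point THI threshold: bothersome tinnitus (BT) above 36,
#' non-bothersome (NBT) at or below 36, healthy controls (HC) without a
#' score.
#'
#' @param n_bt,n_nbt,n_hc Group sizes (each >= 2).
#' @param duration_s Recording duration per subject in seconds; must divide
#'   into whole 2-s epochs.
#' @param fs Sampling rate in Hz.
#' @param n_sensors,n_sources Leadfield geometry.
#' @param roi_profiles Named list (`BT`, `NBT`, `HC`) of lists of
#'   [roi_profile()]; all groups must cover the same ROI set.
#' @param thi_model Named list (`BT`, `NBT`) of `c(mean, sd)` for the
#'   truncated-normal THI draw. Defaults follow published tinnitus cohort
#'   descriptives (BT 44.43 +/- 9.32, NBT 18.52 +/- 11.22).
#' @param sensor_snr_db Sensor SNR passed to [generate_subject()].
#' @param seed Master seed; all subject-level streams derive from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_bt = 21, n_nbt = 27, n_hc = 21,
                        duration_s = 60, fs = 500,
                        n_sensors = 32, n_sources = 2 * length(roi_profiles$BT),
                        roi_profiles = default_roi_profiles(),
                        thi_model = list(BT = c(mean = 44.43, sd = 9.32),
                                         NBT = c(mean = 18.52, sd = 11.22)),
                        sensor_snr_db = 20, seed = 1) {
  if (n_bt < 2 || n_nbt < 2) stop_tinnpac("need at least 2 subjects per tinnitus group")
  if (abs(duration_s %% 2) > 1e-9) {
    stop_tinnpac("duration_s must divide into whole 2-s epochs")
  }
  if (!all(c("BT", "NBT", "HC") %in% names(roi_profiles))) {
    stop_tinnpac("roi_profiles must name groups BT, NBT, HC")
  }
  lab <- function(g) vapply(roi_profiles[[g]], function(p) p$roi_label, character(1))
  if (!identical(lab("BT"), lab("NBT")) || !identical(lab("BT"), lab("HC"))) {
    stop_tinnpac("all groups must share one ROI set, in the same order")
  }
  # a THI model that can never satisfy the group threshold is a spec error
  if (thi_model$BT[["sd"]] == 0 && thi_model$BT[["mean"]] <= 36) {
    stop_tinnpac("BT THI model cannot exceed the 36-point threshold")
  }
  if (thi_model$NBT[["sd"]] == 0 && thi_model$NBT[["mean"]] > 36) {
    stop_tinnpac("NBT THI model cannot respect the 36-point threshold")
  }
  structure(list(n_bt = n_bt, n_nbt = n_nbt, n_hc = n_hc,
                 duration_s = duration_s, fs = fs, n_sensors = n_sensors,
                 n_sources = n_sources, roi_profiles = roi_profiles,
                 thi_model = thi_model, sensor_snr_db = sensor_snr_db,
                 seed = seed),
            class = "cohort_spec")
}

#' Default per-group ROI coupling profiles
#'
#' An eight-ROI desk-scale study design echoing the qualitative group
#' pattern reported for tinnitus: enhanced theta-beta and theta-gamma
#' coupling in auditory regions (Heschl gyrus, superior temporal gyrus) and
#' posterior cingulate of the bothersome-tinnitus group, with reduced
#' theta-gamma coupling in inferior orbitofrontal cortex; the
#' non-bothersome group sits between patients and controls.
#'
#' @return Named list (`BT`, `NBT`, `HC`) of lists of [roi_profile()].
#' @export
default_roi_profiles <- function() {
  rois <- c("HES.L", "HES.R", "STG.L", "STG.R",
            "ORBinf.L", "ORBinf.R", "PCG.L", "PCG.R")
  depth <- list(
    BT  = list(tb = c(0.60, 0.60, 0.60, 0.60, 0.50, 0.50, 0.55, 0.55),
               tg = c(0.70, 0.70, 0.70, 0.70, 0.10, 0.10, 0.55, 0.55)),
    NBT = list(tb = c(0.30, 0.30, 0.30, 0.30, 0.30, 0.30, 0.30, 0.30),
               tg = c(0.30, 0.30, 0.30, 0.30, 0.40, 0.40, 0.30, 0.30)),
    HC  = list(tb = rep(0.15, 8), tg = rep(0.15, 8)))
  lapply(depth, function(d) {
    lapply(seq_along(rois), function(i) {
      roi_profile(rois[i], theta_beta_depth = d$tb[i], theta_gamma_depth = d$tg[i])
    })
  })
}

# Truncated-normal THI draw consistent with the 36-point group threshold,
# clipped to the instrument's 0-100 range.
draw_thi <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (iter in 1:10000) {
      x <- round(min(100, max(0, stats::rnorm(1, mean, sd))))
      if (x > lower && x <= upper) { out[i] <- x; break }
      if (iter == 10000) stop_tinnpac("THI model inconsistent with threshold")
    }
  }
  out
}

#' Generate a synthetic cohort
#'
#' Draws cohort metadata (group labels, THI scores, per-subject seeds) and
#' the shared leadfield. Subject EEG is materialized lazily with
#' [cohort_subject()], so arbitrarily large cohorts never need to fit in
#' memory at once.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `cohort` with `metadata` (data.frame:
#'   `subject_id`, `group`, `thi`, `seed`), `leadfield`, and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  roi_labels <- vapply(spec$roi_profiles$BT, function(p) p$roi_label, character(1))
  lf <- generate_leadfield(spec$n_sensors, spec$n_sources, roi_labels,
                           seed = derive_seed(spec$seed, "leadfield"))
  groups <- c(rep("BT", spec$n_bt), rep("NBT", spec$n_nbt), rep("HC", spec$n_hc))
  n <- length(groups)
  thi <- rep(NA_real_, n)
  with_seed(derive_seed(spec$seed, "thi"), {
    thi[groups == "BT"] <- draw_thi(spec$n_bt, spec$thi_model$BT[["mean"]],
                                    spec$thi_model$BT[["sd"]], 36, 100)
    thi[groups == "NBT"] <- draw_thi(spec$n_nbt, spec$thi_model$NBT[["mean"]],
                                     spec$thi_model$NBT[["sd"]], -1, 36)
  })
  metadata <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    group = groups, thi = thi,
    seed = vapply(seq_len(n), function(i) derive_seed(spec$seed, "subject", i),
                  integer(1)),
    stringsAsFactors = FALSE)
  structure(list(metadata = metadata, leadfield = lf, spec = spec,
                 roi_labels = roi_labels),
            class = "cohort")
}

#' Materialize one subject of a cohort
#'
#' @param cohort A [generate_cohort()] result.
#' @param i Subject index (row of `cohort$metadata`).
#' @return The [generate_subject()] result for that subject.
#' @export
cohort_subject <- function(cohort, i) {
  stopifnot(inherits(cohort, "cohort"))
  meta <- cohort$metadata[i, ]
  profiles <- cohort$spec$roi_profiles[[meta$group]]
  generate_subject(profiles, cohort$leadfield,
                   duration_s = cohort$spec$duration_s, fs = cohort$spec$fs,
                   seed = meta$seed, sensor_snr_db = cohort$spec$sensor_snr_db)
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$metadata$group)
  cat(sprintf("<cohort> %d subjects (%s), %d ROIs, %g s @ %g Hz\n",
              nrow(x$metadata),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              length(x$roi_labels), x$spec$duration_s, x$spec$fs))
  invisible(x)
}
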