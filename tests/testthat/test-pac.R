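test_that("Hilbert phase/amplitude extraction matches the analytic closed form", {
  fs <- 500
  t <- (0:(10 * fs - 1)) / fs
  x <- sin(2 * pi * 6 * t)
  ha <- hilbert_phase_amp(x)
  interior <- 500:4500
  expect_lt(max(abs(ha$amplitude[interior] - 1)), 0.01)
  # phase advances at 2*pi*f/fs per sample: regression on unwrapped phase
  dphi <- diff(ha$phase[interior])
  dphi[dphi < -pi] <- dphi[dphi < -pi] + 2 * pi
  f_est <- mean(dphi) * fs / (2 * pi)
  expect_equal(f_est, 6, tolerance = 0.01)
  # linearity of amplitude, invariance of phase
  ha3 <- hilbert_phase_amp(3 * x)
  expect_equal(ha3$amplitude, 3 * ha$amplitude, tolerance = 1e-10)
  expect_equal(ha3$phase, ha$phase, tolerance = 1e-8)
  expect_error(hilbert_phase_amp(c(1, NA, 3)), "finite")
})

test_that("fir_band passes in-band tones and rejects distant tones", {
  fs <- 500
  t <- (0:(20 * fs - 1)) / fs
  centre <- sin(2 * pi * 6 * t)
  expect_gt(sd(fir_band(centre, fs, 6, 2)) / sd(centre), 0.90)
  far <- sin(2 * pi * 12 * t)  # centre + 3 bandwidths
  expect_lt(sd(fir_band(far, fs, 6, 2)) / sd(far), 0.10)
  expect_lt(max(abs(fir_band(numeric(2000), fs, 6, 2))), 1e-12)
  expect_error(fir_band(centre, fs, 0.5, 2), "positive")
  expect_error(fir_band(centre, fs, 260, 2), "Nyquist")
})

test_that("kl_mi hits exact values at the distribution extremes", {
  set.seed(1)
  phase <- runif(30000, -pi, pi)
  expect_identical(kl_mi(phase, rep(2.5, 30000)), 0)
  # all amplitude mass in one bin
  amp <- as.numeric(phase > -pi + 0 & phase <= -pi + 2 * pi / 18)
  expect_equal(kl_mi(phase, amp), 1, tolerance = 1e-12)
})

test_that("kl_mi stays in [0,1] and is invariant to amplitude scale and bin rotation", {
  set.seed(2)
  for (i in 1:50) {
    n <- sample(500:3000, 1)
    phase <- runif(n, -pi, pi)
    amp <- rexp(n)
    mi <- kl_mi(phase, amp)
    expect_gte(mi, 0)
    expect_lte(mi, 1)
    expect_equal(kl_mi(phase, 17.3 * amp), mi, tolerance = 1e-12)
    # circular relabeling: rotate phases by exactly one bin width
    rot <- phase + 2 * pi / 18
    rot[rot > pi] <- rot[rot > pi] - 2 * pi
    expect_equal(kl_mi(rot, amp), mi, tolerance = 1e-9)
  }
})

test_that("kl_mi matches the quadrature oracle for cosine amplitude profiles", {
  phi <- seq(-pi, pi, length.out = 2e5 + 1)[-1]
  for (m in c(0.2, 0.5, 0.8)) {
    expect_equal(kl_mi(phi, 1 + m * cos(phi)), quad_mi_oracle(m),
                 tolerance = 5e-4)
  }
})

test_that("kl_mi rejects degenerate inputs", {
  expect_error(kl_mi(runif(5, -pi, pi), rep(1, 5)), "empty phase bin")
  expect_error(kl_mi(runif(1000, -pi, pi), rep(0, 1000)), "all-zero")
  expect_error(kl_mi(runif(100, -pi, pi), c(rep(1, 99), -1)), "non-negative")
  expect_error(kl_mi(1:3, 1:4), "length mismatch")
})

test_that("comodulogram localizes a planted coupling and flags inadmissible cells", {
  spec <- coupling_spec(6, 40, 0.9)
  x <- generate_coupled_signal(spec, 100, 500, seed = 1)
  com <- comodulogram(x, 500)
  am <- comodulogram_argmax(com)
  expect_equal(unname(am["phase"]), 6, tolerance = 2)
  expect_equal(unname(am["amp"]), 40, tolerance = 2)
  # admissibility: phase band upper edge must sit below amp band lower edge
  expect_true(is.na(com$mi["8", "8"]))   # phase [7,9] vs amp [7,9]
  expect_false(anyNA(com$mi[, com$amp_centers >= 12]))
  expect_error(comodulogram(x[1:500], 500), "10 cycles")
})

test_that("uncoupled signals stay below the phase-shuffled surrogate threshold", {
  set.seed(5)
  noise <- rnorm(60 * 500)
  sur <- pac_surrogate_max(noise, 500, n_surrogates = 100, seed = 2)
  expect_lt(sur$observed_max, sur$threshold95)
  # a pure tone has no coupling partner either
  tone <- sin(2 * pi * 10 * (0:(60 * 500 - 1)) / 500) + rnorm(60 * 500, sd = 0.05)
  sur2 <- pac_surrogate_max(tone, 500, n_surrogates = 100, seed = 3)
  expect_lt(sur2$observed_max, sur2$threshold95)
})

test_that("band_pac averages the admissible cells inside the band box", {
  com <- structure(list(
    mi = matrix(c(0.1, 0.3, 0.2, 0.4), 2, 2,
                dimnames = list(c(4, 6), c(20, 40))),
    phase_centers = c(4, 6), amp_centers = c(20, 40)),
    class = "comodulogram")
  expect_equal(band_pac(com, c(4, 8), c(13, 30)), 0.2)       # mean(0.1, 0.3)
  expect_equal(band_pac(com, c(4, 8), c(30, 70)), 0.3)       # mean(0.2, 0.4)
  expect_equal(band_pac(com, c(4, 8), c(13, 70)), 0.25)
  com$mi[] <- 0.07
  expect_equal(band_pac(com, c(4, 8), c(13, 70)), 0.07)      # constant box
  expect_error(band_pac(com, c(4, 8), c(100, 120)), "no admissible")
})

test_that("pac_pipeline returns one row per ROI with the planted band ordering", {
  # gamma-only coupling in R1, beta-only in R2, none in R3
  mk <- function(tb, tg, seed) {
    p <- roi_profile("X", theta_beta_depth = tb, theta_gamma_depth = tg)
    tinnpac:::with_seed(seed, tinnpac:::roi_source_signal(p, 40 * 500, 500))
  }
  rs <- make_roi_series(list(mk(0, 0.8, 1), mk(0.8, 0, 2), mk(0, 0, 3)),
                        labels = c("GAMMA", "BETA", "NONE"))
  pt <- pac_pipeline(rs, subject_id = "s1", group = "BT")
  expect_s3_class(pt, "pac_table")
  expect_equal(nrow(pt), 3)
  expect_identical(pt$roi, c("GAMMA", "BETA", "NONE"))
  g <- pt[pt$roi == "GAMMA", ]; b <- pt[pt$roi == "BETA", ]; z <- pt[pt$roi == "NONE", ]
  expect_gt(g$theta_gamma_mi, g$theta_beta_mi)
  expect_gt(b$theta_beta_mi, b$theta_gamma_mi)
  expect_gt(g$theta_gamma_mi, z$theta_gamma_mi)
  expect_gt(b$theta_beta_mi, z$theta_beta_mi)
  # determinism: identical input gives identical rows
  pt2 <- pac_pipeline(rs, subject_id = "s1", group = "BT")
  expect_identical(pt, pt2)
})

test_that("planted per-ROI coupling ordering survives the full subject chain", {
  labels <- c("ORBinf.L", "HES.L")
  profiles <- list(roi_profile("ORBinf.L", 0.1, 0.1),
                   roi_profile("HES.L", 0.8, 0.8))
  lf <- generate_leadfield(8, 4, labels, seed = 3)
  subj <- generate_subject(profiles, lf, duration_s = 40, fs = 500, seed = 2,
                           sensor_snr_db = 20)
  ep <- detrend_noise(resample_epoch(subj$recording, 500, 2))
  roi <- aggregate_rois(mne_inverse(ep, lf), lf$roi_map, labels)
  pt <- pac_pipeline(roi)
  expect_gt(pt$theta_gamma_mi[pt$roi == "HES.L"],
            pt$theta_gamma_mi[pt$roi == "ORBinf.L"])
  expect_gt(pt$theta_beta_mi[pt$roi == "HES.L"],
            pt$theta_beta_mi[pt$roi == "ORBinf.L"])
})
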