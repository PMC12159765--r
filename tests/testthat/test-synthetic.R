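test_that("generate_coupled_signal honours length, determinism and preconditions", {
  spec <- coupling_spec(phase_freq = 6, amp_freq = 40, modulation_depth = 0.5)
  x <- generate_coupled_signal(spec, duration_s = 10, fs = 500, seed = 1)
  expect_length(x, 5000)
  expect_identical(x, generate_coupled_signal(spec, 10, 500, seed = 1))
  expect_false(identical(x, generate_coupled_signal(spec, 10, 500, seed = 2)))
  expect_error(generate_coupled_signal(spec, 10, fs = 60, seed = 1), "aliasing")
  expect_error(generate_coupled_signal(spec, 1, 500, seed = 1), "10 cycles")
  expect_error(coupling_spec(modulation_depth = 1.2), "\\[0, 1\\]")
  expect_error(coupling_spec(phase_freq = 50, amp_freq = 40), "below")
  expect_error(coupling_spec(noise_sd = -1), "non-negative")
})

test_that("generated signal's PSD peaks at the planted phase and carrier frequencies", {
  spec <- coupling_spec(6, 40, 0.8, noise_sd = 0)
  x <- generate_coupled_signal(spec, 60, 500, seed = 1)
  ep <- matrix(x[1:(30 * 1000)], nrow = 30, byrow = TRUE)  # 2-s epochs
  sp <- psd(ep, 500)
  theta_peak <- sp$freqs[sp$freqs < 20][which.max(sp$power[sp$freqs < 20])]
  high <- sp$freqs > 20 & sp$freqs < 100
  amp_peak <- sp$freqs[high][which.max(sp$power[high])]
  expect_lt(abs(theta_peak - 6), 0.5 + 1e-9)
  expect_lt(abs(amp_peak - 40), 0.5 + 1e-9)
})

test_that("estimated coupling at the planted pair is monotone in modulation depth", {
  depths <- c(0, 0.25, 0.5, 0.75, 1)
  n_increasing <- 0
  for (s in 1:5) {
    mis <- vapply(depths, function(m) {
      x <- generate_coupled_signal(coupling_spec(6, 40, m), 60, 500, seed = s)
      com <- comodulogram(x, 500, phase_lower_edges = 5, amp_lower_edges = 39)
      com$mi[1, 1]
    }, numeric(1))
    if (!is.unsorted(mis)) n_increasing <- n_increasing + 1
  }
  expect_gte(n_increasing, 3)  # majority of seeds strictly ordered
})

test_that("generate_leadfield yields full-rank matrices covering every ROI", {
  labels <- sprintf("ROI%02d", 1:26)
  lf <- generate_leadfield(32, 52, labels, seed = 4)
  expect_equal(dim(lf$gain), c(32, 52))
  expect_equal(qr(lf$gain)$rank, 32)
  expect_true(all(labels %in% lf$roi_map))
  expect_identical(lf$gain, generate_leadfield(32, 52, labels, seed = 4)$gain)
  expect_error(generate_leadfield(8, 4, sprintf("R%d", 1:6)), "n_sources >= n_rois")
  # square case is invertible
  lf4 <- generate_leadfield(4, 4, c("A", "B", "C", "D"), seed = 1)
  expect_gt(abs(det(lf4$gain)), 0)
})

test_that("generate_subject mixes sources through the leadfield as specified", {
  labels <- c("A", "B", "C", "D")
  lf <- generate_leadfield(4, 4, labels, seed = 2)
  lf$gain <- diag(4)  # identity mixing
  profiles <- lapply(labels, function(l) roi_profile(l, 0.5, 0.5, noise_sd = 0.2))
  subj <- generate_subject(profiles, lf, duration_s = 4, fs = 250, seed = 9,
                           sensor_snr_db = Inf, source_noise_sd = 0)
  expect_equal(unname(subj$recording$data), unname(subj$truth),
               tolerance = 1e-12)
  # determinism
  subj2 <- generate_subject(profiles, lf, 4, 250, seed = 9,
                            sensor_snr_db = Inf, source_noise_sd = 0)
  expect_identical(subj$recording$data, subj2$recording$data)
  bad <- list(roi_profile("MISSING", 0.1, 0.1))
  expect_error(generate_subject(bad, lf, 4, 250), "missing from leadfield")
})

test_that("cohort metadata respects group sizes and the 36-point THI threshold", {
  spec <- cohort_spec(n_bt = 21, n_nbt = 27, n_hc = 21, duration_s = 2,
                      n_sensors = 8, seed = 5)
  cohort <- generate_cohort(spec)
  tab <- table(cohort$metadata$group)
  expect_equal(unname(tab[c("BT", "NBT", "HC")]), c(21L, 27L, 21L),
               ignore_attr = TRUE)
  expect_true(all(cohort$metadata$thi[cohort$metadata$group == "BT"] > 36))
  expect_true(all(cohort$metadata$thi[cohort$metadata$group == "NBT"] <= 36))
  expect_true(all(is.na(cohort$metadata$thi[cohort$metadata$group == "HC"])))
  expect_true(all(cohort$metadata$thi >= 0 | is.na(cohort$metadata$thi)))
  # reproducible end to end
  cohort2 <- generate_cohort(spec)
  expect_identical(cohort$metadata, cohort2$metadata)
})

test_that("impossible THI models are rejected", {
  expect_error(
    cohort_spec(thi_model = list(BT = c(mean = 30, sd = 0),
                                 NBT = c(mean = 18.52, sd = 11.22))),
    "36-point")
  expect_error(
    cohort_spec(thi_model = list(BT = c(mean = 44.43, sd = 9.32),
                                 NBT = c(mean = 50, sd = 0))),
    "36-point")
  expect_error(cohort_spec(duration_s = 3), "2-s epochs")
  expect_error(cohort_spec(n_bt = 1), "at least 2")
})

test_that("pink noise has a decaying spectrum and exact standard deviation", {
  set.seed(42)
  x <- pink_noise(2^14, sd = 2)
  expect_equal(sd(x), 2, tolerance = 1e-9)
  sp <- psd(matrix(x, nrow = 16, byrow = TRUE), 500)
  low <- mean(sp$power[sp$freqs >= 2 & sp$freqs <= 10])
  high <- mean(sp$power[sp$freqs >= 60 & sp$freqs <= 100])
  expect_gt(low / high, 3)
})
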