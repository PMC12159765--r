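test_that("normality_screen separates normal from skewed samples", {
  set.seed(30)
  flags <- replicate(40, normality_screen(rnorm(200))$normal)
  expect_gte(mean(flags), 0.8)
  flags_exp <- replicate(40, normality_screen(rexp(200))$normal)
  expect_lte(mean(flags_exp), 0.05)
  sw <- normality_screen(rnorm(50))
  expect_gt(sw$W, 0); expect_lte(sw$W, 1)
  expect_error(normality_screen(c(1, 2)), "3 <= n")
  expect_error(normality_screen(rep(2, 10)), "constant")
})

test_that("rm_anova reproduces the hand-computed 2x2 mixed-design example", {
  res <- rm_anova(anova_mini_data(), n_family = 1)
  expect_equal(res$F[res$effect == "Group"], anova_mini_expected[["Group"]],
               tolerance = 1e-10)
  expect_equal(res$F[res$effect == "ROI"], anova_mini_expected[["ROI"]],
               tolerance = 1e-10)
  expect_equal(res$F[res$effect == "ROI:Group"],
               anova_mini_expected[["ROI:Group"]], tolerance = 1e-10)
  expect_equal(res$df_num, c(1, 1, 1))
  expect_equal(res$df_den, c(2, 2, 2))
})

test_that("rm_anova degenerate and invalid designs are handled", {
  d <- anova_mini_data()
  d$theta_beta_mi <- 5
  res <- rm_anova(d)
  expect_true(all(res$F == 0))
  expect_true(all(res$p == 1))
  d2 <- anova_mini_data()[-1, ]  # subject A missing ROI r1
  expect_error(rm_anova(d2), "unbalanced")
  d3 <- anova_mini_data()
  d3$group <- "g1"
  expect_error(rm_anova(d3), "two groups")
})

test_that("rm_anova detects a planted ROI-by-Group interaction", {
  set.seed(31)
  hits <- 0
  runs <- 100
  for (r in seq_len(runs)) {
    rois <- paste0("R", 1:6)
    df <- expand.grid(subject_id = sprintf("s%02d", 1:40), roi = rois,
                      stringsAsFactors = FALSE)
    df$group <- ifelse(as.integer(sub("s", "", df$subject_id)) <= 20, "a", "b")
    df$theta_beta_mi <- rnorm(nrow(df))
    shift <- df$group == "a" & df$roi %in% rois[1:3]
    df$theta_beta_mi[shift] <- df$theta_beta_mi[shift] + 1  # d = 1, half the ROIs
    res <- rm_anova(df)
    if (res$p[res$effect == "ROI:Group"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits / runs, 0.8)
})

test_that("Greenhouse-Geisser correction is exact-null at two within levels", {
  # with k = 2 repeated measures sphericity holds trivially and epsilon = 1,
  # so corrected and uncorrected analyses must agree
  plain <- rm_anova(anova_mini_data(), n_family = 1)
  gg <- rm_anova(anova_mini_data(), n_family = 1, gg_correction = TRUE)
  expect_equal(gg$p, plain$p, tolerance = 1e-10)
  expect_equal(gg$F, plain$F, tolerance = 1e-12)
})

test_that("bootstrap_posthoc is seed-reproducible and finds a planted shift", {
  set.seed(32)
  rois <- paste0("R", 1:5)
  df <- expand.grid(subject_id = sprintf("s%02d", 1:30), roi = rois,
                    stringsAsFactors = FALSE)
  df$group <- ifelse(as.integer(sub("s", "", df$subject_id)) <= 15, "BT", "HC")
  df$theta_beta_mi <- rnorm(nrow(df))
  pick <- df$roi == "R2" & df$group == "BT"
  df$theta_beta_mi[pick] <- df$theta_beta_mi[pick] + 2  # d = 2
  r1 <- bootstrap_posthoc(df, n_boot = 1000, seed = 7)
  r2 <- bootstrap_posthoc(df, n_boot = 1000, seed = 7)
  expect_identical(r1, r2)
  expect_lt(r1$q[r1$roi == "R2"], 0.05)
  expect_true(all(r1$q >= r1$p - 1e-12))
  expect_equal(r1$n_boot[1], 1000)
  expect_error(bootstrap_posthoc(df, n_boot = 50), "below 100")
})

test_that("fdr_bh equals the exhaustive step-up oracle", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.37), 0.37)
  expect_equal(fdr_bh(rep(1, 6)), rep(1, 6))
  set.seed(33)
  for (i in 1:50) {
    p <- runif(sample(1:12, 1))
    expect_equal(fdr_bh(p), brute_bh(p), tolerance = 1e-12)
  }
  expect_error(fdr_bh(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("pac_thi_correlation recovers exact linear relations and rejects tiny n", {
  thi <- c(s1 = 10, s2 = 20, s3 = 30, s4 = 40, s5 = 50)
  pac <- data.frame(subject_id = names(thi), roi = "HES.L",
                    theta_beta_mi = 0.5 - 0.002 * thi,
                    theta_gamma_mi = 0.1 + 0.003 * thi)
  res <- pac_thi_correlation(pac, thi)
  expect_equal(res$r[res$band == "theta_beta_mi"], -1, tolerance = 1e-12)
  expect_equal(res$r[res$band == "theta_gamma_mi"], 1, tolerance = 1e-12)
  expect_equal(res$n, c(5, 5))
  # rank-based option is invariant to monotone transforms of the score
  rs <- pac_thi_correlation(pac, thi^2, bands = "theta_beta_mi",
                            method = "spearman")
  expect_equal(rs$r, -1)
  expect_error(pac_thi_correlation(pac[1:3, ], thi[1:3]), "n >= 4")
})

test_that("pac_thi_correlation is calibrated under independence", {
  set.seed(34)
  ps <- replicate(100, {
    thi <- stats::setNames(runif(27, 0, 100), sprintf("s%02d", 1:27))
    pac <- data.frame(subject_id = names(thi), roi = "X",
                      theta_beta_mi = rnorm(27), theta_gamma_mi = rnorm(27))
    pac_thi_correlation(pac, thi, bands = "theta_beta_mi")$p
  })
  expect_gte(mean(ps < 0.05), 0.0)
  expect_lte(mean(ps < 0.05), 0.12)
})
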