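# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths.

# Quadrature oracle for the 18-bin KL modulation index of the analytic
# amplitude profile A(phi) = 1 + m*cos(phi) under uniform phase: per-bin
# mean amplitude by exact integration, then the entropy formula.
quad_mi_oracle <- function(m, n_bins = 18L) {
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  binmean <- vapply(seq_len(n_bins), function(j) {
    w <- edges[j + 1] - edges[j]
    # integral of 1 + m cos over the bin, divided by bin width
    (w + m * (sin(edges[j + 1]) - sin(edges[j]))) / w
  }, numeric(1))
  P <- binmean / sum(binmean)
  (log(n_bins) + sum(P * log(P))) / log(n_bins)
}

# Exhaustive Benjamini-Hochberg step-up: q_i = min_{j >= rank_i} p_(j)*m/j.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(ps[i:m] * m / (i:m), 1)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Spearman rho by explicit rank computation.
spearman_brute <- function(a, b) {
  ra <- rank(a)
  rb <- rank(b)
  1 - 6 * sum((ra - rb)^2) / (length(a) * (length(a)^2 - 1))
}

# Hand-computed mixed-design (2 groups x 2 ROIs, 2 subjects each) ANOVA.
# Data: subjects A,B in g1 with (r1, r2) = (1,2), (2,3); C,D in g2 with
# (4,6), (5,6). Worked sums of squares:
#   SS_group = 21.125 (df 1), SS_subj(group) = 1.25 (df 2) -> F_group = 33.8
#   SS_roi = 3.125 (df 1), SS_int = 0.125 (df 1),
#   SS_err_within = 0.25 (df 2)  -> F_roi = 25, F_interaction = 1
anova_mini_data <- function() {
  data.frame(
    subject_id = rep(c("A", "B", "C", "D"), each = 2),
    group = rep(c("g1", "g1", "g2", "g2"), each = 2),
    roi = rep(c("r1", "r2"), 4),
    theta_beta_mi = c(1, 2, 2, 3, 4, 6, 5, 6))
}
anova_mini_expected <- c(Group = 33.8, ROI = 25, `ROI:Group` = 1)

# A minimal cohort / roi-series fixture built in code.
make_roi_series <- function(signals, fs = 500, epoch_len_s = 2,
                            labels = paste0("R", seq_along(signals))) {
  roi_series_from_matrix(do.call(rbind, signals), fs, labels, epoch_len_s)
}
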