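## Inferential layer: normality screening, mixed-design ROI x Group ANOVA,
## bootstrap post-hoc with FDR, and PAC-THI correlation.

#' Shapiro-Wilk normality screen
#'
#' @param values Numeric vector, 3 <= n <= 5000, non-constant.
#' @return List with `W`, `p`, and `normal` (routing flag at p = 0.05).
#' @export
normality_screen <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000) stop_tinnpac("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(values) == 0) stop_tinnpac("constant vector: normality undefined")
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value, normal = sw$p.value > 0.05)
}

#' Mixed-design ROI x Group repeated-measures ANOVA
#'
#' ROI is the within-subject factor, Group the between-subjects factor.
#' Classical mixed-model sums of squares via `aov` with an
#' `Error(subject/roi)` stratum structure. Requires a balanced ROI set
#' across subjects and exactly two groups (group pairs are compared one at
#' a time, as in pairwise patient-vs-control contrasts). A
#' Bonferroni-adjusted p for the interaction is reported for a family of
#' `n_family` comparisons.
#'
#' @param pac A `pac_table` (see [pac_pipeline()]) restricted to two
#'   groups.
#' @param value_col Which PAC column to analyse (`"theta_beta_mi"` or
#'   `"theta_gamma_mi"`).
#' @param n_family Size of the Bonferroni family (default 4: two bands x
#'   two group pairs).
#' @param gg_correction Apply the Greenhouse-Geisser sphericity correction
#'   to the within-subject effects (default `FALSE`: uncorrected df).
#' @return Data.frame with one row per effect (`Group`, `ROI`,
#'   `ROI:Group`): `F`, `df_num`, `df_den`, `p`, `p_bonferroni`.
#' @export
rm_anova <- function(pac, value_col = "theta_beta_mi", n_family = 4,
                     gg_correction = FALSE) {
  df <- data.frame(subject = factor(pac$subject_id),
                   group = factor(pac$group),
                   roi = factor(pac$roi),
                   value = pac[[value_col]])
  if (nlevels(df$group) != 2) stop_tinnpac("rm_anova compares exactly two groups")
  counts <- table(df$subject, df$roi)
  if (any(counts != 1)) stop_tinnpac("unbalanced design: every subject needs every ROI exactly once")
  if (any(table(unique(df[c("subject", "group")])$group) < 2)) {
    stop_tinnpac("need >= 2 subjects per group")
  }
  if (stats::sd(df$value) == 0) {
    # zero-variance limit: every effect's SS is exactly 0
    return(data.frame(effect = c("Group", "ROI", "ROI:Group"), F = 0,
                      df_num = c(1, nlevels(df$roi) - 1, nlevels(df$roi) - 1),
                      df_den = NA_real_, p = 1, p_bonferroni = 1,
                      stringsAsFactors = FALSE))
  }
  fit <- stats::aov(value ~ group * roi + Error(subject / roi), data = df)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1]]
  within <- s[["Error: subject:roi"]][[1]]
  grab <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    resid <- nrow(tab)                  # residual row is last in each stratum
    data.frame(effect = term,
               F = tab[i, "F value"], df_num = tab[i, "Df"],
               df_den = tab[resid, "Df"], p = tab[i, "Pr(>F)"],
               stringsAsFactors = FALSE)
  }
  out <- rbind(grab(between, "group"), grab(within, "roi"),
               grab(within, "group:roi"))
  out$effect <- c("Group", "ROI", "ROI:Group")
  if (gg_correction) {
    eps <- gg_epsilon(df)
    within_rows <- out$effect %in% c("ROI", "ROI:Group")
    out$df_num[within_rows] <- out$df_num[within_rows] * eps
    out$df_den[within_rows] <- out$df_den[within_rows] * eps
    out$p[within_rows] <- stats::pf(out$F[within_rows],
                                    out$df_num[within_rows],
                                    out$df_den[within_rows],
                                    lower.tail = FALSE)
  }
  # an all-constant response yields NA F in aov; report F = 0 as the
  # zero-variance limit
  out$F[is.na(out$F)] <- 0
  out$p[is.na(out$p)] <- 1
  out$p_bonferroni <- pmin(1, out$p * n_family)
  rownames(out) <- NULL
  out
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# k repeated (ROI) measures, via the double-centred covariance matrix.
gg_epsilon <- function(df) {
  wide <- stats::reshape(df[c("subject", "roi", "value")], idvar = "subject",
                         timevar = "roi", direction = "wide")
  m <- as.matrix(wide[, -1, drop = FALSE])
  groups <- df$group[match(wide$subject, df$subject)]
  centred <- do.call(rbind, lapply(split(as.data.frame(m), groups), scale,
                                   scale = FALSE))
  S <- stats::cov(centred)
  k <- ncol(S)
  C <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  sum(diag(C))^2 / ((k - 1) * sum(C^2))
}

#' Bootstrap post-hoc group comparison per ROI with BH-FDR
#'
#' For every ROI, the observed group mean difference is compared against a
#' bootstrap null: subjects are resampled with replacement within group
#' (`n_boot` times), and the resampled differences are centred on the
#' observed difference (shift method) to form the null; the two-sided p is
#' the fraction of null draws at least as extreme as the observation.
#' Benjamini-Hochberg correction is applied across the ROI list.
#'
#' @param pac A `pac_table` restricted to two groups.
#' @param value_col PAC column to compare.
#' @param n_boot Bootstrap resamples (>= 100; default 1000).
#' @param seed Integer seed (recorded in the output).
#' @param min_per_group Minimum subjects per group (default 5).
#' @return Data.frame per ROI: `roi`, `group_pair`, `diff`, `p`, `q`,
#'   `n_boot`, `seed`.
#' @export
bootstrap_posthoc <- function(pac, value_col = "theta_beta_mi", n_boot = 1000,
                              seed = 1, min_per_group = 5) {
  if (n_boot < 100) stop_tinnpac("n_boot below 100 is rejected")
  groups <- sort(unique(pac$group))
  if (length(groups) != 2) stop_tinnpac("bootstrap_posthoc compares exactly two groups")
  rois <- unique(pac$roi)
  res <- with_seed(seed, {
    lapply(rois, function(r) {
      sub <- pac[pac$roi == r, ]
      x <- sub[[value_col]][sub$group == groups[1]]
      y <- sub[[value_col]][sub$group == groups[2]]
      if (length(x) < min_per_group || length(y) < min_per_group) {
        stop_tinnpac("need >= ", min_per_group, " subjects per group per ROI")
      }
      obs <- mean(x) - mean(y)
      bx <- matrix(sample(x, length(x) * n_boot, replace = TRUE), ncol = n_boot)
      by <- matrix(sample(y, length(y) * n_boot, replace = TRUE), ncol = n_boot)
      dstar <- colMeans(bx) - colMeans(by)
      null <- dstar - obs
      p <- (1 + sum(abs(null) >= abs(obs))) / (n_boot + 1)
      data.frame(roi = r, group_pair = paste(groups, collapse = "-"),
                 diff = obs, p = p, stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, res)
  out$q <- fdr_bh(out$p)
  out$n_boot <- n_boot
  out$seed <- seed
  out
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up BH adjusted p-values (q-values): monotone, `q >= p`, capped at
#' 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
fdr_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_tinnpac("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' PAC-THI correlation per ROI and band
#'
#' Pearson correlation (the standardized linear-regression slope) between
#' per-subject PAC and THI severity scores, per ROI and band, with
#' two-sided p-values. Intended for within-patient-group analyses (HC
#' subjects have no THI score).
#'
#' @param pac A `pac_table` for the subjects of interest.
#' @param thi Named numeric vector of THI scores (names = subject ids), or
#'   unnamed in `pac` subject order within each ROI.
#' @param bands Which PAC columns to correlate.
#' @param method `"pearson"` (the regression-based default) or
#'   `"spearman"`.
#' @return Data.frame: `roi`, `band`, `r`, `p`, `n`.
#' @export
pac_thi_correlation <- function(pac, thi,
                                bands = c("theta_beta_mi", "theta_gamma_mi"),
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  rois <- unique(pac$roi)
  rows <- list()
  for (r in rois) {
    sub <- pac[pac$roi == r, ]
    scores <- if (!is.null(names(thi))) thi[sub$subject_id] else thi
    ok <- is.finite(scores)
    for (b in bands) {
      v <- sub[[b]][ok]; s <- scores[ok]
      if (length(v) < 4) stop_tinnpac("need n >= 4 subjects with THI scores")
      if (stats::sd(v) == 0 || stats::sd(s) == 0) {
        stop_tinnpac("constant vector: correlation undefined (ROI ", r, ")")
      }
      ct <- suppressWarnings(stats::cor.test(v, s, method = method))
      rows[[length(rows) + 1L]] <-
        data.frame(roi = r, band = b, r = unname(ct$estimate), p = ct$p.value,
                   n = length(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
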