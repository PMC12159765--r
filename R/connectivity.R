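## Frequency-domain functional connectivity between ROIs: coherence, PLV,
## PLI and wPLI from epoch-wise cross-spectra, plus FDR-corrected group
## contrasts over edges.

#' Epoch-wise cross-spectra of ROI time series
#'
#' Hann-windowed FFT of every ROI per epoch, restricted to the in-band
#' frequency bins; the per-epoch Fourier coefficients are retained so the
#' epoch-wise synchronization estimators can be formed.
#'
#' @param roi A `roi_series`.
#' @param band Numeric `c(lo, hi)` in Hz.
#' @return A `cross_spectra`: complex array `epochs x rois x freqs`, with
#'   `freqs` and `roi_labels`.
#' @export
cross_spectra <- function(roi, band) {
  stopifnot(inherits(roi, "roi_series"))
  d <- dim(roi$data)
  if (d[1] < 2) stop_tinnpac("need at least 2 epochs")
  if (band[2] >= roi$fs / 2) stop_tinnpac("band extends beyond Nyquist")
  n <- d[3]
  freqs_all <- (seq_len(floor(n / 2) + 1) - 1) * roi$fs / n
  sel <- which(freqs_all >= band[1] & freqs_all <= band[2])
  if (!length(sel)) stop_tinnpac("no frequency bins inside the band")
  w <- hann_window(n)
  coef <- array(0i, dim = c(d[1], d[2], length(sel)))
  for (e in seq_len(d[1])) {
    for (r in seq_len(d[2])) {
      coef[e, r, ] <- stats::fft(roi$data[e, r, ] * w)[sel]
    }
  }
  structure(list(coef = coef, freqs = freqs_all[sel],
                 roi_labels = roi$roi_labels, band = band),
            class = "cross_spectra")
}

# Shared engine: builds one ROI x ROI matrix for a metric, averaging over
# in-band frequencies. Expectations are means over epochs.
connectivity_engine <- function(cs, metric) {
  coef <- cs$coef
  n_roi <- dim(coef)[2]
  n_f <- dim(coef)[3]
  vals <- matrix(0, n_roi, n_roi, dimnames = list(cs$roi_labels, cs$roi_labels))
  for (a in seq_len(n_roi)) {
    for (b in seq_len(n_roi)) {
      if (b < a) next
      acc <- numeric(n_f)
      for (f in seq_len(n_f)) {
        Sxy <- coef[, a, f] * Conj(coef[, b, f])
        acc[f] <- switch(metric,
          coherence = {
            Mod(mean(Sxy))^2 /
              (mean(Mod(coef[, a, f])^2) * mean(Mod(coef[, b, f])^2))
          },
          plv = Mod(mean(exp(1i * Arg(Sxy)))),
          pli = abs(mean(sign(Im(Sxy)))),
          wpli = {
            den <- mean(abs(Im(Sxy)))
            if (den == 0) 0 else abs(mean(Im(Sxy))) / den
          })
      }
      vals[a, b] <- vals[b, a] <- mean(acc)
    }
  }
  if (metric %in% c("pli", "wpli")) diag(vals) <- 0
  structure(list(metric = metric, band = cs$band, values = vals,
                 roi_labels = cs$roi_labels),
            class = "connectivity_matrix")
}

#' Connectivity matrices from cross-spectra
#'
#' Standard epoch-wise estimators over the in-band frequencies (band value
#' is the unweighted mean over bins), with expectations taken over epochs:
#' \itemize{
#'   \item coherence \eqn{|E S_{xy}|^2 / (E S_{xx} \cdot E S_{yy})}
#'   \item PLV \eqn{|E e^{i \arg S_{xy}}|}
#'   \item PLI \eqn{|E\, \mathrm{sign}(\Im S_{xy})|}
#'   \item wPLI \eqn{|E \Im S_{xy}| / E |\Im S_{xy}|} (0 when the
#'     denominator vanishes, e.g. exactly zero-lag signals)
#' }
#' All values lie in `[0, 1]` and are invariant to per-channel amplitude
#' rescaling; PLI and wPLI additionally discount zero-lag (volume
#' conduction) coupling.
#'
#' @param cs A [cross_spectra()].
#' @param metric One of `"coherence"`, `"plv"`, `"pli"`, `"wpli"`.
#' @return A `connectivity_matrix`: symmetric ROI x ROI `values` plus
#'   metadata.
#' @export
connectivity <- function(cs, metric = c("wpli", "coherence", "plv", "pli")) {
  stopifnot(inherits(cs, "cross_spectra"))
  metric <- match.arg(metric)
  connectivity_engine(cs, metric)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("<connectivity_matrix> %s, band %g-%g Hz, %d ROIs, mean edge %.3f\n",
              x$metric, x$band[1], x$band[2], length(x$roi_labels), mean(off)))
  invisible(x)
}

# Upper-triangle edge vector of a connectivity matrix, stably named.
edge_vector <- function(cm) {
  v <- cm$values
  ut <- which(upper.tri(v), arr.ind = TRUE)
  stats::setNames(v[ut],
                  paste(rownames(v)[ut[, 1]], colnames(v)[ut[, 2]], sep = "--"))
}

#' Edge-wise group contrast with FDR correction
#'
#' Two-sided Welch t-test per edge between two groups of subjects, with
#' Benjamini-Hochberg correction across all edges. Correlation-like metrics
#' (coherence, PLV) are Fisher-z transformed before testing for variance
#' stabilization; PLI/wPLI are tested on the raw scale.
#'
#' @param matrices List of `connectivity_matrix`, one per subject.
#' @param groups Character/factor vector of group labels (exactly 2 levels,
#'   >= 2 subjects each).
#' @param alpha FDR level used for the `significant` flag (default 0.05).
#' @return Data.frame with `edge`, `diff` (group1 - group2 mean), `p`, `q`,
#'   `significant`.
#' @export
group_contrast_fdr <- function(matrices, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop_tinnpac("exactly two groups required")
  if (any(table(groups) < 2)) stop_tinnpac("need >= 2 subjects per group")
  metric <- matrices[[1]]$metric
  edges <- t(vapply(matrices, edge_vector,
                    numeric(sum(upper.tri(matrices[[1]]$values)))))
  if (metric %in% c("coherence", "plv")) {
    edges <- atanh(pmin(pmax(edges, -0.999999), 0.999999))
  }
  g1 <- levels(groups)[1]
  res <- apply(edges, 2, function(v) {
    a <- v[groups == g1]; b <- v[groups != g1]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      c(diff = mean(a) - mean(b), p = 1)
    } else {
      tt <- stats::t.test(a, b)
      c(diff = mean(a) - mean(b), p = tt$p.value)
    }
  })
  p <- res["p", ]
  data.frame(edge = colnames(edges), diff = res["diff", ], p = p,
             q = fdr_bh(p), significant = fdr_bh(p) < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}
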