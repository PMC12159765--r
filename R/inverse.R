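## Minimum-norm source inversion and AAL ROI aggregation.

#' The 26-ROI AAL registry
#'
#' The bilateral region set analysed at the source level: Heschl gyrus
#' (HES), superior/middle/inferior temporal gyrus (STG/MTG/ITG),
#' superior/middle/inferior orbitofrontal cortex (ORBsup/ORBmid/ORBinf),
#' anterior/dorsal/posterior cingulate gyrus (ACG/DCG/PCG), hippocampus
#' (HIP), parahippocampal gyrus (PHG), and insula (INS) — 13 bilateral
#' pairs, 26 labels.
#'
#' @return A data.frame with columns `label` (e.g. `"HES.L"`), `region`,
#'   `aal_name`, `hemisphere`.
#' @export
roi_registry <- function() {
  regions <- c(HES = "Heschl", STG = "Temporal_Sup", MTG = "Temporal_Mid",
               ITG = "Temporal_Inf", ORBsup = "Frontal_Sup_Orb",
               ORBmid = "Frontal_Mid_Orb", ORBinf = "Frontal_Inf_Orb",
               ACG = "Cingulum_Ant", DCG = "Cingulum_Mid",
               PCG = "Cingulum_Post", HIP = "Hippocampus",
               PHG = "ParaHippocampal", INS = "Insula")
  hemi <- c(L = "L", R = "R")
  grid <- expand.grid(hemisphere = names(hemi), region = names(regions),
                      stringsAsFactors = FALSE)[, 2:1]
  data.frame(label = paste(grid$region, grid$hemisphere, sep = "."),
             region = grid$region,
             aal_name = paste(regions[grid$region], grid$hemisphere, sep = "_"),
             hemisphere = grid$hemisphere,
             stringsAsFactors = FALSE)
}

#' Default minimum-norm regularization
#'
#' SNR-based rule \eqn{\lambda = \mathrm{tr}(LL^T) / (n_{sensors} \cdot SNR^2)},
#' the standard practice for scaling the regularizer to the leadfield's
#' power when no noise covariance is available.
#'
#' @param leadfield A `leadfield`.
#' @param snr Assumed amplitude SNR (default 3).
#' @return Scalar lambda.
#' @export
default_lambda <- function(leadfield, snr = 3) {
  L <- leadfield$gain
  sum(L * L) / (nrow(L) * snr^2)
}

#' Minimum-norm estimate (MNE) inverse solution
#'
#' Projects sensor epochs to source space with the L2-regularized linear
#' inverse \eqn{\hat S = L^T (L L^T + \lambda I)^{-1} X}. For a square
#' invertible leadfield and \eqn{\lambda \to 0} this reproduces
#' \eqn{L^{-1} X} exactly.
#'
#' @param ep An [epoched_data()] of sensor signals.
#' @param leadfield A `leadfield` whose row count matches the sensor count.
#' @param lambda Regularization parameter (>= 0); default from
#'   [default_lambda()].
#' @return An [epoched_data()] of source signals (`epochs x sources x
#'   samples`).
#' @export
mne_inverse <- function(ep, leadfield, lambda = default_lambda(leadfield)) {
  stopifnot(inherits(ep, "epoched_data"))
  L <- leadfield$gain
  d <- dim(ep$data)
  if (d[2] != nrow(L)) {
    stop_tinnpac("sensor count (", d[2], ") does not match leadfield rows (",
                 nrow(L), ")")
  }
  if (lambda < 0) stop_tinnpac("lambda must be non-negative")
  G <- tcrossprod(L) + lambda * diag(nrow(L))
  Ginv <- tryCatch(solve(G), error = function(e) {
    stop_tinnpac("(L L^T + lambda I) is singular; use lambda > 0")
  })
  K <- crossprod(L, Ginv)                 # sources x sensors
  out <- array(0, dim = c(d[1], ncol(L), d[3]))
  for (e in seq_len(d[1])) {
    out[e, , ] <- K %*% ep$data[e, , ]
  }
  epoched_data(out, fs = ep$fs, epoch_len_s = ep$epoch_len_s,
               kept_mask = ep$kept_mask,
               channel_labels = sprintf("SRC%03d", seq_len(ncol(L))))
}

#' Remove per-epoch mean and linear trend
#'
#' Epoch-wise noise regression in the time dimension: each channel of each
#' epoch has its mean and least-squares linear trend removed. Idempotent.
#' Accepts sensor/source [epoched_data()] or a `roi_series`.
#'
#' @param ep An [epoched_data()] or `roi_series`.
#' @return The detrended object, same class as the input.
#' @export
detrend_noise <- function(ep) {
  stopifnot(inherits(ep, "epoched_data") || inherits(ep, "roi_series"))
  d <- dim(ep$data)
  if (d[3] < 2) stop_tinnpac("need at least 2 samples per epoch")
  t <- seq_len(d[3])
  tc <- t - mean(t)
  denom <- sum(tc^2)
  for (e in seq_len(d[1])) {
    x <- ep$data[e, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, 1, d[3])
    slope <- (x %*% tc) / denom
    ep$data[e, , ] <- x - rowMeans(x) - slope %*% tc
  }
  ep
}

#' Aggregate source epochs into ROI time series
#'
#' ROI series are the signed mean over each ROI's sources, per epoch and
#' sample. Output ROI order follows the supplied registry labels.
#'
#' @param src Source-space [epoched_data()] (from [mne_inverse()]).
#' @param roi_map Character vector assigning each source to an ROI label.
#' @param roi_labels Ordered ROI labels to extract (default: all labels in
#'   `roi_map`, sorted).
#' @return A `roi_series`: list with `data` (`epochs x rois x samples`),
#'   `fs`, `epoch_len_s`, `roi_labels`.
#' @export
aggregate_rois <- function(src, roi_map, roi_labels = sort(unique(roi_map))) {
  stopifnot(inherits(src, "epoched_data"))
  d <- dim(src$data)
  if (length(roi_map) != d[2]) {
    stop_tinnpac("roi_map length must equal source count")
  }
  if (anyDuplicated(roi_labels)) stop_tinnpac("roi_labels must be unique")
  missing <- setdiff(roi_labels, roi_map)
  if (length(missing)) {
    stop_tinnpac("ROI(s) with zero sources: ", paste(missing, collapse = ", "))
  }
  out <- array(0, dim = c(d[1], length(roi_labels), d[3]))
  for (r in seq_along(roi_labels)) {
    idx <- which(roi_map == roi_labels[r])
    for (e in seq_len(d[1])) {
      block <- src$data[e, idx, , drop = FALSE]
      out[e, r, ] <- colMeans(matrix(block, length(idx), d[3]))
    }
  }
  structure(list(data = out, fs = src$fs, epoch_len_s = src$epoch_len_s,
                 roi_labels = roi_labels),
            class = "roi_series")
}

#' @export
print.roi_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<roi_series> %d epochs x %d ROIs x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' Build an roi_series directly from a continuous ROI matrix
#'
#' Convenience constructor for ground-truth series or externally computed
#' ROI signals: segments a `rois x samples` matrix into fixed-length
#' epochs.
#'
#' @param mat ROIs x samples matrix.
#' @param fs Sampling rate (Hz).
#' @param roi_labels Labels, one per row.
#' @param epoch_len_s Epoch length in seconds.
#' @return A `roi_series`.
#' @export
roi_series_from_matrix <- function(mat, fs, roi_labels, epoch_len_s = 2) {
  spe <- round(fs * epoch_len_s)
  n_ep <- floor(ncol(mat) / spe)
  out <- array(0, dim = c(n_ep, nrow(mat), spe))
  for (e in seq_len(n_ep)) {
    out[e, , ] <- mat[, (e - 1) * spe + seq_len(spe), drop = FALSE]
  }
  structure(list(data = out, fs = fs, epoch_len_s = epoch_len_s,
                 roi_labels = roi_labels),
            class = "roi_series")
}
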