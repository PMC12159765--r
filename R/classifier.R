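## BT-vs-NBT classification: feature assembly, Fisher-discriminant
## dimensionality reduction, and KNN with leave-one-out cross-validation.

#' Construct a feature table
#'
#' @param x Subjects x features numeric matrix with rownames (subject ids)
#'   and unique colnames.
#' @param label Class labels (`"BT"` / `"NBT"`), one per subject.
#' @param level `"sensor"` or `"source"` provenance tag.
#' @return A `feature_table`.
#' @export
feature_table <- function(x, label, level = "source") {
  x <- as.matrix(x)
  if (anyDuplicated(colnames(x))) stop_tinnpac("feature names must be unique")
  if (any(!is.finite(x))) stop_tinnpac("missing values in feature matrix")
  label <- factor(label)
  if (nlevels(label) != 2) stop_tinnpac("exactly two classes required")
  if (any(table(label) < 1)) stop_tinnpac("each class needs >= 1 subject")
  structure(list(x = x, label = label, subject_id = rownames(x),
                 level = level),
            class = "feature_table")
}

# pac_table -> wide subjects x (2 * n_roi) block
pac_feature_block <- function(pac) {
  subjects <- unique(pac$subject_id)
  rois <- unique(pac$roi)
  out <- matrix(NA_real_, length(subjects), 2 * length(rois),
                dimnames = list(subjects,
                                c(paste0("pac_tb_", rois), paste0("pac_tg_", rois))))
  for (i in seq_len(nrow(pac))) {
    s <- pac$subject_id[i]; r <- pac$roi[i]
    out[s, paste0("pac_tb_", r)] <- pac$theta_beta_mi[i]
    out[s, paste0("pac_tg_", r)] <- pac$theta_gamma_mi[i]
  }
  out
}

# named list(block -> list(subject_id -> connectivity_matrix)) -> matrix
conn_feature_block <- function(conn) {
  blocks <- lapply(names(conn), function(bn) {
    per_subj <- conn[[bn]]
    edges <- t(vapply(per_subj, edge_vector,
                      numeric(sum(upper.tri(per_subj[[1]]$values)))))
    colnames(edges) <- paste0("fc_", bn, "_", colnames(edges))
    rownames(edges) <- names(per_subj)
    edges
  })
  do.call(cbind, blocks)
}

#' Assemble classification features
#'
#' Combines PAC, functional-connectivity and band-power blocks into one
#' feature table for a chosen combination. All blocks must cover the same
#' subjects. Standardization is deliberately NOT applied here: z-scoring is
#' fit on training folds only, inside [knn_loocv()].
#'
#' @param labels Named character vector (subject id -> `"BT"`/`"NBT"`).
#' @param pac Optional `pac_table`.
#' @param conn Optional named list: block name -> list (subject id ->
#'   `connectivity_matrix`).
#' @param power Optional subjects x features matrix (rownames = ids).
#' @param combo One of `"PAC"`, `"FC"`, `"FC+power"`, `"FC+PAC"`, `"all"`.
#' @param level Provenance tag.
#' @return A [feature_table()].
#' @export
assemble_features <- function(labels, pac = NULL, conn = NULL, power = NULL,
                              combo = c("all", "PAC", "FC", "FC+power", "FC+PAC"),
                              level = "source") {
  combo <- match.arg(combo)
  want <- switch(combo,
                 "PAC" = "pac", "FC" = "fc",
                 "FC+power" = c("fc", "power"),
                 "FC+PAC" = c("fc", "pac"),
                 "all" = c("fc", "pac", "power"))
  blocks <- list()
  if ("fc" %in% want) {
    if (is.null(conn)) stop_tinnpac("combo ", combo, " needs connectivity input")
    blocks$fc <- conn_feature_block(conn)
  }
  if ("pac" %in% want) {
    if (is.null(pac)) stop_tinnpac("combo ", combo, " needs PAC input")
    blocks$pac <- pac_feature_block(pac)
  }
  if ("power" %in% want) {
    if (is.null(power)) stop_tinnpac("combo ", combo, " needs power input")
    blocks$power <- as.matrix(power)
  }
  subjects <- names(labels)
  for (bn in names(blocks)) {
    missing <- setdiff(subjects, rownames(blocks[[bn]]))
    if (length(missing)) {
      stop_tinnpac("subject(s) missing from ", bn, " block: ",
                   paste(missing, collapse = ", "))
    }
    blocks[[bn]] <- blocks[[bn]][subjects, , drop = FALSE]
  }
  x <- do.call(cbind, unname(blocks))
  feature_table(x, labels[subjects], level = level)
}

# Per-feature Fisher discriminant ratio (m1 - m2)^2 / (v1 + v2).
fisher_scores <- function(x, y) {
  cl <- levels(y)
  a <- x[y == cl[1], , drop = FALSE]
  b <- x[y == cl[2], , drop = FALSE]
  num <- (colMeans(a) - colMeans(b))^2
  den <- apply(a, 2, stats::var) + apply(b, 2, stats::var)
  num / pmax(den, 1e-12)
}

# Fit a reducer on training data only. method "score": keep the top-m
# features by Fisher score. method "projection": the canonical Fisher
# direction w = (Sw + eps I)^{-1} (m1 - m2) (ridge-regularized when the
# within-class scatter is singular).
fit_reducer <- function(x, y, method = c("score", "projection", "none"),
                        m = 10) {
  method <- match.arg(method)
  if (method == "none") {
    return(list(project = function(z) z, method = "none"))
  }
  if (method == "score") {
    keep <- order(fisher_scores(x, y), decreasing = TRUE)[seq_len(min(m, ncol(x)))]
    return(list(project = function(z) z[, keep, drop = FALSE],
                method = "score", keep = keep))
  }
  cl <- levels(y)
  a <- x[y == cl[1], , drop = FALSE]
  b <- x[y == cl[2], , drop = FALSE]
  Sw <- (crossprod(scale(a, scale = FALSE)) + crossprod(scale(b, scale = FALSE)))
  eps <- 1e-8 * mean(diag(Sw)) + 1e-12
  w <- solve(Sw + eps * diag(ncol(x)), colMeans(a) - colMeans(b))
  w <- w / sqrt(sum(w^2))
  list(project = function(z) z %*% w, method = "projection", w = w)
}

#' Fisher-discriminant dimensionality reduction
#'
#' Two interchangeable readings of Fisher-discriminant reduction: the
#' canonical projection (one component for two classes, ridge-regularized
#' within-class scatter) or Fisher-score feature selection (top-`m`
#' features by per-feature discriminant ratio; the default, `m = 10`).
#'
#' @param ft A [feature_table()].
#' @param method `"score"` (default), `"projection"`, or `"none"`.
#' @param m Number of features kept by the score method.
#' @return A reduced [feature_table()]; for `"projection"` the fitted
#'   direction is attached as attribute `"w"`.
#' @export
fisher_reduce <- function(ft, method = c("score", "projection", "none"), m = 10) {
  method <- match.arg(method)
  red <- fit_reducer(ft$x, ft$label, method, m)
  out <- feature_table(structure(red$project(ft$x),
                                 dimnames = list(ft$subject_id, NULL)),
                       ft$label, level = ft$level)
  if (method == "projection") attr(out, "w") <- red$w
  out
}

#' KNN classification with leave-one-out cross-validation
#'
#' Each subject is classified by the majority vote of its `k` nearest
#' training subjects (Euclidean distance). Per-feature z-scoring and the
#' Fisher reduction are refit inside every fold, never touching the
#' held-out subject. Sensitivity is the recall of the positive class
#' (`"BT"` by default), specificity the recall of the other class.
#'
#' @param ft A [feature_table()].
#' @param k Number of neighbours (odd; default 5).
#' @param reduce Reduction method passed to the per-fold reducer.
#' @param m Top-m features for the score method.
#' @param positive Positive class label (default `"BT"`).
#' @param feature_set Name recorded in the report.
#' @param seed Integer seed (covers KNN distance-tie randomization, so
#'   reports are reproducible).
#' @return A `cv_report`: list with `feature_set`, `accuracy`,
#'   `sensitivity`, `specificity`, `confusion`, `k`, `m`, `seed`,
#'   `predicted`.
#' @export
knn_loocv <- function(ft, k = 5, reduce = c("score", "projection", "none"),
                      m = 10, positive = "BT", feature_set = "features",
                      seed = 1) {
  stopifnot(inherits(ft, "feature_table"))
  reduce <- match.arg(reduce)
  n <- nrow(ft$x)
  if (k >= n) stop_tinnpac("k must be below the subject count")
  if (k %% 2 == 0) stop_tinnpac("use odd k to avoid vote ties")
  pred <- factor(rep(NA_character_, n), levels = levels(ft$label))
  for (i in seq_len(n)) {
    xtr <- ft$x[-i, , drop = FALSE]
    ytr <- ft$label[-i]
    mu <- colMeans(xtr)
    sdv <- apply(xtr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    ztr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
    zte <- (ft$x[i, ] - mu) / sdv
    red <- fit_reducer(ztr, ytr, reduce, m)
    pred[i] <- with_seed(derive_seed(seed, "fold", i),
                         class::knn(red$project(ztr),
                                    red$project(matrix(zte, 1)), ytr, k = k))
  }
  confusion <- table(truth = ft$label, predicted = pred)
  neg <- setdiff(levels(ft$label), positive)
  acc <- mean(pred == ft$label)
  sens <- mean(pred[ft$label == positive] == positive)
  spec <- mean(pred[ft$label == neg] == neg)
  structure(list(feature_set = feature_set, accuracy = acc,
                 sensitivity = sens, specificity = spec,
                 confusion = confusion, k = k, m = m, seed = seed,
                 n = n, predicted = pred),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: accuracy %.3f, sensitivity %.3f, specificity %.3f (n=%d, k=%d)\n",
              x$feature_set, x$accuracy, x$sensitivity, x$specificity, x$n, x$k))
  invisible(x)
}

#' Compare feature combinations under identical folds
#'
#' Runs [knn_loocv()] on each supplied feature table (leave-one-out folds
#' are identical across combos by construction) and orders the reports by
#' accuracy.
#'
#' @param ft_list Named list of [feature_table()] objects.
#' @param ... Passed to [knn_loocv()].
#' @return Data.frame ordered by decreasing accuracy: `feature_set`,
#'   `accuracy`, `sensitivity`, `specificity`.
#' @export
feature_ablation <- function(ft_list, ...) {
  if (length(ft_list) < 1) stop_tinnpac("need at least one feature set")
  reports <- lapply(names(ft_list), function(nm) {
    knn_loocv(ft_list[[nm]], feature_set = nm, ...)
  })
  out <- data.frame(
    feature_set = vapply(reports, `[[`, character(1), "feature_set"),
    accuracy = vapply(reports, `[[`, numeric(1), "accuracy"),
    sensitivity = vapply(reports, `[[`, numeric(1), "sensitivity"),
    specificity = vapply(reports, `[[`, numeric(1), "specificity"),
    stringsAsFactors = FALSE)
  out[order(-out$accuracy), , drop = FALSE]
}
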