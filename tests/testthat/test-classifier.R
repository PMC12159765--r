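mk_pac_table <- function(n_sub, rois, seed = 1, shift_fun = NULL) {
  set.seed(seed)
  subjects <- sprintf("s%02d", seq_len(n_sub))
  groups <- rep(c("BT", "NBT"), length.out = n_sub)
  df <- expand.grid(subject_id = subjects, roi = rois, stringsAsFactors = FALSE)
  df$group <- groups[match(df$subject_id, subjects)]
  df$theta_beta_mi <- abs(rnorm(nrow(df), 0.1, 0.02))
  df$theta_gamma_mi <- abs(rnorm(nrow(df), 0.1, 0.02))
  if (!is.null(shift_fun)) df <- shift_fun(df)
  df
}

mk_conn <- function(subjects, labels, seed = 1) {
  set.seed(seed)
  lapply(stats::setNames(subjects, subjects), function(s) {
    v <- matrix(0, length(labels), length(labels),
                dimnames = list(labels, labels))
    v[upper.tri(v)] <- runif(sum(upper.tri(v)), 0.2, 0.4)
    v <- v + t(v)
    structure(list(metric = "wpli", band = c(4, 8), values = v,
                   roi_labels = labels), class = "connectivity_matrix")
  })
}

test_that("assemble_features produces the documented block shapes", {
  rois <- roi_registry()$label            # 26 ROIs
  pac <- mk_pac_table(10, rois)
  subjects <- unique(pac$subject_id)
  labels <- stats::setNames(pac$group[match(subjects, pac$subject_id)], subjects)
  ft <- assemble_features(labels, pac = pac, combo = "PAC")
  expect_equal(ncol(ft$x), 52)            # 26 ROIs x 2 bands
  conn <- list(theta = mk_conn(subjects, rois))
  ft2 <- assemble_features(labels, conn = conn, combo = "FC")
  expect_equal(ncol(ft2$x), 325)          # 26 * 25 / 2 edges
  ft3 <- assemble_features(labels, pac = pac, conn = conn, combo = "FC+PAC")
  expect_equal(ncol(ft3$x), 377)
  # subject missing from one block is named in the error
  conn_short <- list(theta = mk_conn(subjects[-3], rois))
  expect_error(assemble_features(labels, conn = conn_short, combo = "FC"),
               subjects[3])
  expect_error(assemble_features(labels, conn = conn, combo = "PAC"),
               "needs PAC")
})

test_that("fisher projection recovers the separating axis of constructed clouds", {
  set.seed(40)
  n <- 40
  x <- cbind(sep = c(rnorm(n / 2, -3, 0.5), rnorm(n / 2, 3, 0.5)),
             matrix(rnorm(n * 4), n, 4))
  colnames(x) <- paste0("f", 1:5)
  rownames(x) <- sprintf("s%02d", 1:n)
  y <- rep(c("BT", "NBT"), each = n / 2)
  ft <- feature_table(x, y)
  red <- fisher_reduce(ft, method = "projection")
  w <- attr(red, "w")
  angle <- acos(abs(w[1]) / sqrt(sum(w^2))) * 180 / pi
  expect_lt(angle, 5)
  # score method ranks the separating feature (column 1) first
  scores <- tinnpac:::fisher_scores(ft$x, ft$label)
  expect_identical(unname(which.max(scores)), 1L)
  # pass-through
  red0 <- fisher_reduce(ft, method = "none")
  expect_equal(unname(red0$x), unname(ft$x))
})

test_that("knn_loocv achieves perfect accuracy on well-separated clusters", {
  set.seed(41)
  n <- 40
  x <- rbind(matrix(rnorm(n / 2 * 3, 0, 1), ncol = 3),
             matrix(rnorm(n / 2 * 3, 6, 1), ncol = 3))  # 6 sigma apart
  rownames(x) <- sprintf("s%02d", 1:n)
  colnames(x) <- paste0("f", 1:3)
  ft <- feature_table(x, rep(c("NBT", "BT"), each = n / 2))
  rep_ <- knn_loocv(ft, k = 5, reduce = "none")
  expect_equal(rep_$accuracy, 1.0)
  expect_equal(rep_$sensitivity, 1.0)
  expect_equal(rep_$specificity, 1.0)
  expect_equal(sum(rep_$confusion), n)
  expect_error(knn_loocv(ft, k = n), "below the subject count")
  expect_error(knn_loocv(ft, k = 4), "odd k")
})

test_that("knn_loocv is deterministic and leak-free across folds", {
  set.seed(42)
  x <- matrix(rnorm(30 * 6), 30, 6,
              dimnames = list(sprintf("s%02d", 1:30), paste0("f", 1:6)))
  ft <- feature_table(x, rep(c("BT", "NBT"), 15))
  r1 <- knn_loocv(ft, k = 3, m = 3, seed = 5)
  r2 <- knn_loocv(ft, k = 3, m = 3, seed = 5)
  expect_identical(r1$predicted, r2$predicted)
  # no leakage: a subject's own label never reaches its own fold, so
  # flipping it cannot change that subject's prediction
  flipped <- as.character(ft$label)
  flipped[7] <- setdiff(c("BT", "NBT"), flipped[7])
  r3 <- knn_loocv(feature_table(x, flipped), k = 3, m = 3, seed = 5)
  expect_identical(as.character(r1$predicted[7]), as.character(r3$predicted[7]))
})

test_that("feature combinations with the planted signal outrank pure noise blocks", {
  rois <- paste0("R", 1:8)
  shift <- function(df) {
    sel <- df$group == "BT"
    df$theta_gamma_mi[sel] <- df$theta_gamma_mi[sel] + 0.08
    df
  }
  pac <- mk_pac_table(24, rois, seed = 43, shift_fun = shift)
  subjects <- unique(pac$subject_id)
  labels <- stats::setNames(pac$group[match(subjects, pac$subject_id)], subjects)
  conn <- list(theta = mk_conn(subjects, rois, seed = 44))  # pure noise FC
  fts <- list(
    FC = assemble_features(labels, conn = conn, combo = "FC"),
    `FC+PAC` = assemble_features(labels, pac = pac, conn = conn, combo = "FC+PAC"))
  res <- feature_ablation(fts, k = 5, m = 10, seed = 3)
  expect_equal(res$feature_set[1], "FC+PAC")
  expect_gt(res$accuracy[res$feature_set == "FC+PAC"],
            res$accuracy[res$feature_set == "FC"])
})
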