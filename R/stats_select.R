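check_groups <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values")
}

#' Two-sample pooled-variance t-test p-value
#'
#' Equal-variance two-sample t-test of a single feature between two groups;
#' returns the two-sided p-value.
#'
#' @param x,y numeric values of the feature in each group.
#' @return Two-sided p-value.
#' @export
pooled_ttest <- function(x, y) {
  check_groups(x, y)
  pooled <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  if (pooled <= 0) stop("degenerate pooled variance")
  t.test(x, y, var.equal = TRUE)$p.value
}

#' Bhattacharyya separability criterion
#'
#' Gaussian Bhattacharyya distance between the two group distributions,
#' computed from sample moments:
#' `(1/4) (mu_x - mu_y)^2 / (sx^2 + sy^2) + (1/2) log((sx^2 + sy^2) / (2 sx sy))`.
#' Zero for identical distributions; it bounds the minimum attainable
#' classification error (Chernoff bound).
#'
#' @param x,y numeric values of the feature in each group.
#' @return Non-negative criterion value.
#' @export
bhattacharyya_criterion <- function(x, y) {
  check_groups(x, y)
  vx <- var(x); vy <- var(y)
  if (vx <= 0 || vy <= 0) stop("zero variance in a group")
  (mean(x) - mean(y))^2 / (4 * (vx + vy)) + 0.5 * log((vx + vy) / (2 * sqrt(vx * vy)))
}

#' Symmetrized Kullback-Leibler (relative entropy) criterion
#'
#' Symmetrized Gaussian KL divergence `(KL(x||y) + KL(y||x)) / 2` from
#' sample moments.
#'
#' @param x,y numeric values of the feature in each group.
#' @return Non-negative criterion value.
#' @export
kl_criterion <- function(x, y) {
  check_groups(x, y)
  vx <- var(x); vy <- var(y)
  if (vx <= 0 || vy <= 0) stop("zero variance in a group")
  d2 <- (mean(x) - mean(y))^2
  0.5 * (vx / (2 * vy) + vy / (2 * vx) - 1 + d2 / 2 * (1 / vx + 1 / vy))
}

#' Rank features by a separability criterion
#'
#' Per-feature p-value (pooled t-test), Bhattacharyya criterion and
#' symmetrized relative entropy between the two classes, with a 1-based rank
#' by the requested criterion (descending for `C_B` and `D_KL`, ascending
#' for `p`); ties are broken by column order.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y two-level factor of class labels.
#' @param criterion `"C_B"`, `"D_KL"` or `"p"`.
#' @return Data frame `feature`, `p`, `C_B`, `D_KL`, `rank`, in column order.
#' @export
rank_features <- function(x, y, criterion = c("C_B", "D_KL", "p")) {
  criterion <- match.arg(criterion)
  y <- factor(y)
  if (nlevels(y) != 2L) stop("rank_features requires exactly two classes")
  if (min(table(y)) < 2L) stop("each class needs at least 2 samples")
  a <- x[y == levels(y)[1L], , drop = FALSE]
  b <- x[y == levels(y)[2L], , drop = FALSE]
  tab <- data.frame(
    feature = colnames(x),
    p = vapply(seq_len(ncol(x)), function(j) pooled_ttest(a[, j], b[, j]), 0),
    C_B = vapply(seq_len(ncol(x)), function(j) bhattacharyya_criterion(a[, j], b[, j]), 0),
    D_KL = vapply(seq_len(ncol(x)), function(j) kl_criterion(a[, j], b[, j]), 0),
    stringsAsFactors = FALSE
  )
  key <- switch(criterion, C_B = -tab$C_B, D_KL = -tab$D_KL, p = tab$p)
  ord <- order(key, seq_len(nrow(tab)))  # ties: earlier column wins
  tab$rank <- integer(nrow(tab))
  tab$rank[ord] <- seq_len(nrow(tab))
  tab
}

stratified_folds <- function(y, k) {
  if (any(table(y) < k))
    stop("fold count ", k, " exceeds the size of a class (",
         min(table(y)), ")")
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

cv_mce <- function(x, y, fold, features) {
  k <- max(fold)
  errs <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    fit <- qda_fit(x[tr, features, drop = FALSE], y[tr])
    pred <- qda_predict(fit, x[!tr, features, drop = FALSE])
    mean(pred$class != y[!tr])
  }, 0)
  mean(errs)
}

#' Single run of sequential forward feature selection
#'
#' Greedy wrapper selection with a QDA learner: a stratified 20% holdout is
#' set aside, 10-fold cross-validated misclassification error (MCE) on the
#' training part scores every candidate addition, and the full MCE-versus-k
#' curve is evaluated over all features.  The run's subset is the prefix up
#' to the curve's global minimum (the first local minimum can stop the
#' search prematurely).  Candidate enumeration and tie-breaking follow the
#' features' Bhattacharyya ranking on the training part.
#'
#' @param x numeric feature matrix (balance classes first, see
#'   [balance_smote()]).
#' @param y two-level factor.
#' @param seed integer seed controlling holdout and fold assignment.
#' @param folds number of CV folds on the training part.
#' @param holdout fraction held out for reporting.
#' @return List of class `ehg_sfs_run`: `order` (features in selection
#'   order), `mce_curve`, `subset`, `n_selected`, `holdout_mce`, `seed`.
#' @export
sfs_select <- function(x, y, seed = 1L, folds = 10L, holdout = 0.2) {
  y <- factor(y)
  if (nlevels(y) != 2L) stop("sfs_select requires exactly two classes")
  if (nrow(x) < 20L) stop("need at least 20 rows for SFS with holdout")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  test_idx <- unlist(lapply(levels(y), function(lv) {
    idx <- which(y == lv)
    sample(idx, max(1L, round(holdout * length(idx))))
  }))
  tr_x <- x[-test_idx, , drop = FALSE]; tr_y <- droplevels(y[-test_idx])
  te_x <- x[test_idx, , drop = FALSE]; te_y <- y[test_idx]

  cand_order <- rank_features(tr_x, tr_y, "C_B")
  cand <- cand_order$feature[order(cand_order$rank)]
  fold <- stratified_folds(tr_y, folds)

  selected <- character(0)
  curve <- numeric(ncol(x))
  for (step in seq_len(ncol(x))) {
    rest <- setdiff(cand, selected)
    mces <- vapply(rest, function(f)
      cv_mce(tr_x, tr_y, fold, c(selected, f)), 0)
    best <- rest[which.min(mces)]  # ties: first in C_B order
    selected <- c(selected, best)
    curve[step] <- min(mces)
  }
  n_sel <- which.min(curve)
  subset <- selected[seq_len(n_sel)]
  fit <- qda_fit(tr_x[, subset, drop = FALSE], tr_y)
  holdout_mce <- mean(qda_predict(fit, te_x[, subset, drop = FALSE])$class != te_y)
  structure(list(order = selected, mce_curve = curve, subset = subset,
                 n_selected = n_sel, holdout_mce = holdout_mce, seed = seed),
            class = "ehg_sfs_run")
}

#' Frequency-based aggregation of repeated SFS runs
#'
#' Runs [sfs_select()] `runs` times (200 by default) with per-run seeds
#' spawned from one master seed, accumulates a per-feature selection
#' frequency histogram over the run subsets, and averages the MCE curves.
#' The number of features retained is the argmin of the averaged curve; the
#' final subset is that many features in descending histogram order.
#'
#' @param x numeric feature matrix (balanced).
#' @param y two-level factor.
#' @param runs number of SFS runs.
#' @param seed master seed.
#' @param folds CV folds per run.
#' @return List of class `ehg_selection`: `histogram` (named counts, all
#'   features), `avg_mce_curve`, `n_selected`, `final_subset`, `runs`,
#'   `seed`.
#' @export
aggregate_selection <- function(x, y, runs = 200L, seed = 1L, folds = 10L) {
  if (runs < 1L) stop("runs must be at least 1")
  run_seeds <- (as.integer(seed) + seq_len(runs) * 7919L) %% .Machine$integer.max
  hist_counts <- setNames(numeric(ncol(x)), colnames(x))
  curves <- matrix(0, nrow = runs, ncol = ncol(x))
  subsets <- vector("list", runs)
  for (i in seq_len(runs)) {
    run <- sfs_select(x, y, seed = run_seeds[i], folds = folds)
    hist_counts[run$subset] <- hist_counts[run$subset] + 1
    curves[i, ] <- run$mce_curve
    subsets[[i]] <- run$subset
  }
  avg_curve <- colMeans(curves)
  n_sel <- which.min(avg_curve)
  # descending frequency; ties broken by column order
  ord <- order(-hist_counts, seq_along(hist_counts))
  final <- names(hist_counts)[ord][seq_len(n_sel)]
  structure(list(histogram = hist_counts, avg_mce_curve = avg_curve,
                 n_selected = n_sel, final_subset = final,
                 run_subsets = subsets, runs = runs, seed = seed),
            class = "ehg_selection")
}

#' @export
print.ehg_selection <- function(x, ...) {
  cat(sprintf("<ehg_selection> %d runs, %d features selected (avg MCE min %.4f)\n",
              x$runs, x$n_selected, min(x$avg_mce_curve)))
  cat("  subset:", paste(x$final_subset, collapse = ", "), "\n")
  invisible(x)
}

# save/restore the RNG state so seeded helpers do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
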