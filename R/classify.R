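#' Quadratic discriminant analysis fit
#'
#' Per-class Gaussian model with class-specific mean and covariance and
#' empirical priors.  A class covariance that cannot be Cholesky-factored is
#' ridge-regularized by `lambda * trace(Sigma)/d` on the diagonal (lambda
#' starting at 1e-6 and escalating by decades), so degenerate inputs such as
#' constant feature columns still fit.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y two-level factor.
#' @return List of class `ehg_qda` with per-class `mean`, `chol` (upper
#'   Cholesky factor of the covariance), `logdet`, `logprior`.
#' @export
qda_fit <- function(x, y) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) != 2L) stop("qda_fit requires exactly two classes")
  if (min(table(y)) < 2L) stop("each class needs at least 2 samples")
  d <- ncol(x)
  classes <- levels(y)
  fit <- lapply(classes, function(lv) {
    xi <- x[y == lv, , drop = FALSE]
    mu <- colMeans(xi)
    S <- stats::cov(xi)
    R <- NULL
    lambda <- 0
    base <- max(sum(diag(S)) / d, .Machine$double.eps)
    repeat {
      R <- tryCatch(chol(S + diag(lambda * base, d)), error = function(e) NULL)
      if (!is.null(R) && all(diag(R) > d * 1e-12 * sqrt(base))) break
      lambda <- if (lambda == 0) 1e-6 else lambda * 10
      if (lambda > 1e2)
        stop("class covariance for '", lv, "' is singular beyond repair")
    }
    list(mean = mu, chol = R, logdet = 2 * sum(log(diag(R))),
         logprior = log(mean(y == lv)))
  })
  names(fit) <- classes
  structure(list(classes = classes, fit = fit, d = d,
                 features = colnames(x)), class = "ehg_qda")
}

#' Predict with a QDA model
#'
#' @param model an `ehg_qda` fit.
#' @param x matrix of rows to classify (same feature columns as the fit).
#' @param positive class treated as positive for the score column (default:
#'   second factor level).
#' @return List with `class` (factor) and `score` (posterior probability of
#'   the positive class).
#' @export
qda_predict <- function(model, x, positive = model$classes[2L]) {
  stopifnot(inherits(model, "ehg_qda"))
  x <- as.matrix(x)
  logp <- vapply(model$classes, function(lv) {
    f <- model$fit[[lv]]
    z <- backsolve(f$chol, t(x) - f$mean, transpose = TRUE)
    -0.5 * colSums(z^2) - 0.5 * f$logdet + f$logprior
  }, numeric(nrow(x)))
  logp <- matrix(logp, nrow = nrow(x),
                 dimnames = list(NULL, model$classes))
  cls <- factor(model$classes[max.col(logp, ties.method = "first")],
                levels = model$classes)
  shift <- apply(logp, 1L, max)
  post <- exp(logp - shift)
  post <- post / rowSums(post)
  list(class = cls, score = post[, positive])
}

minority_majority <- function(y) {
  tab <- table(y)
  list(minority = names(tab)[which.min(tab)],
       majority = names(tab)[which.max(tab)],
       gap = max(tab) - min(tab))
}

smote_interpolate <- function(xmin, base_idx, nbr_idx, gaps) {
  xmin[base_idx, , drop = FALSE] +
    gaps * (xmin[nbr_idx, , drop = FALSE] - xmin[base_idx, , drop = FALSE])
}

knn_index <- function(from, to, k, exclude_self = FALSE) {
  d2 <- outer(rowSums(from^2), rowSums(to^2), "+") - 2 * from %*% t(to)
  t(vapply(seq_len(nrow(from)), function(i) {
    ord <- order(d2[i, ], decreasing = FALSE)
    if (exclude_self) ord <- ord[ord != i]
    ord[seq_len(k)]
  }, integer(k)))
}

#' SMOTE minority oversampling
#'
#' Equalizes class counts by adding synthetic minority rows placed uniformly
#' at random on the segment between a minority sample and one of its k
#' nearest minority neighbors; majority rows are untouched.
#'
#' @param x numeric feature matrix.
#' @param y two-level factor.
#' @param k_neighbors number of minority neighbors to draw from.
#' @param seed integer seed.
#' @return List `x`, `y`, `synthetic` (logical row flags).
#' @export
balance_smote <- function(x, y, k_neighbors = 5L, seed = 1L) {
  x <- as.matrix(x); y <- factor(y)
  mm <- minority_majority(y)
  if (mm$gap == 0L)
    return(list(x = x, y = y, synthetic = rep(FALSE, nrow(x))))
  min_idx <- which(y == mm$minority)
  if (length(min_idx) < k_neighbors + 1L)
    stop("minority class has ", length(min_idx),
         " samples; needs at least k_neighbors + 1 = ", k_neighbors + 1L,
         " (use a smaller k_neighbors)")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  xmin <- x[min_idx, , drop = FALSE]
  nn <- knn_index(xmin, xmin, k_neighbors, exclude_self = TRUE)
  base <- sample(seq_len(nrow(xmin)), mm$gap, replace = TRUE)
  nbr <- nn[cbind(base, sample(k_neighbors, mm$gap, replace = TRUE))]
  synth <- smote_interpolate(xmin, base, nbr, runif(mm$gap))
  list(x = rbind(x, synth),
       y = factor(c(as.character(y), rep(mm$minority, mm$gap)),
                  levels = levels(y)),
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, mm$gap)))
}

#' ADASYN adaptive minority oversampling
#'
#' Allocates synthetic minority rows per minority sample in proportion to
#' the fraction of majority points among its k nearest neighbors in the full
#' data (samples nearer the class boundary receive more), then interpolates
#' between minority neighbors as in SMOTE.  The resulting minority count is
#' approximately, not exactly, the majority count.
#'
#' @inheritParams balance_smote
#' @return List `x`, `y`, `synthetic`.
#' @export
balance_adasyn <- function(x, y, k_neighbors = 5L, seed = 1L) {
  x <- as.matrix(x); y <- factor(y)
  mm <- minority_majority(y)
  if (mm$gap == 0L)
    return(list(x = x, y = y, synthetic = rep(FALSE, nrow(x))))
  min_idx <- which(y == mm$minority)
  if (length(min_idx) < k_neighbors + 1L)
    stop("minority class has ", length(min_idx),
         " samples; needs at least k_neighbors + 1 = ", k_neighbors + 1L,
         " (use a smaller k_neighbors)")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  xmin <- x[min_idx, , drop = FALSE]
  nn_all <- knn_index(xmin, x, k_neighbors + 1L)
  r <- vapply(seq_len(nrow(xmin)), function(i) {
    nbrs <- setdiff(nn_all[i, ], min_idx[i])[seq_len(k_neighbors)]
    mean(y[nbrs] == mm$majority)
  }, 0)
  w <- if (sum(r) == 0) rep(1 / length(r), length(r)) else r / sum(r)
  g <- round(w * mm$gap)
  total <- sum(g)
  if (total == 0L) return(list(x = x, y = y, synthetic = rep(FALSE, nrow(x))))
  nn_min <- knn_index(xmin, xmin, min(k_neighbors, nrow(xmin) - 1L),
                      exclude_self = TRUE)
  base <- rep(seq_len(nrow(xmin)), g)
  nbr <- nn_min[cbind(base, sample(ncol(nn_min), total, replace = TRUE))]
  synth <- smote_interpolate(xmin, base, nbr, runif(total))
  list(x = rbind(x, synth),
       y = factor(c(as.character(y), rep(mm$minority, total)),
                  levels = levels(y)),
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, total)))
}

confusion_counts <- function(truth, pred, positive) {
  c(TP = sum(truth == positive & pred == positive),
    FN = sum(truth == positive & pred != positive),
    TN = sum(truth != positive & pred != positive),
    FP = sum(truth != positive & pred == positive))
}

#' Repeated stratified cross-validated classification metrics
#'
#' Stratified k-fold cross-validation of a QDA classifier, repeated
#' `repetitions` times with re-drawn folds, reporting sensitivity,
#' specificity, classification accuracy (from confusion counts pooled across
#' folds within each repetition) and AUC (trapezoidal, on the pooled
#' positive-class posterior scores of each repetition), averaged over
#' repetitions and expressed in percent.  By default balancing is applied
#' inside each training fold only, so test rows are never synthetic;
#' `balance_upfront = TRUE` instead balances the whole dataset once before
#' cross-validation (the protocol under which balanced class sizes such as
#' 53/53 are quoted).
#'
#' @param x numeric feature matrix.
#' @param y two-level factor.
#' @param positive the clinically alarming class (e.g. `"preterm"`).
#' @param folds 5 or 10.
#' @param repetitions number of CV repetitions (default 30).
#' @param balance `"none"`, `"smote"` or `"adasyn"`.
#' @param seed integer seed.
#' @param balance_upfront balance once before CV instead of per fold.
#' @param k_neighbors neighbor count for the balancer.
#' @return List of class `ehg_cv_report`: `Se`, `Sp`, `CA`, `AUC` (percent,
#'   means over repetitions), `per_repetition` data frame, and the settings.
#' @export
cross_validated_metrics <- function(x, y, positive, folds = 10L,
                                    repetitions = 30L,
                                    balance = c("none", "smote", "adasyn"),
                                    seed = 1L, balance_upfront = FALSE,
                                    k_neighbors = 5L) {
  balance <- match.arg(balance)
  x <- as.matrix(x); y <- factor(y)
  if (nlevels(y) != 2L) stop("need exactly two classes")
  if (!positive %in% levels(y)) stop("positive class not in labels")
  balancer <- switch(balance, none = NULL,
                     smote = balance_smote, adasyn = balance_adasyn)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))

  if (balance_upfront && !is.null(balancer)) {
    bal <- balancer(x, y, k_neighbors, seed = seed)
    x <- bal$x; y <- bal$y
  }

  reps <- lapply(seq_len(repetitions), function(rep_i) {
    set.seed((as.integer(seed) + rep_i * 104729L) %% .Machine$integer.max)
    fold <- stratified_folds(y, folds)
    counts <- c(TP = 0L, FN = 0L, TN = 0L, FP = 0L)
    scores <- numeric(length(y)); truth <- y
    for (f in seq_len(folds)) {
      tr <- fold != f
      tx <- x[tr, , drop = FALSE]; ty <- y[tr]
      if (!balance_upfront && !is.null(balancer)) {
        bal <- balancer(tx, ty, k_neighbors,
                        seed = (as.integer(seed) + rep_i * 131L + f) %%
                          .Machine$integer.max)
        tx <- bal$x; ty <- bal$y
      }
      fit <- qda_fit(tx, ty)
      pred <- qda_predict(fit, x[!tr, , drop = FALSE], positive = positive)
      counts <- counts + confusion_counts(y[!tr], pred$class, positive)
      scores[!tr] <- pred$score
    }
    auc <- as.numeric(pROC::auc(pROC::roc(
      response = truth, predictor = scores,
      levels = c(setdiff(levels(y), positive), positive),
      direction = "<", quiet = TRUE)))
    data.frame(repetition = rep_i,
               Se = 100 * counts["TP"] / (counts["TP"] + counts["FN"]),
               Sp = 100 * counts["TN"] / (counts["TN"] + counts["FP"]),
               CA = 100 * (counts["TP"] + counts["TN"]) / sum(counts),
               AUC = 100 * auc, row.names = NULL)
  })
  per_rep <- do.call(rbind, reps)
  structure(list(Se = mean(per_rep$Se), Sp = mean(per_rep$Sp),
                 CA = mean(per_rep$CA), AUC = mean(per_rep$AUC),
                 per_repetition = per_rep, folds = folds,
                 repetitions = repetitions, balance = balance,
                 balance_upfront = balance_upfront, positive = positive,
                 seed = seed),
            class = "ehg_cv_report")
}

#' @export
print.ehg_cv_report <- function(x, ...) {
  cat(sprintf("<ehg_cv_report> QDA, %d-fold CV x %d repetitions (balance: %s%s)\n",
              x$folds, x$repetitions, x$balance,
              if (x$balance_upfront) ", upfront" else ""))
  cat(sprintf("  Se = %.2f%%  Sp = %.2f%%  CA = %.2f%%  AUC = %.2f%%  (positive: %s)\n",
              x$Se, x$Sp, x$CA, x$AUC, x$positive))
  invisible(x)
}
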