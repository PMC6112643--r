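two_gaussians <- function(n1, n2, delta = 3, d = 4, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n1 * d), ncol = d),
             matrix(rnorm(n2 * d, mean = delta), ncol = d))
  colnames(x) <- paste0("f", seq_len(d))
  list(x = x, y = factor(rep(c("pos", "neg"), c(n1, n2)),
                         levels = c("neg", "pos")))
}

test_that("SMOTE equalizes a 47 vs 53 split with convex synthetic rows", {
  g <- two_gaussians(47, 53, delta = 2, seed = 22)
  bal <- balance_smote(g$x, g$y, seed = 5)
  expect_equal(as.integer(table(bal$y)[c("pos", "neg")]), c(53L, 53L))
  expect_equal(sum(bal$synthetic), 6L)
  expect_false(any(bal$synthetic[seq_len(100)]))

  # every synthetic row is a convex combination of two original minority rows
  xmin <- g$x[g$y == "pos", , drop = FALSE]
  for (s in which(bal$synthetic)) {
    row <- bal$x[s, ]
    found <- FALSE
    for (u in seq_len(nrow(xmin))) {
      dir <- row - xmin[u, ]
      for (v in seq_len(nrow(xmin))[-u]) {
        seg <- xmin[v, ] - xmin[u, ]
        tt <- if (abs(seg[1]) > 1e-12) dir[1] / seg[1] else 0
        if (tt >= -1e-9 && tt <= 1 + 1e-9 &&
            max(abs(dir - tt * seg)) < 1e-8) { found <- TRUE; break }
      }
      if (found) break
    }
    expect_true(found)
  }

  # already balanced input is returned unchanged
  gb <- two_gaussians(20, 20, seed = 23)
  balb <- balance_smote(gb$x, gb$y, seed = 5)
  expect_identical(balb$x, gb$x)
  expect_false(any(balb$synthetic))

  expect_error(balance_smote(g$x[c(1:3, 48:100), ], g$y[c(1:3, 48:100)],
                             k_neighbors = 5),
               "smaller k_neighbors")
})

test_that("ADASYN approximately balances and adapts to boundary density", {
  g <- two_gaussians(19, 143, delta = 2, d = 3, seed = 24)
  bal <- balance_adasyn(g$x, g$y, seed = 6)
  n_min <- sum(bal$y == "pos")
  expect_gte(n_min, 129L)
  expect_lte(n_min, 143L + 14L)  # within 10% of the majority count

  gb <- two_gaussians(30, 30, seed = 25)
  balb <- balance_adasyn(gb$x, gb$y, seed = 6)
  expect_equal(nrow(balb$x), 60L)

  # minority far from the majority: allocation degenerates to uniform
  far <- two_gaussians(12, 40, delta = 50, d = 2, seed = 26)
  balf <- balance_adasyn(far$x, far$y, seed = 6)
  n_minf <- sum(balf$y == "pos")
  expect_gte(n_minf, 36L)
  expect_lte(n_minf, 44L)
})

test_that("QDA separates well-separated clouds and is honest at chance", {
  g <- two_gaussians(100, 100, delta = 6, d = 2, seed = 27)
  fit <- qda_fit(g$x, g$y)
  expect_equal(mean(qda_predict(fit, g$x)$class == g$y), 1.0)

  accs <- vapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(rnorm(200 * 2), ncol = 2)
    y <- factor(rep(c("a", "b"), 100))  # interleaved: splits stay stratified
    fit <- qda_fit(x[1:140, ], y[1:140])
    mean(qda_predict(fit, x[141:200, ])$class == y[141:200])
  }, 0)
  expect_gt(mean(accs), 0.40)
  expect_lt(mean(accs), 0.60)

  # constant feature column: regularized fit must not crash
  g2 <- two_gaussians(20, 20, seed = 28)
  g2$x[, 2] <- 1
  expect_s3_class(qda_fit(g2$x, g2$y), "ehg_qda")
  expect_length(qda_predict(qda_fit(g2$x, g2$y), g2$x)$class, 40L)
})

test_that("QDA agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  g <- two_gaussians(60, 70, delta = 1.5, d = 3, seed = 29)
  ours <- qda_predict(qda_fit(g$x, g$y), g$x)
  ref <- predict(MASS::qda(g$x, g$y), g$x)
  expect_equal(as.character(ours$class), as.character(ref$class))
  expect_equal(unname(ours$score), unname(ref$posterior[, "pos"]),
               tolerance = 1e-8)
})

test_that("confusion-count metrics follow the printed formulas", {
  truth <- factor(c(rep("pos", 10), rep("neg", 10)), levels = c("neg", "pos"))
  pred <- factor(c(rep("pos", 9), "neg", rep("neg", 8), "pos", "pos"),
                 levels = c("neg", "pos"))
  counts <- ehgtools:::confusion_counts(truth, pred, "pos")
  expect_equal(unname(counts), c(9L, 1L, 8L, 2L))
  expect_equal(100 * counts[["TP"]] / (counts[["TP"]] + counts[["FN"]]), 90)
  expect_equal(100 * counts[["TN"]] / (counts[["TN"]] + counts[["FP"]]), 80)
  expect_equal(100 * (counts[["TP"]] + counts[["TN"]]) / sum(counts), 85)
})

test_that("cross-validation reports perfect metrics on oracle-labeled data", {
  set.seed(30)
  y <- factor(rep(c("neg", "pos"), each = 30), levels = c("neg", "pos"))
  x <- cbind(f1 = as.numeric(y == "pos") + rnorm(60, sd = 0.01),
             f2 = rnorm(60))
  rep <- cross_validated_metrics(x, y, positive = "pos", folds = 5,
                                 repetitions = 3, seed = 7)
  expect_equal(rep$Se, 100)
  expect_equal(rep$Sp, 100)
  expect_equal(rep$CA, 100)
  expect_equal(rep$AUC, 100)
})

test_that("cross-validation is reproducible and supports balancing modes", {
  g <- two_gaussians(25, 40, delta = 2.5, d = 3, seed = 31)
  r1 <- cross_validated_metrics(g$x, g$y, positive = "pos", folds = 5,
                                repetitions = 4, balance = "smote", seed = 11)
  r2 <- cross_validated_metrics(g$x, g$y, positive = "pos", folds = 5,
                                repetitions = 4, balance = "smote", seed = 11)
  expect_identical(r1, r2)
  expect_true(all(r1$per_repetition$CA >= 0 & r1$per_repetition$CA <= 100))

  up <- cross_validated_metrics(g$x, g$y, positive = "pos", folds = 5,
                                repetitions = 2, balance = "smote",
                                balance_upfront = TRUE, seed = 12)
  expect_s3_class(up, "ehg_cv_report")
  expect_gt(up$CA, 50)

  ad <- cross_validated_metrics(g$x, g$y, positive = "pos", folds = 5,
                                repetitions = 2, balance = "adasyn", seed = 13)
  expect_s3_class(ad, "ehg_cv_report")

  expect_error(cross_validated_metrics(g$x, g$y, positive = "pos",
                                       folds = 30, repetitions = 1, seed = 1),
               "exceeds")
})
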