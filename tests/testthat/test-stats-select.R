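test_that("pooled t-test matches the textbook statistic and handles nulls", {
  x <- c(0.1, 0.2, 0.3); y <- c(1.1, 1.2, 1.3)
  # independent oracle: explicit pooled-variance t statistic and CDF
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(pooled_ttest(x, y), 2 * stats::pt(-abs(tstat), df = 4),
               tolerance = 1e-12)

  # identical means with spread: t = 0, p = 1
  expect_equal(pooled_ttest(c(1, 2, 3), c(3, 2, 1)), 1)
  expect_error(pooled_ttest(1, c(1, 2)), "at least 2")
  expect_error(pooled_ttest(c(1, 1, 1), c(1, 1, 1)), "degenerate")
})

test_that("Bhattacharyya criterion matches closed forms", {
  x <- exact_moments(20, 0, 1)
  expect_equal(bhattacharyya_criterion(x, x), 0)

  y <- exact_moments(20, 2, 1)  # mean gap 2, unit variances: C_B = 0.5
  expect_equal(bhattacharyya_criterion(x, y), 0.5, tolerance = 1e-12)

  set.seed(14)
  a <- rnorm(20000, 0, 1); b <- rnorm(20000, 1, 2)
  pop <- 1 / (4 * (1 + 4)) + 0.5 * log((1 + 4) / (2 * 2))
  expect_lt(abs(bhattacharyya_criterion(a, b) - pop) / pop, 0.05)

  expect_error(bhattacharyya_criterion(c(1, 1, 1), c(0, 1, 2)), "zero variance")
})

test_that("relative entropy criterion matches its Gaussian closed form", {
  x <- exact_moments(30, 0, 1)
  expect_equal(kl_criterion(x, x), 0)
  y <- exact_moments(30, 1, 1)
  # equal unit variances, mean shift 1: (1/2) d^2 (1/vx + 1/vy) / 2 = 0.5
  expect_equal(kl_criterion(x, y), 0.5, tolerance = 1e-12)
  expect_error(kl_criterion(rep(2, 5), c(0, 1, 2)), "zero variance")
})

test_that("C_B and D_KL rank nearly identically on well-separated features", {
  set.seed(15)
  n <- 60
  deltas <- c(3, 2.4, 1.9, 1.5, 1.2, 0.4, 0.3, 0.2, 0.1, 0)
  x <- sapply(deltas, function(d) rnorm(n) + rep(c(0, d), each = n / 2))
  colnames(x) <- paste0("f", seq_along(deltas))
  y <- factor(rep(c("a", "b"), each = n / 2))
  tab_cb <- rank_features(x, y, "C_B")
  tab_kl <- rank_features(x, y, "D_KL")
  top5_cb <- tab_cb$feature[order(tab_cb$rank)][1:5]
  top5_kl <- tab_kl$feature[order(tab_kl$rank)][1:5]
  expect_equal(top5_cb, top5_kl)
})

test_that("ranking places informative features first, ties by column order", {
  set.seed(16)
  n <- 80
  x <- matrix(rnorm(n * 10), ncol = 10)
  x[, 4] <- rnorm(n) + rep(c(0, 3), each = n / 2)
  colnames(x) <- paste0("f", 1:10)
  y <- factor(rep(c("a", "b"), each = n / 2))
  tab <- rank_features(x, y)
  expect_equal(tab$feature[tab$rank == 1], "f4")
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_true(all(tab$C_B >= 0))
  expect_true(all(tab$D_KL >= 0))
  expect_setequal(tab$rank, 1:10)

  # identical columns: all criteria equal, ranks follow column order
  xd <- x[, c(4, 4, 4)]; colnames(xd) <- c("a1", "a2", "a3")
  tabd <- rank_features(xd, y)
  expect_equal(tabd$rank, 1:3)

  expect_error(rank_features(x, factor(rep("a", n))), "two classes")
})

test_that("criteria are invariant to affine rescaling of a feature", {
  set.seed(17)
  x <- rnorm(40); y <- rnorm(40) + 1
  expect_equal(bhattacharyya_criterion(5 * x - 3, 5 * y - 3),
               bhattacharyya_criterion(x, y), tolerance = 1e-9)
  expect_equal(kl_criterion(5 * x - 3, 5 * y - 3), kl_criterion(x, y),
               tolerance = 1e-9)
})

test_that("single SFS runs recover informative features and trace a full curve", {
  prob <- make_selection_problem(n_per_class = 50, n_noise = 8, delta = 2,
                                 seed = 18)
  run <- sfs_select(prob$x, prob$y, seed = 2)
  expect_length(run$mce_curve, 10L)
  expect_true(all(run$mce_curve >= 0 & run$mce_curve <= 1))
  expect_true(all(c("inf1", "inf2") %in% run$subset))
  expect_equal(run$subset, run$order[seq_len(run$n_selected)])

  # exhaustive best-subset-of-2 oracle: every pair is fit on the data and
  # scored on a large fresh draw from the same construction; the
  # informative pair must win
  big <- make_selection_problem(n_per_class = 2000, n_noise = 8, delta = 2,
                                seed = 118)
  pairs <- utils::combn(colnames(prob$x), 2)
  pair_mce <- apply(pairs, 2, function(fp) {
    fit <- qda_fit(prob$x[, fp], prob$y)
    mean(qda_predict(fit, big$x[, fp])$class != big$y)
  })
  best_pair <- sort(pairs[, which.min(pair_mce)])
  expect_equal(best_pair, c("inf1", "inf2"))
})

test_that("a perfectly separable feature yields an immediate zero MCE", {
  set.seed(19)
  n <- 60
  x <- cbind(sep = rep(c(0, 10), each = n / 2) + rnorm(n, sd = 0.01),
             junk = rnorm(n))
  y <- factor(rep(c("a", "b"), each = n / 2))
  run <- sfs_select(x, y, seed = 4)
  expect_equal(run$mce_curve[1], 0)
  expect_equal(run$n_selected, 1L)
  expect_equal(run$subset, "sep")
})

test_that("aggregated selection is reproducible and counts are consistent", {
  prob <- make_selection_problem(n_per_class = 25, n_noise = 4, seed = 20)
  sel1 <- aggregate_selection(prob$x, prob$y, runs = 8, seed = 9)
  sel2 <- aggregate_selection(prob$x, prob$y, runs = 8, seed = 9)
  expect_identical(sel1, sel2)
  expect_equal(sum(sel1$histogram),
               sum(lengths(sel1$run_subsets)))
  expect_length(sel1$final_subset, sel1$n_selected)

  # runs = 1 degenerates to the single run's subset in histogram order
  one <- aggregate_selection(prob$x, prob$y, runs = 1, seed = 9)
  single <- sfs_select(prob$x, prob$y,
                       seed = (9L + 1L * 7919L) %% .Machine$integer.max)
  expect_setequal(one$final_subset, single$subset)
  expect_error(aggregate_selection(prob$x, prob$y, runs = 0), "at least 1")
})
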