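test_that("sentence-scheme folds partition samples with balanced sizes", {
  plan <- make_folds(seq_len(100), k = 10, r = 3, scheme = "sentence",
                     seed = 2)
  for (f in plan$assignments) {
    expect_equal(sort(unique(f)), 1:10)
    expect_true(all(table(f) == 10))        # exact division
    expect_length(f, 100)
  }
  # uneven M: sizes differ by at most one
  p2 <- make_folds(seq_len(103), k = 10, r = 2, seed = 3)
  for (f in p2$assignments)
    expect_lte(diff(range(table(f))), 1)
  expect_error(make_folds(1:5, k = 10), "exceeds")
  expect_error(make_folds(1:10, k = 1), "k must be")
})

test_that("abstract scheme never splits an abstract across folds", {
  abs_ids <- rep(sprintf("a%02d", 1:20), each = 5)
  plan <- make_folds(seq_along(abs_ids), abs_ids, k = 10, r = 4,
                     scheme = "abstract", seed = 7)
  for (f in plan$assignments) {
    expect_equal(sort(unique(f)), 1:10)
    per_abstract <- tapply(f, abs_ids, function(x) length(unique(x)))
    expect_true(all(per_abstract == 1))
    # fold sizes balanced in abstracts (2 each here)
    expect_true(all(table(tapply(f, abs_ids, unique)) == 2))
  }
  expect_error(make_folds(1:10, k = 3, scheme = "abstract"),
               "needs abstract_ids")
  expect_error(make_folds(1:10, rep("a", 10), k = 3, scheme = "abstract"),
               "exceeds the number of abstracts")
})

test_that("metrics match the hand-computed confusion matrix", {
  # TP=3, FP=1, FN=2, TN=4 at threshold 0.5
  labels <- c(rep(1, 5), rep(0, 5))
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.6, 0.4, 0.3, 0.2, 0.1)
  m <- compute_metrics(labels, scores)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f_score, 2 * 0.75 * 0.6 / 1.35)
  expect_equal(round(m$f_score, 5), 0.66667)
  expect_equal(m$error_pct, 30)
})

test_that("AUC follows the rank formulation with tie credit", {
  expect_equal(compute_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(compute_metrics(c(0, 1), c(0.5, 0.5))$auc, 0.5)
  expect_equal(compute_metrics(c(0, 1, 0, 1),
                               c(0.9, 0.8, 0.1, 0.2))$auc, 0.5)
  expect_warning(m <- compute_metrics(c(1, 1), c(0.2, 0.9)), "single-class")
  expect_true(is.na(m$auc))
})

test_that("F equals the harmonic-mean formula, 0 when P + R = 0", {
  # P = R = 0.5 -> F = 0.5
  m <- compute_metrics(c(1, 0), c(0.9, 0.8))
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 1)
  m2 <- compute_metrics(c(1, 1, 0, 0), c(0.6, 0.2, 0.7, 0.1))
  expect_equal(m2$precision, 0.5); expect_equal(m2$recall, 0.5)
  expect_equal(m2$f_score, 0.5)
  m0 <- compute_metrics(c(1, 0), c(0.1, 0.2))
  expect_equal(m0$f_score, 0)
})

test_that("corrected t-test matches the closed form on a fixed fixture", {
  set.seed(99)
  a <- stats::rnorm(100, 0.72, 0.03)
  b <- stats::rnorm(100, 0.70, 0.03)
  res <- corrected_ttest(a, b, k = 10, r = 10)
  # independent hand computation of the corrected statistic
  d <- a - b
  t_hand <- mean(d) / sqrt(stats::var(d) * (1 / 100 + (1 / 10) / (9 / 10)))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 99)
  expect_equal(res$p, 2 * stats::pt(-abs(t_hand), 99), tolerance = 1e-12)
})

test_that("corrected t-test degenerate contracts", {
  x <- runif(100)
  res <- corrected_ttest(x, x)
  expect_equal(res$t, 0); expect_equal(res$p, 1)
  res2 <- corrected_ttest(rep(0.75, 100), rep(0.7, 100))
  expect_true(is.infinite(res2$t) && res2$t > 0)
  expect_equal(res2$p, 0)
})

test_that("removing the overlap term recovers the classical paired t", {
  set.seed(3)
  a <- stats::rnorm(100, 0.6, 0.05); b <- stats::rnorm(100, 0.58, 0.05)
  res <- corrected_ttest(a, b, k = 10, r = 10, test_fraction = 0)
  classical <- stats::t.test(a, b, paired = TRUE)
  expect_equal(res$t, unname(classical$statistic), tolerance = 1e-10)
  # corrected |t| is always smaller than classical |t| (conservative)
  expect_lt(abs(corrected_ttest(a, b, k = 10, r = 10)$t), abs(res$t))
})

test_that("corrected test stays conservative under a correlated null", {
  # fold values share a per-repetition random effect, mimicking the
  # training-set overlap of repeated CV; nominal alpha = 0.05
  set.seed(123)
  rejections <- 0L
  for (rep in 1:100) {
    eff_a <- rep(stats::rnorm(10, 0, 0.02), each = 10)
    eff_b <- rep(stats::rnorm(10, 0, 0.02), each = 10)
    a <- 0.7 + eff_a + stats::rnorm(100, 0, 0.03)
    b <- 0.7 + eff_b + stats::rnorm(100, 0, 0.03)
    if (corrected_ttest(a, b)$p < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 15L)
})

test_that("theta tuning returns a grid value that a holdout confirms", {
  set.seed(7)
  n <- 90
  X <- rbind(matrix(stats::rnorm(n * 5, 0), ncol = 5),
             matrix(stats::rnorm(n * 5, 1), ncol = 5))
  y <- rep(c(0, 1), each = n)
  grid <- 10^(-5:1)
  th <- tune_gaussian_theta(X, y, grid = grid, seed = 7)
  expect_true(th %in% grid)
  # independent oracle: validation AUC of every grid value on fresh data
  set.seed(8)
  Xv <- rbind(matrix(stats::rnorm(60 * 5, 0), ncol = 5),
              matrix(stats::rnorm(60 * 5, 1), ncol = 5))
  yv <- rep(c(0, 1), each = 60)
  val <- vapply(grid, function(g) {
    f <- pmkl_fit(kernel_gaussian(X, theta = g), y)
    compute_metrics(yv, pmkl_predict(f, kernel_gaussian(Xv, X, theta = g))$scores)$auc
  }, 0)
  expect_gte(val[match(th, grid)], max(val) - 0.02)
})

test_that("theta tuning tie-break and single-value contracts", {
  expect_equal(tune_gaussian_theta(matrix(1, 4, 2), c(0, 1, 0, 1),
                                   grid = 0.5), 0.5)
  # all-zero features: every theta gives the same constant kernel, so
  # scores tie and the smallest grid value must be returned
  X0 <- matrix(0, 12, 3)
  y0 <- rep(c(0, 1), 6)
  expect_equal(tune_gaussian_theta(X0, y0, grid = c(0.01, 0.1, 1), seed = 1),
               0.01)
})
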