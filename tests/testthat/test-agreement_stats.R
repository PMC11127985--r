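test_that("KS comparison: degenerate cases and oracle agreement", {
  x <- c(1.2, 3.4, 5.6, 7.8, 9.1)
  same <- ks_compare(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  apart <- ks_compare(c(1, 2, 3), c(10, 11, 12))
  expect_equal(apart$statistic, 1)

  # fixed two-sample fixture against the ECDF-supremum + Kolmogorov-series
  # oracle (statistic countable by hand: sup |ECDF diff| = 0.2)
  a <- c(1.6243, -0.6118, -0.5282, -1.073, 0.8654, -2.3015, 1.7448,
         -0.7612, 0.319, -0.2494, 1.4621, -2.0601)
  b <- c(0.0832, 0.4437, -1.6362, 2.1403, -1.2934, -0.3417, 1.0029,
         -0.7453, -0.558, -0.409, 1.0515, 2.7922, 0.5415, -0.6179, 1.0391)
  got <- ks_compare(a, b)
  orc <- oracle_ks(a, b)
  expect_equal(got$statistic, 0.2, tolerance = 1e-12)
  expect_equal(got$statistic, orc$statistic, tolerance = 1e-12)
  expect_equal(got$p_value, orc$p_value, tolerance = 1e-6)

  # oracle agreement on random continuous samples of varying sizes
  set.seed(31)
  for (rep in 1:5) {
    x <- rnorm(sample(10:80, 1)); y <- rnorm(sample(10:80, 1), 0.3)
    g <- ks_compare(x, y); o <- oracle_ks(x, y)
    expect_equal(g$statistic, o$statistic, tolerance = 1e-12)
    # series truncation differs slightly between implementations
    expect_equal(g$p_value, o$p_value, tolerance = 1e-5)
  }

  expect_error(ks_compare(1, c(1, 2)), "at least 2")
})

test_that("Bland-Altman limits of agreement", {
  ref <- c(50, 55, 60, 65)
  same <- bland_altman(ref, ref)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$loa_low, 0)
  expect_equal(same$loa_high, 0)

  # diffs {-2, +2}: mean 0, LOA = +/- 1.96 * sqrt(8)
  ba <- bland_altman(c(48, 57), c(50, 55))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_high, 1.96 * sqrt(8))
  expect_equal(ba$loa_low, -1.96 * sqrt(8))

  # translation equivariance
  shifted <- bland_altman(c(48, 57) + 3.5, c(50, 55))
  expect_equal(shifted$mean_diff, ba$mean_diff + 3.5)
  expect_equal(shifted$loa_low, ba$loa_low + 3.5)
  expect_equal(shifted$loa_high, ba$loa_high + 3.5)

  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("ICC(2,1) matches frozen external reference values", {
  # 6 subjects x 2 raters; reference values computed with an independent
  # two-way random-effects absolute-agreement (single measures) routine
  m <- matrix(c(9, 6, 8, 7, 10, 6, 2, 1, 4, 1, 5, 2), ncol = 2)
  res <- icc_absolute_single(m)
  expect_equal(res$icc, 0.125654, tolerance = 1e-5)
  # reference CIs are published at two decimals; compare at that precision
  expect_lt(abs(res$ci_low - (-0.02)), 0.005)
  expect_lt(abs(res$ci_high - 0.60), 0.005)

  # 8 subjects x 3 raters
  v <- c(50.906, 37.459, 55.363, 57.645, 28.729, 35.218, 53.94, 49.499,
         52.494, 43.297, 60.621, 59.605, 52.724, 63.336, 56.739, 43.561,
         55.842, 42.565, 69.493, 60.209, 58.86, 41.159, 60.193, 46.423)
  m3 <- matrix(v, ncol = 3, byrow = TRUE)
  res3 <- icc_absolute_single(m3)
  expect_equal(res3$icc, 0.180918, tolerance = 1e-5)
  expect_lt(abs(res3$ci_low - (-0.25)), 0.005)
  expect_lt(abs(res3$ci_high - 0.70), 0.005)
})

test_that("ICC(2,1) degenerate and error cases", {
  dup <- cbind(c(5, 7, 9, 11, 13, 15), c(5, 7, 9, 11, 13, 15))
  res <- icc_absolute_single(dup)
  expect_equal(res$icc, 1)
  expect_error(icc_absolute_single(matrix(3, nrow = 6, ncol = 2)),
               "undefined ICC")
  expect_error(icc_absolute_single(matrix(1:8, ncol = 2)), "at least 5")
  expect_error(icc_absolute_single(matrix(1:12, ncol = 1)), "at least 2")
})

test_that("ICC(2,1) agrees with an aov-based variance-components oracle", {
  set.seed(77)
  for (rep in 1:8) {
    n <- sample(6:50, 1)
    k <- sample(2:6, 1)
    subj <- rnorm(n, 0, 2)
    mat <- sapply(seq_len(k), function(j) subj + rnorm(n) + rnorm(1, 0, 0.5))
    expect_equal(icc_absolute_single(mat)$icc, oracle_icc21(mat),
                 tolerance = 1e-8)
  }
})

test_that("independent rater columns give ICC near zero", {
  set.seed(42)
  iccs <- replicate(30, icc_absolute_single(matrix(rnorm(400), ncol = 2))$icc)
  se <- sd(iccs) / sqrt(length(iccs))
  expect_lt(abs(mean(iccs)), 3 * se + 0.01)
})

test_that("error and rank correlation summaries", {
  # diffs {1, 3}
  ec <- error_and_correlation(c(51, 58), c(50, 55))
  expect_equal(ec$mae, 2)
  expect_equal(ec$mse, 5)

  mono <- error_and_correlation(c(1, 2, 3, 4), c(10, 20, 30, 40))
  expect_equal(mono$spearman_rho, 1)
  rev <- error_and_correlation(c(4, 3, 2, 1), c(10, 20, 30, 40))
  expect_equal(rev$spearman_rho, -1)

  # ties: compare with the explicit average-rank oracle
  x <- c(3, 1, 4, 1, 5)
  y <- c(2, 7, 1, 8, 2)
  expect_equal(error_and_correlation(x, y)$spearman_rho,
               oracle_spearman(x, y), tolerance = 1e-12)

  expect_error(error_and_correlation(1, 1), "at least 2")
})

test_that("classification performance on separable and forced cases", {
  rep1 <- classification_performance(c(30, 35, 55, 60), c(1, 1, 0, 0),
                                     n_boot = 200, seed = 3)
  expect_equal(rep1$auc, 1)
  expect_equal(rep1$sensitivity, 1)
  expect_equal(rep1$specificity, 1)

  rep2 <- classification_performance(c(35, 38, 45, 50), c(1, 1, 0, 0),
                                     threshold_hu = 40, n_boot = 200,
                                     seed = 3)
  expect_equal(c(rep2$tp, rep2$fp, rep2$tn, rep2$fn), c(2, 0, 2, 0))

  # CIs contain the point estimates
  expect_true(rep2$auc_ci[1] <= rep2$auc && rep2$auc <= rep2$auc_ci[2])
  expect_true(rep2$sens_ci[1] <= rep2$sensitivity &&
                rep2$sensitivity <= rep2$sens_ci[2])

  expect_error(classification_performance(c(30, 50), c(1, 1)),
               "both classes")
})

test_that("AUC equals all-pairs concordance, also under ties", {
  set.seed(55)
  for (rep in 1:6) {
    n <- sample(20:120, 1)
    scores <- round(rnorm(n, 50, 10))    # rounding forces ties
    labels <- scores + rnorm(n, 0, 12) < 45
    if (!any(labels) || all(labels)) next
    got <- classification_performance(scores, labels, n_boot = 10,
                                      seed = 1)$auc
    expect_equal(got, oracle_auc(-scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC is near chance for shuffled labels", {
  set.seed(99)
  n <- 500
  scores <- rnorm(n, 50, 10)
  labels <- sample(rep(c(TRUE, FALSE), each = n / 2))
  got <- classification_performance(scores, labels, n_boot = 10, seed = 2)$auc
  # null SE of the Mann-Whitney AUC
  se <- sqrt((n / 2 + n / 2 + 1) / (12 * (n / 2) * (n / 2)))
  expect_lt(abs(got - 0.5), 3 * se)
})

test_that("rank AUC matches the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  scores <- rnorm(60, 50, 12)
  labels <- scores + rnorm(60, 0, 10) < 45
  got <- classification_performance(scores, labels, n_boot = 10, seed = 1)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = labels,
                                        predictor = -scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("bootstrap CIs shrink with sample size", {
  width <- function(n, seed) {
    with_seed <- function(s, expr) { set.seed(s); expr }
    dat <- with_seed(seed, {
      sc <- c(rnorm(n / 2, 35, 6), rnorm(n / 2, 55, 6))
      list(sc = sc, lab = rep(c(1, 0), each = n / 2))
    })
    r <- classification_performance(dat$sc, dat$lab, n_boot = 300, seed = 11)
    r$auc_ci[2] - r$auc_ci[1]
  }
  w <- vapply(c(50, 200, 800), width, numeric(1), seed = 21)
  expect_true(w[1] > w[2] && w[2] > w[3])
})

test_that("agreement_report bundles all statistics consistently", {
  set.seed(13)
  ref <- rnorm(40, 56, 11)
  method <- ref + rnorm(40, 0, 2)
  rep <- agreement_report(method, ref)
  expect_equal(rep$bland_altman$mean_diff, mean(method - ref))
  expect_true(rep$bland_altman$loa_low <= rep$bland_altman$mean_diff)
  expect_true(rep$bland_altman$mean_diff <= rep$bland_altman$loa_high)
  expect_gte(rep$errors$mse, rep$errors$mae^2)
  expect_true(rep$icc$icc > 0.9 && rep$icc$icc <= 1)
  expect_true(rep$icc$ci_low <= rep$icc$icc && rep$icc$icc <= rep$icc$ci_high)
})
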