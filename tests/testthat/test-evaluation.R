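test_that("MAPE and signed bias match hand arithmetic", {
  expect_equal(mape(c(100, 200), c(100, 200)), 0)
  expect_equal(mape(c(100, 200), c(110, 180)), 10)
  expect_equal(mape(100, 50), 50)
  expect_equal(mean_bias_percent(c(100, 100), c(110, 90)), 0)
  expect_equal(mape(c(100, 100), c(110, 90)), 10)
  expect_equal(mean_bias_percent(100, 99), -1)
  expect_warning(z <- mape(c(0, 100), c(5, 110)), "excluded")
  expect_equal(z, 10)
  expect_error(suppressWarnings(mape(0, 5)), "no subjects")
})

test_that("MAPE dominates the absolute bias", {
  set.seed(51)
  for (i in 1:20) {
    tr <- runif(8, 500, 5000)
    pr <- tr * runif(8, 0.5, 1.5)
    expect_gte(mape(tr, pr) + 1e-12, abs(mean_bias_percent(tr, pr)))
  }
})

test_that("Spearman correlation is rank-based with average ranks on ties", {
  x <- c(2, 5, 9, 14)
  expect_equal(spearman_rho(x, exp(x)), 1)
  expect_equal(spearman_rho(x, rev(x)), -1)
  expect_equal(spearman_rho(1:4, c(1, 3, 2, 4)), 0.8)
  expect_error(spearman_rho(c(1, 1, 1), 1:3), "constant")
  expect_error(spearman_rho(1:2, 2:1), "n >= 3")
})

test_that("Bland-Altman limits use 1.96 sample SDs", {
  ba0 <- bland_altman(c(10, 20), c(10, 20))
  expect_equal(unlist(ba0[c("mean_diff", "loa_low", "loa_high")]),
               c(mean_diff = 0, loa_low = 0, loa_high = 0))
  ba <- bland_altman(c(100, 100), c(90, 110))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(200))
  expect_equal(ba$loa_high, 1.96 * sqrt(200))
  # translation equivariance
  ba2 <- bland_altman(c(100, 100), c(90, 110) + 7)
  expect_equal(ba2$mean_diff, ba$mean_diff + 7)
  expect_equal(ba2$loa_low, ba$loa_low + 7)
  expect_equal(ba2$loa_high, ba$loa_high + 7)
})

test_that("classification metrics match the hand-computed 2x2 table", {
  perfect <- rep(c("walk", "nonwalk"), 10)
  cm <- classification_metrics(perfect, perfect)
  expect_equal(unlist(cm[c("precision", "recall", "f1", "accuracy",
                           "cohens_kappa")]),
               c(precision = 1, recall = 1, f1 = 1, accuracy = 1,
                 cohens_kappa = 1))
  # TP 40, FN 10, FP 20, TN 30
  truth <- rep(c("walk", "walk", "nonwalk", "nonwalk"), c(40, 10, 20, 30))
  pred <- rep(c("walk", "nonwalk", "walk", "nonwalk"), c(40, 10, 20, 30))
  cm2 <- classification_metrics(truth, pred)
  expect_equal(cm2$precision, 2 / 3)
  expect_equal(cm2$recall, 0.8)
  expect_equal(cm2$accuracy, 0.7)
  expect_equal(cm2$cohens_kappa, 0.4)
  expect_equal(cm2$f1, 2 * (2 / 3) * 0.8 / (2 / 3 + 0.8))
  # constant prediction: chance-level kappa
  expect_equal(classification_metrics(truth, rep("walk", 100))$cohens_kappa, 0)
  # reordering subjects changes nothing
  set.seed(52)
  o <- sample(100)
  cm3 <- classification_metrics(truth[o], pred[o])
  expect_equal(cm3$cohens_kappa, cm2$cohens_kappa)
  # zero denominators are NA with a warning, not 0
  expect_warning(
    cmw <- classification_metrics(rep("nonwalk", 5), rep("nonwalk", 5)),
    "undefined")
  expect_true(is.na(cmw$precision))
})

test_that("agreement_report bundles the per-subject metrics", {
  set.seed(53)
  tr <- runif(6, 1000, 5000)
  pr <- tr * runif(6, 0.9, 1.1)
  ar <- agreement_report(tr, pr)
  expect_equal(ar$mape_percent, mape(tr, pr))
  expect_equal(ar$mean_bias_percent, mean_bias_percent(tr, pr))
  expect_equal(ar$spearman_rho, spearman_rho(tr, pr))
  expect_equal(ar$n_subjects, 6)
  expect_lte(ar$bland_altman$loa_low, ar$bland_altman$mean_diff)
  expect_gte(ar$bland_altman$loa_high, ar$bland_altman$mean_diff)
})
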