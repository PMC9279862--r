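# Concordance and discrimination statistics against hand oracles.

test_that("spearman matches exhaustive hand ranking on a 6-pair toy", {
  pairs <- data.frame(ffr3d = c(0.62, 0.85, 0.74, 0.91, 0.55, 0.79),
                      ffr_ref = c(0.60, 0.88, 0.95, 0.70, 0.58, 0.72))
  # ranks x: 2 5 3 6 1 4; y: 2 5 6 3 1 4; sum d^2 = 18; r = 1 - 108/210
  sp <- spearman_concordance(pairs)
  expect_equal(sp$r, 17 / 35)
  # perfectly monotone and reversed orderings
  mono <- data.frame(ffr3d = (1:6) / 10, ffr_ref = (2:7) / 10)
  expect_equal(spearman_concordance(mono)$r, 1)
  rev <- data.frame(ffr3d = (1:6) / 10, ffr_ref = (7:2) / 10)
  expect_equal(spearman_concordance(rev)$r, -1)
  expect_error(spearman_concordance(
    data.frame(ffr3d = rep(0.5, 5), ffr_ref = (1:5) / 10)), "constant")
})

test_that("bland-altman bias and limits reproduce hand arithmetic", {
  # d = {+0.1, -0.1}: bias 0, sd 0.1414..., LOA about +/- 0.277
  pairs <- data.frame(ffr3d = c(0.8, 0.6), ffr_ref = c(0.7, 0.7))
  ba <- bland_altman(pairs)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, sqrt(0.02), tolerance = 1e-12)
  expect_equal(ba$loa_high, 1.96 * sqrt(0.02))
  expect_equal(ba$loa_low, -1.96 * sqrt(0.02))
  # identical pairs: bias 0, LOA collapse to (0, 0)
  same <- data.frame(ffr3d = c(0.7, 0.8, 0.9), ffr_ref = c(0.7, 0.8, 0.9))
  ba0 <- bland_altman(same)
  expect_equal(c(ba0$bias, ba0$loa_low, ba0$loa_high), c(0, 0, 0))
  # translation equivariance: constant shift moves bias, not the width
  pairs2 <- toy_pairs()
  shifted <- transform(pairs2, ffr3d = ffr3d + 0.03)
  ba1 <- bland_altman(pairs2)
  ba2 <- bland_altman(shifted)
  expect_equal(ba2$bias, ba1$bias + 0.03)
  expect_equal(ba2$loa_high - ba2$loa_low, ba1$loa_high - ba1$loa_low)
})

test_that("limits of agreement cover about 95% of Gaussian differences", {
  set.seed(52)
  n <- 4000
  ref <- runif(n, 0.4, 0.9)
  pairs <- data.frame(ffr3d = pmin(1, pmax(0.01, ref + rnorm(n, 0, 0.03))),
                      ffr_ref = ref)
  ba <- bland_altman(pairs)
  d <- pairs$ffr3d - pairs$ffr_ref
  cover <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_equal(cover, 0.95, tolerance = 0.02)
})

test_that("paired mean comparison matches the closed-form t oracle", {
  pairs <- data.frame(ffr3d = c(0.80, 0.74, 0.69, 0.91, 0.62),
                      ffr_ref = c(0.76, 0.75, 0.66, 0.85, 0.61))
  d <- pairs$ffr3d - pairs$ffr_ref
  tstat <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(compare_means(pairs), 2 * pt(-abs(tstat), df = 4))
  # symmetric differences: zero mean difference, p = 1
  sym <- data.frame(ffr3d = c(0.68, 0.72, 0.68, 0.72),
                    ffr_ref = c(0.70, 0.70, 0.70, 0.70))
  expect_equal(compare_means(sym), 1)
  ident <- data.frame(ffr3d = c(0.7, 0.8), ffr_ref = c(0.7, 0.8))
  expect_error(compare_means(ident), "degenerate")
})

test_that("AUC equals exhaustive concordant-pair counting", {
  pairs <- toy_pairs()
  rep <- roc_analysis(pairs)
  oracle <- auc_by_counting(pairs$ffr3d, pairs$ffr_ref <= 0.80)
  expect_equal(rep$auc, oracle)
  # and agrees with an independent implementation
  proc_auc <- as.numeric(pROC::auc(pROC::roc(
    response = pairs$ffr_ref <= 0.80, predictor = pairs$ffr3d,
    levels = c(FALSE, TRUE), direction = ">", quiet = TRUE)))
  expect_equal(rep$auc, proc_auc)
})

test_that("AUC equals Mann-Whitney counting on random instances", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    ref <- runif(n, 0.5, 1)
    est <- pmin(1, pmax(0.01,
      ref + rnorm(n, 0, 0.1) + sample(c(0, 0.02), n, replace = TRUE)))
    est <- round(est, 2)  # force some ties
    if (length(unique(ref <= 0.8)) < 2) next
    rep <- roc_analysis(data.frame(ffr3d = est, ffr_ref = ref))
    expect_equal(rep$auc, auc_by_counting(est, ref <= 0.8))
  }
})

test_that("ROC degenerate and separated cases behave", {
  # perfectly separated: AUC 1 and a threshold with sens = spec = 1
  sep <- data.frame(ffr3d = c(0.5, 0.55, 0.6, 0.85, 0.9, 0.95),
                    ffr_ref = c(0.6, 0.7, 0.75, 0.85, 0.9, 0.95))
  r <- roc_analysis(sep)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  # estimate carries no information: all equal -> AUC 1/2
  flat <- data.frame(ffr3d = rep(0.7, 8),
                     ffr_ref = c(0.6, 0.7, 0.75, 0.78, 0.85, 0.9, 0.88, 0.95))
  expect_equal(roc_analysis(flat)$auc, 0.5)
  one <- data.frame(ffr3d = runif(5, 0.2, 0.9), ffr_ref = rep(0.9, 5))
  expect_error(roc_analysis(one), "single class")
})

test_that("youden threshold and exact intervals recompute from the matrix", {
  pairs <- toy_pairs()
  r <- roc_analysis(pairs)
  pos <- pairs$ffr_ref <= 0.80
  # dichotomization consistency at the chosen threshold
  sens <- mean(pairs$ffr3d[pos] <= r$optimal_threshold)
  spec <- mean(pairs$ffr3d[!pos] > r$optimal_threshold)
  expect_equal(r$sensitivity, sens)
  expect_equal(r$specificity, spec)
  expect_equal(r$youden, sens + spec - 1)
  # no other threshold has larger J
  js <- vapply(unique(pairs$ffr3d), function(t)
    mean(pairs$ffr3d[pos] <= t) + mean(pairs$ffr3d[!pos] > t) - 1,
    numeric(1))
  expect_equal(r$youden, max(js))
  # Clopper-Pearson CIs against direct binomial tail inversion
  expect_equal(r$sensitivity_ci,
               clopper_pearson(round(sens * sum(pos)), sum(pos)),
               tolerance = 1e-6)
  expect_equal(r$specificity_ci,
               clopper_pearson(round(spec * sum(!pos)), sum(!pos)),
               tolerance = 1e-6)
  # CIs contain the point estimates; AUC CI contains the AUC
  expect_true(r$sensitivity_ci[1] <= sens && sens <= r$sensitivity_ci[2])
  expect_true(r$auc_ci_low <= r$auc && r$auc <= r$auc_ci_high)
})

test_that("concordance report bundles the pieces coherently", {
  pairs <- toy_pairs()
  rep <- concordance_report(pairs)
  expect_equal(rep$n, 10)
  expect_equal(rep$bias, mean(pairs$ffr3d - pairs$ffr_ref))
  expect_equal(rep$loa_high - rep$bias, 1.96 * rep$sd_diff)
  expect_equal(rep$mean_ffr3d, mean(pairs$ffr3d))
  expect_true(rep$loa_low <= rep$bias && rep$bias <= rep$loa_high)
})
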