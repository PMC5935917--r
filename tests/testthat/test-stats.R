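test_that("Pearson correlation matches hand computation and the stats oracle", {
  expect_equal(pearson_r(1:10, 1:10)$r, 1)
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 5))$r, -0.5)
  set.seed(4)
  for (i in 1:5) {
    x <- rnorm(25); y <- 0.4 * x + rnorm(25)
    ref <- cor.test(x, y)
    got <- pearson_r(x, y)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("Spearman correlation uses mid-ranks and tracks monotone relations", {
  x <- seq(-2, 2, length.out = 20)
  expect_equal(spearman_r(x, exp(x))$r, 1)
  expect_equal(spearman_r(x, rev(x))$r, -1)
  # ties: equals the Pearson correlation of averaged ranks (mid-rank oracle)
  xt <- c(1, 2, 2, 3, 3, 3, 4)
  yt <- c(2, 1, 3, 3, 5, 4, 4)
  expect_equal(spearman_r(xt, yt)$r,
               cor(rank(xt), rank(yt)), tolerance = 1e-12)
  expect_equal(spearman_r(xt, yt)$r,
               unname(cor.test(xt, yt, method = "spearman", exact = FALSE)$estimate),
               tolerance = 1e-12)
  # coincides with Pearson under a strict linear relation
  expect_equal(spearman_r(x, 2 * x + 1)$r, pearson_r(x, 2 * x + 1)$r)
})

test_that("Welch t-test matches hand computation and the stats oracle", {
  same <- t_test_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(abs(t_test_two_sample(c(1, 2, 3), c(4, 5, 6))$t), 3.6742,
               tolerance = 1e-4)
  set.seed(6)
  a <- rnorm(12); b <- rnorm(17, 0.5, 2)
  ref <- t.test(a, b)
  got <- t_test_two_sample(a, b)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-9)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
})

test_that("ROC AUC equals the pairwise enumeration oracle and handles extremes", {
  expect_equal(roc_curve(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 0, 0, 0), "lower")$auc, 1)
  set.seed(8)
  for (i in 1:10) {
    n <- sample(8:20, 1)
    scores <- sample(1:6, n, replace = TRUE)  # forces ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    # brute force: P(case more disease-ward than control) + 1/2 P(tie)
    cs <- scores[labels]; ct <- scores[!labels]
    oracle <- mean(outer(cs, ct, function(a, b) (a < b) + 0.5 * (a == b)))
    expect_equal(roc_curve(scores, labels, "lower")$auc, oracle)
    if (requireNamespace("pROC", quietly = TRUE)) {
      expect_equal(roc_curve(scores, labels, "lower")$auc,
                   as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                  direction = ">", quiet = TRUE))))
    }
  }
  # labels independent of scores -> AUC near 1/2
  set.seed(9)
  expect_equal(roc_curve(rnorm(4000), rbinom(4000, 1, 0.5), "lower")$auc, 0.5,
               tolerance = 0.03)
  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both")
})

test_that("AUC is invariant to strictly monotone score transforms", {
  set.seed(10)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.4) == 1
  ref <- roc_curve(scores, labels, "lower")$auc
  expect_equal(roc_curve(exp(scores), labels, "lower")$auc, ref)
  expect_equal(roc_curve(scores^3 + 5 * scores, labels, "lower")$auc, ref)
  # flipping both sign and orientation leaves the AUC unchanged
  expect_equal(roc_curve(-scores, labels, "higher")$auc, ref)
})

test_that("sensitivity/specificity at a cutoff follow the declared convention", {
  scores <- c(1, 2, 3, 4)
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(sens_spec_at_cutoff(scores, labels, 0.5, "lower"),
               list(sensitivity = 0, specificity = 1))
  expect_equal(sens_spec_at_cutoff(scores, labels, 99, "lower"),
               list(sensitivity = 1, specificity = 0))
  expect_equal(sens_spec_at_cutoff(scores, labels, 2.5, "lower"),
               list(sensitivity = 1, specificity = 1))
})

test_that("the stored Youden cutoff maximizes J and lies on the curve", {
  set.seed(12)
  for (i in 1:8) {
    scores <- round(c(rnorm(20, 0), rnorm(15, 1)), 1)
    labels <- rep(c(TRUE, FALSE), c(20, 15))
    roc <- roc_curve(scores, labels, "lower")
    jmax <- roc$sensitivity + roc$specificity - 1
    # exhaustive threshold scan: no cutoff does better
    for (cu in sort(unique(c(scores - 0.05, scores + 0.05)))) {
      ss <- sens_spec_at_cutoff(scores, labels, cu, "lower")
      expect_lte(ss$sensitivity + ss$specificity - 1, jmax + 1e-12)
    }
    # stored operating point is on the curve
    expect_true(any(abs(roc$points$tpr - roc$sensitivity) < 1e-12 &
                    abs(1 - roc$points$fpr - roc$specificity) < 1e-12))
  }
  # perfect separation: returned cutoff splits the groups with J = 1
  roc <- roc_curve(c(1, 2, 3, 10, 11, 12), rep(c(TRUE, FALSE), each = 3), "lower")
  expect_gt(roc$cutoff, 3)
  expect_lt(roc$cutoff, 10)
  expect_equal(roc$sensitivity + roc$specificity - 1, 1)
})

test_that("DeLong paired AUC comparison agrees with jackknife and pROC oracles", {
  roc_of <- function(s, l) roc_curve(s, l, "lower")
  set.seed(14)
  labels <- rep(c(TRUE, FALSE), c(18, 15))
  s1 <- rnorm(33) - labels
  s2 <- 0.7 * s1 + 0.3 * rnorm(33)
  r1 <- roc_of(s1, labels); r2 <- roc_of(s2, labels)
  expect_equal(auc_compare_z(r1, r1)$z, 0)
  cmp <- auc_compare_z(r1, r2)
  # delete-one jackknife SE of the AUC difference
  n <- length(labels)
  theta <- vapply(seq_len(n), function(i) {
    roc_of(s1[-i], labels[-i])$auc - roc_of(s2[-i], labels[-i])$auc
  }, numeric(1))
  se_jack <- sqrt((n - 1) / n * sum((theta - mean(theta))^2))
  expect_equal(cmp$se_diff, se_jack, tolerance = 0.1)
  if (requireNamespace("pROC", quietly = TRUE)) {
    ref <- pROC::roc.test(pROC::roc(labels, s1, direction = ">", quiet = TRUE),
                          pROC::roc(labels, s2, direction = ">", quiet = TRUE),
                          method = "delong", paired = TRUE)
    expect_equal(abs(cmp$z), abs(unname(ref$statistic)), tolerance = 1e-9)
    expect_equal(cmp$p, ref$p.value, tolerance = 1e-9)
  }
  expect_error(auc_compare_z(r1, roc_of(s2[-1], labels[-1])), "unpaired")
})

test_that("replicate mixture cohorts reproduce the published group-level statistics", {
  set.seed(16)
  reps <- 60
  stats <- vapply(seq_len(reps), function(i) {
    coh <- simulate_cohort(cad_group_specs())
    cad <- coh$cad
    c(r = pearson_r(coh$pav, coh$fmd_percent)$r,
      p = t_test_two_sample(coh$pav[cad], coh$pav[!cad])$p)
  }, numeric(2))
  expect_equal(mean(stats["r", ]), 0.69, tolerance = 0.03)
  # CAD vs non-CAD PAV difference significant in nearly every replicate
  expect_gte(mean(stats["p", ] < 0.01), 0.95)
})
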