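test_that("ROC with the le-positivity rule handles canonical cases", {
  # perfect separation: transformed strictly below stable
  r <- roc_analysis(c(0.5, 0.7, 0.9, 1.1, 1.3, 1.5), c(1, 1, 1, 0, 0, 0))
  expect_equal(r$auc, 1.0)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_equal(r$cutoff, 1.0)          # midpoint between 0.9 and 1.1
  expect_equal(unname(r$confusion), c(3, 0, 3, 0))
  expect_equal(r$ppv, 100)
  # confusion counts partition the classes on random instances
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(8:25, 1)
    l <- c(1, 0, rbinom(n - 2, 1, 0.4))
    v <- round(rnorm(n, 1, 0.3), 2)
    rr <- roc_analysis(v, l)
    expect_equal(rr$confusion[["TP"]] + rr$confusion[["FN"]], sum(l == 1))
    expect_equal(rr$confusion[["TN"]] + rr$confusion[["FP"]], sum(l == 0))
    expect_equal(rr$sensitivity,
                 100 * rr$confusion[["TP"]] / sum(l == 1), tolerance = 1e-3)
  }
  expect_error(roc_analysis(c(1, 2), c(1, 1)), "both classes")
  expect_error(roc_analysis(c(1, NA), c(1, 0)), "finite")
})

test_that("AUC is invariant and the cutoff equivariant under positive scaling", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 20
    l <- c(1, 0, rbinom(n - 2, 1, 0.4))
    v <- rnorm(n, 1, 0.3)
    k <- runif(1, 0.1, 10)
    r1 <- roc_analysis(v, l)
    r2 <- roc_analysis(k * v, l)
    expect_equal(r2$auc, r1$auc, tolerance = 1e-12)
    expect_equal(r2$sensitivity, r1$sensitivity)
    expect_equal(r2$specificity, r1$specificity)
    expect_equal(r2$cutoff, k * r1$cutoff, tolerance = 1e-9)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  co <- simulate_cohort(cohort_spec(seed = 7))
  for (p in c("ad_min", "md_min", "rd_min")) {
    mine <- roc_analysis(co[[p]], co$label)
    ref <- pROC::roc(co$label, co[[p]], direction = ">", quiet = TRUE)
    expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  }
})

test_that("reversing the positivity direction maps AUC to 1 - AUC", {
  set.seed(9)
  v <- rnorm(30, 1, 0.3)
  l <- c(1, 0, rbinom(28, 1, 0.4))
  a <- roc_analysis(v, l)$auc
  expect_equal(roc_analysis(-v, l)$auc, 1 - a, tolerance = 1e-12)
})

test_that("PPV follows from the confusion counts", {
  expect_equal(ppv_from_confusion(c(TP = 17, FP = 4, TN = 25, FN = 1)),
               100 * 17 / 21)
  expect_equal(round(ppv_from_confusion(c(TP = 17, FP = 4)), 1), 81.0)
  expect_equal(ppv_from_confusion(c(TP = 5, FP = 0)), 100)
  expect_equal(ppv_from_confusion(c(TP = 7, FP = 7)), 50)
  expect_error(ppv_from_confusion(c(TP = 0, FP = 0)), "undefined")
})

test_that("weighted kappa matches hand computation and its symmetries", {
  # contingency ((20,5),(5,20)): p_o = 0.8, p_e = 0.5, kappa = 0.6
  r1 <- rep(c(0, 0, 1, 1), c(20, 5, 5, 20))
  r2 <- rep(c(0, 1, 0, 1), c(20, 5, 5, 20))
  k <- weighted_kappa(r1, r2)
  expect_equal(k$kappa, 0.6)
  expect_equal(k$band_label, "moderate")
  # binary: linear and quadratic weights coincide with unweighted kappa
  expect_equal(weighted_kappa(r1, r2, "quadratic")$kappa, 0.6)
  skip_if_not_installed("e1071")
  expect_equal(k$kappa, e1071::classAgreement(table(r1, r2))$kappa,
               tolerance = 1e-12)
})

test_that("kappa is rater-symmetric and stable under tandem permutation", {
  set.seed(5)
  r1 <- sample(1:3, 60, replace = TRUE)
  r2 <- sample(1:3, 60, replace = TRUE)
  for (w in c("linear", "quadratic")) {
    a <- weighted_kappa(r1, r2, w)$kappa
    expect_equal(weighted_kappa(r2, r1, w)$kappa, a, tolerance = 1e-12)
    perm <- sample(60)
    expect_equal(weighted_kappa(r1[perm], r2[perm], w)$kappa, a,
                 tolerance = 1e-12)
  }
  # perfect agreement and degenerate marginals
  expect_equal(weighted_kappa(r1, r1)$kappa, 1)
  expect_error(weighted_kappa(rep(1, 10), rep(1, 10)), "degenerate")
})

test_that("ordinal disagreements are penalised by category distance", {
  # one far disagreement vs one near disagreement on a 3-level scale
  base1 <- c(rep(1, 10), rep(2, 10), rep(3, 10))
  near <- base1; near[1] <- 2
  far <- base1; far[1] <- 3
  k_near <- weighted_kappa(base1, near, "quadratic")$kappa
  k_far <- weighted_kappa(base1, far, "quadratic")$kappa
  expect_gt(k_near, k_far)
})

test_that("two-group ANOVA equals the pooled-variance t-test squared", {
  set.seed(12)
  for (rep in 1:10) {
    co <- simulate_cohort(cohort_spec(seed = rep))
    g <- group_compare(co)
    tt <- t.test(ad_min ~ label, data = co, var.equal = TRUE)
    expect_equal(unique(g$f_statistic[g$parameter == "ad_min"]),
                 unname(tt$statistic^2), tolerance = 1e-10)
    expect_equal(unique(g$p_raw[g$parameter == "ad_min"]),
                 tt$p.value, tolerance = 1e-10)
  }
})

test_that("group comparison reports the study-table layout with Bonferroni", {
  co <- simulate_cohort(cohort_spec(seed = 2))
  g <- group_compare(co)
  expect_equal(nrow(g), 6L)
  expect_setequal(unique(g$parameter), c("ad_min", "md_min", "rd_min"))
  expect_true(all(g$p_bonferroni >= g$p_raw - 1e-15))
  expect_true(all(g$p_bonferroni <= pmin(1, 3 * g$p_raw) + 1e-15))
  expect_true(all(g$f_statistic >= 0))
  expect_true(all(g$ci_lo < g$mean & g$mean < g$ci_hi))
  # identical group values: F = 0, p = 1
  co2 <- data.frame(subject_id = sprintf("S%d", 1:8),
                    label = rep(c(0L, 1L), each = 4L),
                    ad_min = rep(c(1, 2, 3, 4), 2))
  gf <- group_compare(co2, "ad_min")
  expect_equal(unique(gf$f_statistic), 0, tolerance = 1e-12)
  expect_equal(unique(gf$p_raw), 1, tolerance = 1e-12)
})
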