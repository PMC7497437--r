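test_that("FFR labeling and QCA eligibility honor their boundaries", {
  expect_true(label_significant(data.frame(ffr = 0.80)))
  expect_false(label_significant(0.81))
  expect_equal(sum(label_significant(rep(1.0, 5))), 0)
  expect_error(label_significant(c(0.7, NA)), "missing")
  expect_equal(ffr_eligible(c(30, 69, 29.9, 69.1, 50)),
               c(TRUE, TRUE, FALSE, FALSE, TRUE))
})

test_that("Spearman correlation matches the hand rank computation", {
  # d = (0, 1, -1, 1) -> 1 - 6*4/(4*15) = 0.6
  expect_equal(spearman_r(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  x <- c(0.2, 1.4, 2.2, 3.1, 7.0)
  expect_equal(spearman_r(x, exp(x)), 1)
  expect_equal(spearman_r(x, -exp(x)), -1)
  set.seed(3); a <- rnorm(30); b <- a + rnorm(30)
  expect_equal(spearman_r(a, -b), -spearman_r(a, b))
  expect_equal(spearman_r(a, b), cor(a, b, method = "spearman"))
  expect_warning(r <- spearman_r(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
})

test_that("pooled t test separates the printed perfusion groups", {
  a <- fixed_moments(20, 1.38, 0.27, seed = 10)
  b <- fixed_moments(19, 1.74, 0.35, seed = 11)
  out <- two_sample_t(a, b)
  expect_lt(out$p, 0.05)
  expect_lt(out$t, 0)
  swapped <- two_sample_t(b, a)
  expect_equal(swapped$t, -out$t)
  expect_equal(swapped$p, out$p)
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_warning(two_sample_t(c(1, 1), c(1, 1)), "variance")
})

test_that("AUC pair counting handles ties and perfect separation", {
  r <- roc_auc(c(0.6, 0.7, 0.9, 1.0), c(TRUE, TRUE, FALSE, FALSE),
               direction = "lower")
  expect_equal(r$auc, 1)
  r2 <- roc_auc(c(1, 1, 2, 2), c(TRUE, FALSE, TRUE, FALSE),
                direction = "lower")
  expect_equal(r2$auc, 0.5)
  # exhaustive pair counting oracle on a random tied instance
  set.seed(8)
  s <- sample(1:6, 40, replace = TRUE)
  lab <- runif(40) < 0.4
  pairs <- outer(s[lab], s[!lab], function(p, n) (p < n) + 0.5 * (p == n))
  expect_equal(roc_auc(s, lab, "lower")$auc, mean(pairs))
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("pair-counting AUC equals the trapezoidal ROC area", {
  set.seed(41)
  for (i in 1:300) {
    n <- sample(6:60, 1)
    ties <- sample(c(TRUE, FALSE), 1)
    s <- if (ties) sample(1:8, n, replace = TRUE) else rnorm(n)
    lab <- runif(n) < runif(1, 0.2, 0.8)
    if (!any(lab) || all(lab)) next
    r <- roc_auc(s, lab, sample(c("lower", "higher"), 1))
    expect_equal(roc_auc_trap <- roc_trapezoid_area(r), r$auc,
                 tolerance = 1e-12)
  }
})

test_that("AUC and ROC agree with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (i in 1:20) {
    s <- round(rnorm(40, 1.5, 0.4), 2)
    lab <- runif(40) < 0.5
    if (!any(lab) || all(lab)) next
    mine <- roc_auc(s, lab, "lower")$auc
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = lab, predictor = s, direction = ">", quiet = TRUE)))
    expect_equal(mine, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("Youden cutoff maximizes J and lands inside the separation gap", {
  r <- roc_auc(c(0.6, 0.7, 0.75, 0.85, 0.9), c(TRUE, TRUE, TRUE, FALSE, FALSE),
               direction = "lower")
  y <- youden_cutoff(r)
  expect_equal(y$youden, 1)
  expect_gt(y$cutoff, 0.75)
  expect_lte(y$cutoff, 0.85)
  expect_equal(y$cutoff, 0.8)
  # exhaustive threshold-scan oracle on a random instance
  set.seed(19)
  s <- rnorm(50); lab <- runif(50) < 0.45
  r2 <- roc_auc(s, lab, "lower")
  y2 <- youden_cutoff(r2)
  grid <- sort(unique(s))
  js <- vapply(grid, function(t0)
    mean(s[lab] <= t0) + mean(s[!lab] > t0) - 1, numeric(1))
  expect_equal(y2$youden, max(js))
  # re-applying the cutoff reproduces the reported operating point
  pred <- predict_at_cutoff(s, y2$cutoff, "lower")
  dm <- diagnostic_metrics(pred, lab)
  expect_equal(dm$sens[["est"]] / 100, y2$sens)
  expect_equal(dm$spec[["est"]] / 100, y2$spec)
  # J is invariant under monotone transforms of the scores
  r3 <- roc_auc(exp(s), lab, "lower")
  expect_equal(youden_cutoff(r3)$youden, y2$youden)
})

test_that("diagnostic proportions reproduce the truncated Wald intervals", {
  # sensitivity 19/20 -> 95 (85-100)
  labels <- rep(c(TRUE, FALSE), c(20, 19))
  pred <- c(rep(TRUE, 19), FALSE, rep(FALSE, 17), TRUE, TRUE)
  dm <- diagnostic_metrics(pred, labels)
  expect_equal(dm$sens[["est"]], 95)
  expect_equal(round(dm$sens[["lo"]]), 85)
  expect_equal(dm$sens[["hi"]], 100)
  # specificity 17/19 -> 89.5, CI rounding to (76, 100)
  expect_equal(dm$spec[["est"]], 100 * 17 / 19)
  expect_equal(round(dm$spec[["est"]]), 89)
  expect_equal(round(dm$spec[["lo"]]), 76)
  expect_equal(dm$spec[["hi"]], 100)
  # all correct -> degenerate CIs at 100
  perfect <- diagnostic_metrics(labels, labels)
  for (m in list(perfect$sens, perfect$spec, perfect$ppv, perfect$npv))
    expect_equal(unname(m), c(100, 100, 100))
  # undefined predictive value flagged
  expect_warning(dm0 <- diagnostic_metrics(rep(FALSE, 10),
                                           rep(c(TRUE, FALSE), 5)), "empty")
  expect_true(is.na(dm0$ppv[["est"]]))
})

test_that("DeLong comparison is null for identical scores and matches pROC", {
  set.seed(23)
  s <- rnorm(30); lab <- runif(30) < 0.5
  same <- compare_auc_paired(s, s, lab)
  expect_equal(same$diff, 0)
  expect_equal(same$p, 1)
  s2 <- s + rnorm(30, sd = 0.6)
  out <- compare_auc_paired(s, s2, lab)
  expect_equal(out$auc_a, roc_auc(s, lab, "lower")$auc)
  expect_equal(out$auc_b, roc_auc(s2, lab, "lower")$auc)
  skip_if_not_installed("pROC")
  ra <- pROC::roc(response = lab, predictor = s, direction = ">", quiet = TRUE)
  rb <- pROC::roc(response = lab, predictor = s2, direction = ">", quiet = TRUE)
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(out$p, ref$p.value, tolerance = 1e-9)
})

test_that("paired DeLong p matches pROC across random small instances", {
  skip_if_not_installed("pROC")
  set.seed(35)
  for (k in 1:10) {
    n <- sample(c(12, 20, 39), 1)
    lab <- runif(n) < 0.5
    if (!any(lab) || all(lab)) next
    a <- ifelse(lab, rnorm(n, 1.35, 0.3), rnorm(n, 1.75, 0.35))
    b <- a + rnorm(n, sd = 0.3)
    out <- compare_auc_paired(a, b, lab)
    ra <- pROC::roc(response = lab, predictor = a, direction = ">", quiet = TRUE)
    rb <- pROC::roc(response = lab, predictor = b, direction = ">", quiet = TRUE)
    ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    expect_equal(out$p, ref$p.value, tolerance = 1e-9)
    expect_equal(out$diff, as.numeric(ref$estimate[1] - ref$estimate[2]),
                 tolerance = 1e-12)
  }
})

test_that("ICC(2,1) matches the mean-squares oracle and penalizes rater bias", {
  m <- cbind(c(9, 6, 8, 7, 10), c(2, 1, 4, 1, 5))
  # independent route: two-way ANOVA mean squares via aov()
  df <- data.frame(y = c(m), subj = factor(rep(1:5, 2)),
                   rater = factor(rep(1:2, each = 5)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc_ref <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 5)
  expect_equal(icc_two_rater(m), icc_ref, tolerance = 1e-12)
  # identical raters agree perfectly
  expect_equal(icc_two_rater(cbind(1:5, 1:5)), 1)
  # absolute agreement penalizes a constant shift
  set.seed(6); x <- rnorm(20, 10, 2)
  base <- icc_two_rater(cbind(x, x + rnorm(20, sd = 0.3)))
  shifted <- icc_two_rater(cbind(x, x + rnorm(20, sd = 0.3) + 3))
  expect_lt(shifted, base)
  expect_warning(icc_two_rater(cbind(rep(1, 4), rep(1, 4))), "variance")
})

test_that("CV percent and its CI behave as stated", {
  out <- cv_percent(fixed_moments(39, 1.55, 0.36, seed = 40))
  expect_equal(out$cv, 100 * 0.36 / 1.55, tolerance = 1e-9)
  expect_equal(out$cv, 23.2, tolerance = 0.05)
  expect_true(out$lo < out$cv && out$cv < out$hi)
  z <- cv_percent(c(2, 2, 2))
  expect_equal(z$cv, 0)
  expect_equal(z$lo, 0)
  expect_equal(z$hi, 0)
  set.seed(12)
  v <- rlnorm(25, 0, 0.4)
  expect_equal(cv_percent(3.7 * v)$cv, cv_percent(v)$cv, tolerance = 1e-12)
  expect_error(cv_percent(c(-5, 1, 1)), "positive")
})

test_that("binormal AUC links the group summaries to the printed AUC", {
  expect_equal(binormal_auc(1, 1, 1, 2), 0.5)
  expect_equal(round(binormal_auc(1.38, 0.27, 1.74, 0.35), 2), 0.79)
  expect_equal(binormal_auc(1.38, 0.27, 1.74, 0.35),
               binormal_auc(1.74, 0.35, 1.38, 0.27))
  # Monte-Carlo cross-check of the closed form
  set.seed(55)
  x <- rnorm(200000, 1.38, 0.27); y <- rnorm(200000, 1.74, 0.35)
  expect_equal(mean(x < y) , binormal_auc(1.38, 0.27, 1.74, 0.35),
               tolerance = 0.005)
})

test_that("vessel-level AUCs center on the binormal values across replicates", {
  aucs <- sapply(1:60, function(s) {
    tab <- simulate_vessel_table(20, 19, seed = 1000 + s)
    lab <- label_significant(tab)
    c(mbf = roc_auc(tab$mbf, lab, "lower")$auc,
      qpr = roc_auc(tab$qpr, lab, "lower")$auc)
  })
  expect_equal(mean(aucs["mbf", ]), binormal_auc(1.38, 0.27, 1.74, 0.35),
               tolerance = 0.05)
  # QPR discriminates better than MBF in most replicates, echoing the study
  expect_gt(mean(aucs["qpr", ] > aucs["mbf", ]), 0.5)
})
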