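# Metrics, splitting, ROC, clinical metrics, non-inferiority test.

test_that("mse and r2 reproduce hand-computed values", {
  y <- c(0, 1, 2, 3); yh <- c(0, 1, 2, 2)
  expect_equal(ecg_mse(y, yh), 0.25)       # SS_res 1 over 4 samples
  expect_equal(ecg_r2(y, yh), 80)          # 1 - 1/5
  expect_equal(ecg_mse(y, y), 0)
  expect_equal(ecg_r2(y, y), 100)
  expect_equal(ecg_r2(y, rep(mean(y), 4)), 0)
  expect_equal(ecg_mse(y, y + 0.1), 0.01)
  expect_error(ecg_mse(1:4, 1:5), "matching shapes")
})

test_that("r2 handles zero-variance leads and affine invariance", {
  y <- rbind(a = c(1, 1, 1, 1), b = c(0, 1, 2, 3))
  yh <- rbind(a = c(1, 1, 1, 1), b = c(0, 1, 2, 2))
  expect_warning(v <- ecg_r2(y, yh), "zero-variance")
  expect_equal(v, 80)
  # invariance under simultaneous affine transform of y and yhat
  set.seed(31)
  yy <- rnorm(50); hh <- yy + rnorm(50, sd = 0.3)
  expect_equal(ecg_r2(yy, hh), ecg_r2(3.2 * yy - 1, 3.2 * hh - 1))
  expect_equal(ecg_r2(yy, hh), ecg_r2(-2 * yy + 5, -2 * hh + 5))
})

test_that("confidence halfwidths follow the normal approximation", {
  expect_equal(aggregate_with_ci(rep(3, 10))$halfwidth, 0)
  x <- rnorm(100); x <- (x - mean(x)) / sd(x)  # sd exactly 1
  expect_equal(aggregate_with_ci(x)$halfwidth, qnorm(0.975) / 10,
               tolerance = 1e-12)
  expect_error(aggregate_with_ci(1), "at least two")
})

test_that("halfwidth is close to a bootstrap for a skewed sample", {
  set.seed(42)
  x <- rexp(500)^1.5
  hw <- aggregate_with_ci(x)$halfwidth
  boot <- replicate(10000, mean(sample(x, replace = TRUE)))
  hw_boot <- (quantile(boot, 0.975) - quantile(boot, 0.025)) / 2
  expect_lt(abs(hw - hw_boot) / hw_boot, 0.10)
})

test_that("trapezoidal AUC equals brute-force pair counting", {
  pair_auc <- function(y, s) {
    pos <- s[y]; neg <- s[!y]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(7)
  for (i in 1:100) {
    y <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c(TRUE, FALSE)
    s <- sample(round(runif(30, 0, 1), 2))  # rounded scores force ties
    expect_equal(roc_auc(y, s)$auc, pair_auc(y, s), tolerance = 1e-12)
  }
})

test_that("AUC conventions: separation, ties, reversal, monotone invariance", {
  y <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(roc_auc(y, c(rep(1, 5), rep(0, 5)))$auc, 1)
  expect_equal(roc_auc(y, rep(0.3, 10))$auc, 0.5)
  set.seed(8)
  s <- runif(10)
  expect_equal(roc_auc(y, s)$auc + roc_auc(y, -s)$auc, 1)
  expect_equal(roc_auc(y, s)$auc, roc_auc(y, exp(5 * s))$auc)
  expect_error(roc_auc(rep(TRUE, 4), runif(4)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  y <- sample(c(TRUE, FALSE), 60, replace = TRUE)
  s <- runif(60) + 0.5 * y
  expect_equal(roc_auc(y, s)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("clinical metrics score indeterminate calls as incorrect", {
  truth <- c(TRUE, TRUE, FALSE, FALSE)
  cm <- clinical_metrics(truth, c("positive", "positive", "negative",
                                  "negative"))
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 1)
  expect_equal(cm$accuracy, 1)
  cm2 <- clinical_metrics(truth, rep("negative", 4))
  expect_equal(cm2$sensitivity, 0)
  expect_equal(cm2$specificity, 1)
  expect_equal(cm2$accuracy, 0.5)
  cm3 <- clinical_metrics(truth, c("indeterminate", "positive",
                                   "indeterminate", "negative"))
  expect_equal(cm3$sensitivity, 0.5)
  expect_equal(cm3$specificity, 0.5)
  expect_equal(cm3$accuracy, 0.5)
})

test_that("the printed reader-study accuracy reproduces its halfwidth", {
  # accuracy 84.6% of n = 238 -> halfwidth ~ 4.6 percentage points
  n <- 238
  k <- round(0.846 * n)
  truth <- rep(c(TRUE, FALSE), length.out = n)
  calls <- ifelse(seq_len(n) <= k,
                  ifelse(truth[seq_len(n) <= k][seq_len(k)], "positive",
                         "negative"),
                  "indeterminate")
  calls <- ifelse(seq_len(n) <= k, ifelse(truth, "positive", "negative"),
                  "indeterminate")
  cm <- clinical_metrics(truth, calls)
  expect_equal(cm$accuracy, k / n, tolerance = 1e-12)
  expect_equal(cm$accuracy_halfwidth, 0.046, tolerance = 0.02)
})

test_that("non-inferiority z-test matches its closed form and boundaries", {
  # null boundary: p_new exactly margin below p_ref
  r <- noninferiority_z(0.8, 1000, 0.7, 1000, margin = 0.10)
  expect_equal(r$z, 0)
  expect_equal(r$one_sided_p, 0.5)
  r2 <- noninferiority_z(0.8, 1e6, 0.8, 1e6, margin = 0)
  expect_equal(r2$one_sided_p, 0.5)
  # closed form check
  r3 <- noninferiority_z(0.846, 238, 0.814, 238, margin = 0.10)
  v <- 0.846 * 0.154 / 238 + 0.814 * 0.186 / 238
  expect_equal(r3$z, (0.814 - 0.846 + 0.1) / sqrt(v))
  expect_equal(r3$one_sided_p, 1 - pnorm(r3$z))
  expect_error(noninferiority_z(0, 5, 0, 5), "zero variance")
})

test_that("grouped split never separates an individual and stratifies labels", {
  set.seed(17)
  manifest <- data.frame(
    record_id = sprintf("r%04d", 1:1000),
    individual_id = sprintf("i%03d", sample(300, 1000, replace = TRUE)),
    mi_label = runif(1000) < 0.5)
  sp <- grouped_stratified_split(manifest, seed = 5)
  per_ind <- tapply(sp$subset, sp$individual_id,
                    function(s) length(unique(s)))
  expect_true(all(per_ind == 1))
  p <- mean(manifest$mi_label)
  for (s in c("train", "validation", "test"))
    expect_lt(abs(mean(sp$mi_label[sp$subset == s]) - p), 0.02)
  tab <- table(sp$subset) / nrow(sp)
  expect_equal(as.vector(tab[c("train", "validation", "test")]),
               c(0.70, 0.15, 0.15), tolerance = 0.05)
  # determinism
  sp2 <- grouped_stratified_split(manifest, seed = 5)
  expect_identical(sp$subset, sp2$subset)
  expect_error(grouped_stratified_split(manifest, fractions = c(0.5, 0.2)),
               "sum to 1")
})

test_that("single-individual records always land in one subset together", {
  manifest <- data.frame(record_id = sprintf("r%d", 1:6),
                         individual_id = "only-one",
                         mi_label = rep(c(TRUE, FALSE), 3))
  sp <- suppressWarnings(grouped_stratified_split(manifest, seed = 1))
  expect_length(unique(sp$subset), 1L)
})
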