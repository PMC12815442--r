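test_that("rank-sum AUC equals brute-force pair counting, with ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  set.seed(12)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))  # both classes guaranteed
    scores <- round(runif(n), sample(1:3, 1)) # tie-rich
    expect_equal(roc_auc(scores, labels), pair_count_auc(scores, labels))
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(13)
  scores <- runif(30); labels <- c(0, 1, rbinom(28, 1, 0.5))
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(exp(scores), labels), a)
  expect_equal(roc_auc(qlogis(scores), labels), a)
  expect_equal(roc_auc(rank(scores), labels), a)
})

test_that("rank-sum AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(19)
  scores <- round(runif(80), 2); labels <- c(0, 1, rbinom(78, 1, 0.3))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels), ref)
})

test_that("the ROC curve runs from (0,0) to (1,1) and is monotone", {
  set.seed(15)
  scores <- round(runif(40), 2); labels <- c(0, 1, rbinom(38, 1, 0.4))
  roc <- roc_curve(scores, labels)
  expect_equal(c(roc$tpr[1], roc$fpr[1]), c(0, 0))
  expect_equal(c(roc$tpr[length(roc$tpr)], roc$fpr[length(roc$fpr)]), c(1, 1))
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$thresholds) <= 0))
})

test_that("the Youden threshold matches exhaustive cut-point search", {
  scores <- c(0.1, 0.4, 0.35, 0.8); labels <- c(0, 0, 1, 1)
  roc <- roc_curve(scores, labels)
  thr <- youden_threshold(roc)
  # enumerate every cut-point
  best <- -Inf; arg <- NULL
  for (t in c(sort(unique(scores), decreasing = TRUE), -Inf)) {
    j <- mean(scores[labels == 1] > t) - mean(scores[labels == 0] > t)
    if (j > best + 1e-12) { best <- j; arg <- t }
  }
  j_at <- function(t) mean(scores[labels == 1] > t) -
    mean(scores[labels == 0] > t)
  expect_equal(j_at(thr), best)
  # perfect separation reaches J = 1
  roc2 <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  thr2 <- youden_threshold(roc2)
  expect_equal(max(roc2$tpr - roc2$fpr), 1)
  expect_true(thr2 >= 0.2 && thr2 < 0.8)
  # all-ties curve: J = 0 everywhere
  roc3 <- roc_curve(rep(1, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(max(roc3$tpr - roc3$fpr), 0)
})

test_that("confusion metrics match arithmetic and report NA on empty cells", {
  # counts tp=164, fp=104, fn=36, tn=696 realized as score vectors
  scores <- c(rep(1, 164), rep(0, 36), rep(1, 104), rep(0, 696))
  labels <- c(rep(1, 200), rep(0, 800))
  cm <- confusion_metrics(scores, labels, 0.5)
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(164, 104, 36, 696))
  expect_equal(cm$sensitivity, 0.82)
  expect_equal(cm$specificity, 0.87)
  expect_equal(cm$accuracy, 0.86)
  expect_equal(cm$ppv, 164 / 268)   # ~0.612, the Bayes-consistent value
  expect_equal(cm$npv, 696 / 732)
  # complementary rates
  expect_equal(cm$sensitivity + cm$fn / (cm$tp + cm$fn), 1)
  expect_equal(cm$specificity + cm$fp / (cm$tn + cm$fp), 1)
  # perfect classification
  cm2 <- confusion_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(c(cm2$sensitivity, cm2$specificity, cm2$ppv, cm2$npv,
                 cm2$accuracy), rep(1, 5))
  # threshold above every score: nobody classified positive, PPV absent
  cm3 <- confusion_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 2)
  expect_equal(cm3$sensitivity, 0)
  expect_equal(cm3$specificity, 1)
  expect_true(is.na(cm3$ppv))
})

test_that("bootstrap intervals are percentile, stratified, reproducible", {
  scores <- runif(50); labels <- c(rep(1, 20), rep(0, 30))
  # constant statistic: zero-width interval
  ci <- bootstrap_ci(function(s, l) 0.7, scores, labels, B = 50, seed = 1)
  expect_equal(ci, c(0.7, 0.7))
  # stratification preserves class counts on every resample
  ci2 <- bootstrap_ci(function(s, l) {
    expect_equal(sum(l == 1), 20)
    expect_equal(sum(l == 0), 30)
    mean(s)
  }, scores, labels, B = 10, seed = 2)
  # reproducibility
  f <- function(s, l) roc_auc(s, l)
  expect_identical(bootstrap_ci(f, scores, labels, B = 100, seed = 3),
                   bootstrap_ci(f, scores, labels, B = 100, seed = 3))
})

test_that("bootstrap of a proportion matches the binomial percentile", {
  set.seed(17)
  n <- 200
  scores <- as.numeric(runif(n) < 0.35)
  labels <- rep(0, n)  # single stratum: simple resampling
  ci <- bootstrap_ci(function(s, l) mean(s > 0.5), scores, labels,
                     B = 10000, seed = 5)
  phat <- mean(scores)
  ref <- qbinom(c(0.025, 0.975), n, phat) / n
  expect_equal(ci[1], ref[1], tolerance = 0.01)
  expect_equal(ci[2], ref[2], tolerance = 0.01)
})

test_that("bootstrap AUC interval covers the point estimate on default data", {
  cohort <- make_toy_cohort(n = 200, seed = 23)
  auc <- roc_auc(cohort$wase, cohort$injured)
  ci <- bootstrap_ci(function(s, l) roc_auc(s, l), cohort$wase,
                     cohort$injured, B = 2000, seed = 7)
  expect_true(ci[1] <= auc && auc <= ci[2])
})

test_that("unpaired DeLong behaves at its fixed points and is antisymmetric", {
  set.seed(21)
  s <- runif(30); l <- c(rep(1, 12), rep(0, 18))
  same <- delong_test(s, l, s, l)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  s2 <- runif(24); l2 <- c(rep(1, 10), rep(0, 14))
  ab <- delong_test(s, l, s2, l2)
  ba <- delong_test(s2, l2, s, l)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_value, ba$p_value)
  expect_true(ab$p_value >= 0 && ab$p_value <= 1)
})

test_that("DeLong variance matches a direct placement-value computation", {
  set.seed(22)
  for (i in 1:10) {
    s <- round(runif(16), 1)
    l <- rep(c(1, 0), each = 8)
    x <- s[l == 1]; y <- s[l == 0]
    # direct psi-matrix computation
    psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
    v10 <- rowMeans(psi); v01 <- colMeans(psi)
    var_direct <- var(v10) / 8 + var(v01) / 8
    d <- delong_test(s, l, rev(s), l)
    expect_equal(d$var_a, var_direct)
    expect_equal(d$auc_a, mean(psi))
  }
})

test_that("DeLong agrees with pROC's unpaired test", {
  skip_if_not_installed("pROC")
  set.seed(25)
  s1 <- runif(60); l1 <- c(rep(1, 25), rep(0, 35))
  s2 <- runif(50); l2 <- c(rep(1, 20), rep(0, 30))
  mine <- delong_test(s1, l1, s2, l2)
  ref <- pROC::roc.test(pROC::roc(l1, s1, quiet = TRUE, direction = "<"),
                        pROC::roc(l2, s2, quiet = TRUE, direction = "<"),
                        method = "delong", paired = FALSE)
  expect_equal(unname(mine$z), unname(ref$statistic), tolerance = 1e-10)
  # pROC refers D to a Welch t; we use the normal reference, so p-values
  # agree only to distribution-choice accuracy
  expect_equal(mine$p_value, ref$p.value, tolerance = 0.01)
  # the placement-value variances themselves agree exactly
  expect_equal(mine$var_a, as.numeric(pROC::var(
    pROC::roc(l1, s1, quiet = TRUE, direction = "<"), method = "delong")))
})

test_that("Hosmer-Lemeshow is zero under perfect calibration", {
  # every bin's observed rate equals its mean predicted probability
  probs <- rep(c(0.2, 0.4, 0.6, 0.8), each = 10)
  outcomes <- as.vector(sapply(c(0.2, 0.4, 0.6, 0.8), function(p)
    rep(c(1, 0), c(p * 10, 10 - p * 10))))
  hl <- hosmer_lemeshow(probs, outcomes, g = 4)
  expect_equal(hl$chi2, 0)
  expect_equal(hl$df, 2L)
  expect_equal(hl$p_value, 1)
  # all probabilities tied at 0.5 collapse to one bin, chi2 = 0
  hl2 <- hosmer_lemeshow(rep(0.5, 20), rep(c(1, 0), 10), g = 2)
  expect_equal(hl2$chi2, 0)
})

test_that("Hosmer-Lemeshow matches hand arithmetic on a two-bin instance", {
  probs <- rep(c(0.2, 0.8), each = 10)
  outcomes <- c(rep(c(1, 0), c(3, 7)), rep(c(1, 0), c(7, 3)))
  hl <- hosmer_lemeshow(probs, outcomes, g = 2)
  # bin1: E1=2, O1=3 -> 1/2 + 1/8; bin2: E1=8, O1=7 -> 1/8 + 1/2
  expect_equal(hl$chi2, 1.25)
  expect_equal(hl$table$n, c(10, 10))
  expect_equal(hl$table$mean_pred, c(0.2, 0.8))
  expect_equal(hl$table$obs_rate, c(0.3, 0.7))
})

test_that("Hosmer-Lemeshow is invariant to within-bin ordering and sums n", {
  set.seed(27)
  probs <- runif(100); outcomes <- rbinom(100, 1, probs)
  hl <- hosmer_lemeshow(probs, outcomes, g = 10)
  expect_equal(sum(hl$table$n), 100)
  perm <- sample(100)
  hl2 <- hosmer_lemeshow(probs[perm], outcomes[perm], g = 10)
  expect_equal(hl2$chi2, hl$chi2)
  expect_gte(hl$chi2, 0)
})

test_that("evaluate_scores assembles a coherent report", {
  cohort <- make_toy_cohort(n = 150, seed = 31)
  rep <- evaluate_scores(cohort$wase, cohort$injured, B = 200, seed = 9)
  expect_equal(rep$auc, roc_auc(cohort$wase, cohort$injured))
  expect_equal(rep$tp + rep$fp + rep$tn + rep$fn, 150)
  for (m in c("auc", "sensitivity", "specificity", "accuracy")) {
    expect_true(rep$ci[[m]][1] <= rep[[m]] + 1e-12)
    expect_true(rep$ci[[m]][2] >= rep[[m]] - 1e-12)
  }
})
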