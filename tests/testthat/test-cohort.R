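test_that("covariance construction is exact and round-trips", {
  sds <- c(0.04, 0.03, 0.05, 0.04)
  # independence: diagonal of squared sds
  Sigma <- build_covariance(sds, diag(4))
  expect_equal(Sigma, diag(sds^2), ignore_attr = TRUE)
  # default correlation: reconstruct corr from Sigma entrywise
  corr <- default_correlation()
  Sigma <- build_covariance(sds, corr)
  rec <- Sigma / (sds %o% sds)
  expect_equal(max(abs(rec - corr)), 0, tolerance = 1e-12)
  expect_silent(chol(Sigma))
  # invalid correlations are rejected
  bad <- corr; bad[1, 2] <- bad[2, 1] <- 1.5
  expect_error(build_covariance(sds, bad), "\\[-1, 1\\]")
  nonpd <- matrix(0.99, 4, 4); diag(nonpd) <- 1
  nonpd[1, 2] <- nonpd[2, 1] <- -0.99
  expect_error(build_covariance(sds, nonpd), "positive definite")
})

test_that("demographics are exactly stratified and within bounds", {
  cohort <- generate_cohort(population_config(seed = 5))
  expect_equal(nrow(cohort), 1000L)
  expect_equal(cohort$id, 1:1000)
  expect_equal(as.vector(table(cohort$sex)[c("male", "female")]),
               c(500L, 500L))
  expect_equal(as.vector(table(cohort$sport)[c("running", "jumping",
                                               "cutting")]),
               c(400L, 300L, 300L))
  expect_true(all(cohort$age >= 18 & cohort$age <= 35))
  expect_true(all(cohort$train_hours >= 0))
  # largest-remainder handles non-divisible counts
  c2 <- generate_cohort(population_config(n = 7, seed = 5))
  expect_equal(sum(table(c2$sex)), 7L)
  expect_equal(sum(table(c2$sport)), 7L)
})

test_that("identical (config, seed) gives identical cohorts; seeds differ", {
  a <- generate_cohort(population_config(seed = 9))
  b <- generate_cohort(population_config(seed = 9))
  expect_identical(as.data.frame(a), as.data.frame(b))
  c3 <- generate_cohort(population_config(seed = 10))
  expect_false(identical(a$fv, c3$fv))
})

test_that("components respect truncation bounds before and after noise", {
  cfg <- population_config(n = 2000, seed = 21)
  cohort <- generate_cohort(cfg)
  b <- cfg$component_bounds
  for (i in seq_along(c("fv", "ta", "ld", "ba"))) {
    nm <- c("fv", "ta", "ld", "ba")[i]
    expect_true(all(cohort[[paste0(nm, "_true")]] >= b[i, 1] &
                      cohort[[paste0(nm, "_true")]] <= b[i, 2]))
    expect_true(all(cohort[[nm]] >= b[i, 1] & cohort[[nm]] <= b[i, 2]))
  }
  # pathological bounds exhaust the rejection cap
  bad <- population_config(n = 10, seed = 21)
  bad$component_means <- c(0.0801, 0.0501, 0.1001, 0.0601)
  bad$component_bounds <- cbind(c(0.08, 0.05, 0.10, 0.06),
                                c(0.0802, 0.0502, 0.1002, 0.0602))
  expect_error(generate_cohort(bad, max_rounds = 5L), "infeasible")
})

test_that("measured component mean agrees with a quadrature oracle", {
  # with independent components the FV marginal is exactly the univariate
  # truncated normal, whose mean a quadrature oracle supplies
  cfg <- population_config(n = 10000, seed = 33, correlation = diag(4))
  cohort <- generate_cohort(cfg)
  mu <- 0.15; sd <- 0.04; lo <- 0.08; hi <- 0.25
  zmass <- integrate(function(x) dnorm(x, mu, sd), lo, hi)$value
  m_oracle <- integrate(function(x) x * dnorm(x, mu, sd), lo, hi)$value / zmass
  expect_equal(mean(cohort$fv), m_oracle, tolerance = 0.005)
})

test_that("correlated component means agree with an independent MC oracle", {
  # under the default correlation the box truncation of the partners shifts
  # every marginal; oracle via MASS::mvrnorm + rejection (independent route)
  cfg <- population_config(n = 10000, seed = 34)
  cohort <- generate_cohort(cfg)
  set.seed(99)
  Sigma <- build_covariance(cfg$component_sds, cfg$correlation)
  draw <- MASS::mvrnorm(400000, cfg$component_means, Sigma)
  inside <- draw[apply(draw >= rep(cfg$component_bounds[, 1],
                                   each = nrow(draw)) &
                         draw <= rep(cfg$component_bounds[, 2],
                                     each = nrow(draw)), 1, all), ]
  for (i in 1:4)
    expect_equal(mean(cohort[[c("fv", "ta", "ld", "ba")[i]]]),
                 mean(inside[, i]), tolerance = 0.005)
})

test_that("injury simulation follows the logistic linkage", {
  cohort <- score_cohort(generate_cohort(population_config(seed = 2)))
  # constant risk when the slope is zero
  lk <- list(beta0 = qlogis(0.2), beta1 = 0,
             score_mean = mean(cohort$wase), score_sd = sd(cohort$wase))
  out <- simulate_injuries(cohort, lk, seed = 11)
  expect_true(all(out$p_injury == 0.2))
  expect_lt(abs(mean(out$injured) - 0.2), 0.05)  # binomial, n = 1000
  # direct-summation oracle for the mean probability
  lk2 <- list(beta0 = -2, beta1 = 1,
              score_mean = mean(cohort$wase), score_sd = sd(cohort$wase))
  out2 <- simulate_injuries(cohort, lk2, seed = 11)
  z <- (cohort$wase - lk2$score_mean) / lk2$score_sd
  expect_equal(mean(out2$p_injury), mean(1 / (1 + exp(-(-2 + z)))))
  # near-deterministic outcomes in the steep-slope limit
  lk3 <- list(beta0 = 0, beta1 = 1e6,
              score_mean = mean(cohort$wase), score_sd = sd(cohort$wase))
  out3 <- simulate_injuries(cohort, lk3, seed = 11)
  expect_equal(out3$injured, as.integer(z > 0))
  # same seed reproduces outcomes exactly
  expect_identical(out2$injured,
                   simulate_injuries(cohort, lk2, seed = 11)$injured)
})

test_that("expected AUC matches a brute-force pair sum and is monotone", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(5:25, 1)
    s <- round(runif(n), 2)  # force some ties
    p <- runif(n)
    # brute force over ordered pairs, self-pairs excluded
    num <- 0; den <- 0
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a == b) next
      wgt <- p[a] * (1 - p[b])
      num <- num + wgt * ((s[a] > s[b]) + 0.5 * (s[a] == s[b]))
      den <- den + wgt
    }
    expect_equal(expected_auc(s, p), num / den)
  }
  # monotone non-decreasing in the linkage slope on a default cohort
  cohort <- score_cohort(generate_cohort(population_config(seed = 8)))
  z <- scale(cohort$wase)[, 1]
  aucs <- sapply(seq(0, 6, by = 0.5), function(b1) {
    p <- plogis(qlogis(0.2) + b1 * z)
    expected_auc(cohort$wase, p)
  })
  expect_true(all(diff(aucs) >= -1e-12))
  expect_equal(aucs[1], 0.5)
})

test_that("linkage calibration hits both targets and is a fixed point", {
  cohort <- score_cohort(generate_cohort(population_config(seed = 4)))
  lk <- calibrate_linkage(cohort, 0.20, 0.89)
  z <- (cohort$wase - lk$score_mean) / lk$score_sd
  p <- plogis(lk$beta0 + lk$beta1 * z)
  expect_lt(abs(mean(p) - 0.20), 1e-4)
  expect_lt(abs(expected_auc(cohort$wase, p) - 0.89), 1e-4)
  # recalibrating the same cohort reproduces the same coefficients
  lk2 <- calibrate_linkage(cohort, 0.20, 0.89)
  expect_equal(lk2$beta0, lk$beta0, tolerance = 1e-6)
  expect_equal(lk2$beta1, lk$beta1, tolerance = 1e-6)
  # realized prevalence concentrates on the target across outcome seeds
  prevs <- vapply(1:30, function(k)
    mean(simulate_injuries(cohort, lk, seed = k)$injured), numeric(1))
  expect_lt(abs(mean(prevs) - 0.20), 0.01)
})

test_that("the no-discrimination limit pins the slope near zero", {
  cohort <- score_cohort(generate_cohort(population_config(seed = 4)))
  lk <- calibrate_linkage(cohort, 0.20, 0.5005)
  expect_lt(lk$beta1, 0.05)
  expect_lt(abs(lk$beta0 - qlogis(0.20)), 0.1)
})

test_that("unreachable targets and degenerate scores error", {
  cohort <- score_cohort(generate_cohort(population_config(n = 50, seed = 4)))
  expect_error(calibrate_linkage(cohort, 0.20, 0.9999999),
               "unreachable")
  flat <- cohort
  flat$wase <- rep(0.2, nrow(flat))
  expect_error(calibrate_linkage(flat, 0.2, 0.89), "zero score variance")
})
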