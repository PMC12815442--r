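#' Build the component covariance matrix
#'
#' `Sigma_ij = corr_ij * sd_i * sd_j`. The correlation matrix must be
#' symmetric with unit diagonal and positive definite (its Cholesky
#' factorization must succeed).
#'
#' @param sds numeric(4) of positive standard deviations.
#' @param corr 4 x 4 correlation matrix.
#' @return 4 x 4 symmetric positive-definite covariance matrix.
#' @export
build_covariance <- function(sds, corr) {
  if (length(sds) != 4L || any(sds <= 0))
    stop("`sds` must be four positive numbers")
  corr <- validate_correlation(corr)
  corr * (sds %o% sds)
}

#' Generate the virtual cohort (demographics and components, no outcomes)
#'
#' Five-stage generation under named seed substreams: (1) exactly stratified
#' demographics — sex and sport counts apportioned by largest remainder and
#' shuffled; (2) age from a truncated normal on `age_bounds` and training
#' hours from a normal truncated at 0; (3) latent components from the
#' 4-variate normal with covariance [build_covariance()], rejection-sampled
#' as whole vectors until all four components lie inside their bounds;
#' (4) measured components = latent x (1 + N(0, noise_cv)) per component,
#' clamped back to the bounds. Fully reproducible from `config$seed`.
#'
#' @param config a [population_config()].
#' @param max_rounds rejection-sampling retry cap; exceeding it signals an
#'   infeasible configuration.
#' @return a `wase_cohort`: a data.frame with columns `id`, `age`, `sex`,
#'   `sport`, `train_hours`, `fv_true`..`ba_true`, `fv`..`ba`, carrying the
#'   config and seed as attributes. Scores and outcomes are added by
#'   [score_cohort()] and [simulate_injuries()].
#' @export
generate_cohort <- function(config = population_config(), max_rounds = 1000L) {
  stopifnot(inherits(config, "population_config"))
  n <- config$n

  # demographics substream
  set.seed(substream_seed(config$seed, "demographics"))
  sex_counts <- largest_remainder(n, c(config$sex_split, 1 - config$sex_split))
  sex <- sample(rep(c("male", "female"), sex_counts))
  sport_counts <- largest_remainder(n, config$sport_props)
  sport <- sample(rep(names(config$sport_props), sport_counts))
  age <- rtruncnorm(n, config$age_mean, config$age_sd,
                    config$age_bounds[1], config$age_bounds[2])
  train_hours <- rtruncnorm(n, config$train_mean, config$train_sd, lo = 0)

  # latent components substream: whole-vector rejection sampling
  set.seed(substream_seed(config$seed, "components"))
  Sigma <- build_covariance(config$component_sds, config$correlation)
  R <- chol(Sigma)
  lo <- config$component_bounds[, 1]
  hi <- config$component_bounds[, 2]
  X <- matrix(NA_real_, n, 4)
  need <- seq_len(n)
  rounds <- 0L
  while (length(need) > 0L) {
    rounds <- rounds + 1L
    if (rounds > max_rounds)
      stop("infeasible configuration: component rejection sampling ",
           "exceeded ", max_rounds, " rounds")
    Z <- matrix(stats::rnorm(length(need) * 4L), ncol = 4L)
    cand <- sweep(Z %*% R, 2, config$component_means, "+")
    ok <- rowSums(cand >= rep(lo, each = nrow(cand)) &
                    cand <= rep(hi, each = nrow(cand))) == 4L
    X[need[ok], ] <- cand[ok, , drop = FALSE]
    need <- need[!ok]
  }

  # measurement-noise substream: multiplicative, clamped to bounds
  set.seed(substream_seed(config$seed, "noise"))
  M <- X * (1 + matrix(stats::rnorm(n * 4L, 0, config$noise_cv), n, 4L))
  M <- pmin(pmax(M, rep(lo, each = n)), rep(hi, each = n))

  cohort <- data.frame(
    id = seq_len(n), age = age, sex = sex, sport = sport,
    train_hours = train_hours,
    fv_true = X[, 1], ta_true = X[, 2], ld_true = X[, 3], ba_true = X[, 4],
    fv = M[, 1], ta = M[, 2], ld = M[, 3], ba = M[, 4],
    stringsAsFactors = FALSE)
  structure(cohort,
            class = c("wase_cohort", "data.frame"),
            config = config, seed = config$seed,
            config_digest = config_digest(config))
}

#' Score a cohort with the WASe composite
#'
#' Adds a `wase` column: the weighted sum of the four measured components
#' (cross-sectional mode, Omega = 1). Set `use_true = TRUE` to score the
#' latent noise-free components instead (sensitivity experiments).
#'
#' @param cohort a `wase_cohort`.
#' @param weights a [wase_weights] vector.
#' @param use_true score latent instead of measured components.
#' @return the cohort with a `wase` column.
#' @export
score_cohort <- function(cohort, weights = default_weights(),
                         use_true = FALSE) {
  cols <- if (use_true) c("fv_true", "ta_true", "ld_true", "ba_true")
          else c("fv", "ta", "ld", "ba")
  if (!all(cols %in% names(cohort)))
    stop("cohort is missing component columns: ",
         paste(setdiff(cols, names(cohort)), collapse = ", "))
  X <- as.matrix(cohort[cols])
  cohort$wase <- pmin(pmax(drop(X %*% as.numeric(weights)), 0), 1)
  cohort
}

#' Expected AUC of a score vector under per-participant risk probabilities
#'
#' The resampling-free expectation of the rank-sum AUC when participant `i`
#' is a case with probability `p_i`: each ordered pair `(i, j)`, `i != j`,
#' contributes case weight `p_i` times control weight `1 - p_j`, and
#' `AUC = P(s_case > s_control) + 0.5 P(s_case = s_control)` under those
#' weights, accumulated in one pass over the sorted scores.
#'
#' @param scores numeric score vector.
#' @param p per-participant case probabilities in `[0, 1]`.
#' @return scalar expected AUC.
#' @export
expected_auc <- function(scores, p) {
  stopifnot(length(scores) == length(p), all(p >= 0), all(p <= 1))
  o <- order(scores)
  s <- scores[o]; a <- p[o]; b <- 1 - p[o]
  grp <- cumsum(c(TRUE, diff(s) != 0))
  ag <- rowsum(a, grp); bg <- rowsum(b, grp); abg <- rowsum(a * b, grp)
  blt <- c(0, cumsum(bg))[seq_along(bg)]   # control weight strictly below
  num <- sum(ag * blt) + 0.5 * sum(ag * bg - abg)
  den <- sum(a) * sum(b) - sum(a * b)      # self-pairs excluded
  num / den
}

#' Calibrate the logistic injury linkage
#'
#' The linkage is `p = plogis(beta0 + beta1 * z)` with
#' `z = (wase - score_mean) / score_sd` standardized to the cohort's score
#' moments. Calibration solves two objectives by nested bisection: the outer
#' loop adjusts the slope `beta1 >= 0` until the expected AUC
#' ([expected_auc()]) equals `target_auc`, and for every trial slope the
#' inner loop adjusts the intercept `beta0` until the mean injury
#' probability equals `target_prevalence`. Both residuals are verified to be
#' below 1e-4.
#'
#' @param cohort a scored `wase_cohort` (or anything with a `wase` column).
#' @param target_prevalence target mean injury probability in (0, 1).
#' @param target_auc target expected AUC in (0.5, 1).
#' @param tol bisection tolerance on the parameters.
#' @return object of class `linkage_config`: `beta0`, `beta1`,
#'   `score_mean`, `score_sd`, the targets, and the achieved values.
#' @export
calibrate_linkage <- function(cohort, target_prevalence = 0.20,
                              target_auc = 0.89, tol = 1e-6) {
  s <- cohort$wase
  if (is.null(s)) stop("cohort has no `wase` scores; run score_cohort() first")
  if (target_prevalence <= 0 || target_prevalence >= 1)
    stop("`target_prevalence` must be in (0, 1)")
  if (target_auc <= 0.5 || target_auc >= 1)
    stop("`target_auc` must be in (0.5, 1)")
  m <- mean(s); sdv <- stats::sd(s)
  if (sdv <= 0) stop("zero score variance; linkage cannot be calibrated")
  z <- (s - m) / sdv

  solve_beta0 <- function(beta1) {
    f <- function(b0) mean(stats::plogis(b0 + beta1 * z)) - target_prevalence
    lo <- -20; hi <- 20
    while (f(lo) > 0) lo <- lo * 2   # expand if the root escapes the bracket
    while (f(hi) < 0) hi <- hi * 2
    bisect(f, lo, hi, tol)
  }
  g <- function(beta1) {
    b0 <- solve_beta0(beta1)
    expected_auc(s, stats::plogis(b0 + beta1 * z)) - target_auc
  }
  if (g(50) < 0)
    stop("target AUC unreachable within the slope bracket [0, 50]")
  beta1 <- bisect(g, 0, 50, tol)
  beta0 <- solve_beta0(beta1)
  p <- stats::plogis(beta0 + beta1 * z)
  achieved_prev <- mean(p)
  achieved_auc <- expected_auc(s, p)
  if (abs(achieved_prev - target_prevalence) > 1e-4 ||
      abs(achieved_auc - target_auc) > 1e-4)
    stop("calibration residuals exceed 1e-4")
  structure(list(beta0 = beta0, beta1 = beta1,
                 score_mean = m, score_sd = sdv,
                 target_prevalence = target_prevalence,
                 target_auc = target_auc,
                 achieved_prevalence = achieved_prev,
                 achieved_auc = achieved_auc),
            class = "linkage_config")
}

#' @export
print.linkage_config <- function(x, ...) {
  cat(sprintf(
    "Logistic injury linkage: beta0 = %.4f, beta1 = %.4f (standardized score)\n",
    x$beta0, x$beta1))
  cat(sprintf("  calibrated to prevalence %.3f (achieved %.5f), expected AUC %.3f (achieved %.5f)\n",
              x$target_prevalence, x$achieved_prevalence,
              x$target_auc, x$achieved_auc))
  invisible(x)
}

# plain bisection; f(lo) <= 0 <= f(hi)
bisect <- function(f, lo, hi, tol = 1e-6) {
  flo <- f(lo); fhi <- f(hi)
  if (flo > 0 || fhi < 0) stop("bisection bracket does not enclose a root")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate injury outcomes through the calibrated linkage
#'
#' Fills `p_injury = plogis(beta0 + beta1 * z)` (with the score standardized
#' by the linkage's stored moments) and draws `injured` as an independent
#' Bernoulli per participant from the `"outcomes"` substream of `seed`.
#'
#' @param cohort a scored `wase_cohort`.
#' @param linkage a [calibrate_linkage()] result (or compatible list).
#' @param seed master seed for the outcome draws.
#' @return the cohort with `p_injury` and `injured` columns.
#' @export
simulate_injuries <- function(cohort, linkage, seed = 42L) {
  s <- cohort$wase
  if (is.null(s)) stop("cohort has no `wase` scores; run score_cohort() first")
  if (linkage$score_sd <= 0) stop("linkage score_sd must be positive")
  z <- (s - linkage$score_mean) / linkage$score_sd
  p <- stats::plogis(linkage$beta0 + linkage$beta1 * z)
  set.seed(substream_seed(seed, "outcomes"))
  cohort$p_injury <- p
  cohort$injured <- stats::rbinom(length(p), 1L, p)
  cohort
}

#' @export
print.wase_cohort <- function(x, ...) {
  cat(sprintf("Virtual cohort: %d participants (seed %s, config %s)\n",
              nrow(x), attr(x, "seed"), attr(x, "config_digest")))
  cat(sprintf("  columns: %s\n", paste(names(x), collapse = ", ")))
  if (!is.null(x$injured))
    cat(sprintf("  injury prevalence: %.3f\n", mean(x$injured)))
  invisible(x)
}
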