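#' Population configuration for the virtual cohort
#'
#' Bundles every parameter of the cohort generator: sample size, stratified
#' demographics, the four component means/SDs with their truncation bounds,
#' the inter-component correlation matrix, and the multiplicative
#' measurement-noise coefficient of variation. Defaults reproduce the shipped
#' study population: n = 1000, age 24.5 +/- 5.2 y on [18, 35], 50% male,
#' sports 40/30/30 (running/jumping/cutting), training 8.5 +/- 3.1 h/wk,
#' component means (0.15, 0.08, 0.12, 0.10) and SDs (0.04, 0.03, 0.05, 0.04)
#' truncated to the observed ranges, correlations spanning 0.25-0.65, and 5%
#' CV noise.
#'
#' @param n cohort size.
#' @param age_mean,age_sd,age_bounds age distribution (years), truncated.
#' @param sex_split proportion male in `[0, 1]`.
#' @param sport_props named proportions for running/jumping/cutting, sum 1.
#' @param train_mean,train_sd weekly training hours, truncated at 0.
#' @param component_means,component_sds numeric(4) for FV, TA, LD, BA.
#' @param component_bounds 4 x 2 matrix of truncation bounds `(lo, hi)`.
#' @param correlation 4 x 4 symmetric positive-definite correlation matrix
#'   with unit diagonal.
#' @param noise_cv coefficient of variation of multiplicative measurement
#'   noise, >= 0.
#' @param seed master seed for the generator.
#' @return object of class `population_config`.
#' @export
population_config <- function(n = 1000L,
                              age_mean = 24.5, age_sd = 5.2,
                              age_bounds = c(18, 35),
                              sex_split = 0.5,
                              sport_props = c(running = 0.4, jumping = 0.3,
                                              cutting = 0.3),
                              train_mean = 8.5, train_sd = 3.1,
                              component_means = c(0.15, 0.08, 0.12, 0.10),
                              component_sds = c(0.04, 0.03, 0.05, 0.04),
                              component_bounds = default_component_bounds(),
                              correlation = default_correlation(),
                              noise_cv = 0.05,
                              seed = 42L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer")
  if (abs(sum(sport_props) - 1) > 1e-9)
    stop("`sport_props` must sum to 1")
  if (sex_split < 0 || sex_split > 1) stop("`sex_split` must be in [0, 1]")
  if (noise_cv < 0) stop("`noise_cv` must be non-negative")
  component_bounds <- as.matrix(component_bounds)
  if (!all(dim(component_bounds) == c(4L, 2L)))
    stop("`component_bounds` must be a 4 x 2 matrix")
  if (any(component_bounds[, 1] >= component_bounds[, 2]))
    stop("component bounds must satisfy lo < hi")
  if (any(component_means < component_bounds[, 1]) ||
      any(component_means > component_bounds[, 2]))
    stop("component means must lie inside their bounds")
  if (any(component_sds <= 0)) stop("component SDs must be positive")
  validate_correlation(correlation)
  cfg <- list(
    n = n, age_mean = age_mean, age_sd = age_sd, age_bounds = age_bounds,
    sex_split = sex_split, sport_props = sport_props,
    train_mean = train_mean, train_sd = train_sd,
    component_means = component_means, component_sds = component_sds,
    component_bounds = component_bounds, correlation = correlation,
    noise_cv = noise_cv, seed = as.integer(seed))
  class(cfg) <- "population_config"
  cfg
}

#' Default truncation bounds for the four components
#'
#' The shipped observed ranges: FV 0.08-0.25, TA 0.05-0.20, LD 0.10-0.28,
#' BA 0.06-0.22.
#' @return 4 x 2 numeric matrix.
#' @export
default_component_bounds <- function() {
  matrix(c(0.08, 0.25,
           0.05, 0.20,
           0.10, 0.28,
           0.06, 0.22), 4, 2, byrow = TRUE,
         dimnames = list(c("fv", "ta", "ld", "ba"), c("lo", "hi")))
}

#' Default inter-component correlation matrix
#'
#' Off-diagonals span the empirically reported 0.25-0.65 band:
#' FV-TA 0.45, FV-LD 0.35, FV-BA 0.55, TA-LD 0.25, TA-BA 0.65, LD-BA 0.30.
#' Positive definiteness is asserted at load time.
#' @return 4 x 4 correlation matrix.
#' @export
default_correlation <- function() {
  m <- diag(4)
  m[1, 2] <- m[2, 1] <- 0.45
  m[1, 3] <- m[3, 1] <- 0.35
  m[1, 4] <- m[4, 1] <- 0.55
  m[2, 3] <- m[3, 2] <- 0.25
  m[2, 4] <- m[4, 2] <- 0.65
  m[3, 4] <- m[4, 3] <- 0.30
  dimnames(m) <- list(c("fv", "ta", "ld", "ba"), c("fv", "ta", "ld", "ba"))
  validate_correlation(m)
}

validate_correlation <- function(corr) {
  corr <- as.matrix(corr)
  if (!all(dim(corr) == c(4L, 4L))) stop("correlation must be 4 x 4")
  if (max(abs(corr - t(corr))) > 1e-12) stop("correlation must be symmetric")
  if (max(abs(diag(corr) - 1)) > 1e-12)
    stop("correlation must have unit diagonal")
  off <- corr[upper.tri(corr)]
  if (any(off < -1) || any(off > 1))
    stop("invalid input: correlations must lie in [-1, 1]")
  ch <- tryCatch(chol(corr), error = function(e) NULL)
  if (is.null(ch))
    stop("invalid configuration: correlation matrix is not positive definite")
  corr
}

#' @export
print.population_config <- function(x, ...) {
  cat(sprintf("Population config: n = %d, seed = %d\n", x$n, x$seed))
  cat(sprintf("  age %.1f +/- %.1f y on [%g, %g]; %.0f%% male; sports %s\n",
              x$age_mean, x$age_sd, x$age_bounds[1], x$age_bounds[2],
              100 * x$sex_split,
              paste(sprintf("%s %.0f%%", names(x$sport_props),
                            100 * x$sport_props), collapse = ", ")))
  cat(sprintf("  components mu = (%s), sd = (%s), noise CV = %g\n",
              paste(format(x$component_means), collapse = ", "),
              paste(format(x$component_sds), collapse = ", "), x$noise_cv))
  invisible(x)
}

#' Study configuration
#'
#' Bundles the population configuration with the linkage calibration targets
#' and every analysis setting of the validation study.
#'
#' @param population a [population_config()].
#' @param target_prevalence injury incidence the linkage is calibrated to.
#' @param target_auc expected AUC the linkage is calibrated to.
#' @param cv_folds number of cross-validation folds (>= 2).
#' @param bootstrap_B bootstrap resamples for confidence intervals.
#' @param hl_bins Hosmer-Lemeshow bins.
#' @param sensitivity_delta single-weight perturbation size.
#' @param n_weight_configs random weight configurations to evaluate.
#' @param replicates replicate seeds for headline-metric averaging (>= 1).
#' @param weights scoring weights, a [wase_weights] vector.
#' @param seed master seed of the study.
#' @return object of class `study_config`.
#' @export
study_config <- function(population = population_config(),
                         target_prevalence = 0.20,
                         target_auc = 0.89,
                         cv_folds = 5L,
                         bootstrap_B = 2000L,
                         hl_bins = 10L,
                         sensitivity_delta = 0.05,
                         n_weight_configs = 100L,
                         replicates = 1L,
                         weights = default_weights(),
                         seed = 42L) {
  if (cv_folds < 2L) stop("`cv_folds` must be >= 2")
  if (replicates < 1L) stop("`replicates` must be >= 1")
  if (target_prevalence <= 0 || target_prevalence >= 1)
    stop("`target_prevalence` must be in (0, 1)")
  if (target_auc <= 0.5 || target_auc >= 1)
    stop("`target_auc` must be in (0.5, 1)")
  structure(list(
    population = population,
    target_prevalence = target_prevalence, target_auc = target_auc,
    cv_folds = as.integer(cv_folds), bootstrap_B = as.integer(bootstrap_B),
    hl_bins = as.integer(hl_bins), sensitivity_delta = sensitivity_delta,
    n_weight_configs = as.integer(n_weight_configs),
    replicates = as.integer(replicates),
    weights = weights, seed = as.integer(seed)),
    class = "study_config")
}

#' Read / write configurations as JSON
#'
#' Configurations round-trip through JSON with 17 significant digits.
#' `read_study_config()` accepts a path to a JSON document with the fields
#' of [study_config()] (a nested `population` object plus analysis
#' settings); missing fields take their defaults. The shipped default
#' configuration is at
#' `system.file("extdata", "default-config.json", package = "wase")`.
#'
#' @param path file path.
#' @param config a `study_config` object.
#' @return `read_study_config()` returns a `study_config`;
#'   `write_study_config()` returns `path` invisibly.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  pop_args <- j$population
  pop <- if (is.null(pop_args)) population_config() else {
    if (!is.null(pop_args$component_bounds))
      pop_args$component_bounds <- matrix(unlist(pop_args$component_bounds),
                                          ncol = 2, byrow = FALSE)
    if (!is.null(pop_args$correlation))
      pop_args$correlation <- as.matrix(pop_args$correlation)
    if (!is.null(pop_args$sport_props))
      pop_args$sport_props <- unlist(pop_args$sport_props)
    do.call(population_config, pop_args)
  }
  args <- j[setdiff(names(j), c("population", "version"))]
  if (!is.null(args$weights))
    args$weights <- do.call(wase_weights, as.list(unlist(args$weights)))
  do.call(study_config, c(list(population = pop), args))
}

#' @rdname read_study_config
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  pop <- config$population
  out <- list(
    version = as.character(utils::packageVersion("wase")),
    population = list(
      n = pop$n, age_mean = pop$age_mean, age_sd = pop$age_sd,
      age_bounds = pop$age_bounds, sex_split = pop$sex_split,
      sport_props = as.list(pop$sport_props),
      train_mean = pop$train_mean, train_sd = pop$train_sd,
      component_means = pop$component_means,
      component_sds = pop$component_sds,
      component_bounds = unclass(pop$component_bounds),
      correlation = unclass(pop$correlation),
      noise_cv = pop$noise_cv, seed = pop$seed),
    target_prevalence = config$target_prevalence,
    target_auc = config$target_auc,
    cv_folds = config$cv_folds, bootstrap_B = config$bootstrap_B,
    hl_bins = config$hl_bins, sensitivity_delta = config$sensitivity_delta,
    n_weight_configs = config$n_weight_configs,
    replicates = config$replicates,
    weights = as.list(unclass(config$weights)),
    seed = config$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 17,
                       pretty = TRUE)
  invisible(path)
}

# Stable digest of a canonicalized config (names sorted recursively).
config_digest <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, canon)
      if (!is.null(names(x))) x <- x[order(names(x))]
    }
    x
  }
  s <- jsonlite::toJSON(canon(unclass_deep(config)), auto_unbox = TRUE,
                        digits = 17)
  h <- fnv1a32(as.character(s))
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) x <- lapply(x, unclass_deep)
  x
}
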