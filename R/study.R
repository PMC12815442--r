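#' Stratified k-fold cross-validation of the scoring rule
#'
#' Folds are stratified by injury status with seed-controlled shuffling.
#' For each fold the Youden threshold is re-derived on the k-1 training
#' folds and applied to the held-out fold; AUC, sensitivity, specificity and
#' accuracy are reported per fold with their mean and SD.
#'
#' @param cohort a scored cohort with `injured` outcomes.
#' @param k number of folds (>= 2, at most the number of cases).
#' @param seed shuffling seed.
#' @return list with `folds` (per-fold data.frame), `mean`, `sd`.
#' @export
run_cross_validation <- function(cohort, k = 5L, seed = 42L) {
  scores <- cohort$wase; labels <- cohort$injured
  if (is.null(scores) || is.null(labels))
    stop("cohort must carry `wase` scores and `injured` outcomes")
  n1 <- sum(labels == 1)
  if (k < 2L || k > n1) stop("`k` must be in [2, number of cases]")
  set.seed(substream_seed(seed, "cv_folds"))
  fold <- integer(length(labels))
  for (cl in c(0, 1)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  res <- lapply(seq_len(k), function(f) {
    test <- fold == f
    if (length(unique(labels[test])) < 2 ||
        length(unique(labels[!test])) < 2)
      stop("infeasible k: fold ", f, " has a single outcome class")
    thr <- youden_threshold(roc_curve(scores[!test], labels[!test]))
    cm <- confusion_metrics(scores[test], labels[test], thr)
    data.frame(fold = f, n_test = sum(test), threshold = thr,
               auc = roc_auc(scores[test], labels[test]),
               sensitivity = cm$sensitivity, specificity = cm$specificity,
               accuracy = cm$accuracy)
  })
  folds <- do.call(rbind, res)
  metrics <- c("auc", "sensitivity", "specificity", "accuracy")
  list(folds = folds,
       mean = colMeans(folds[metrics]),
       sd = vapply(folds[metrics], stats::sd, numeric(1)))
}

#' Subgroup analysis with DeLong AUC comparisons
#'
#' Computes per-subgroup metrics (at the full-cohort Youden threshold,
#' mirroring deployment of one rule across groups) for sex, age bands
#' (18-25 / 26-35) and sport, plus unpaired DeLong comparisons: male vs
#' female, age band vs age band, and all three sport pairs, with the
#' headline sport p-value taken from the max-AUC vs min-AUC pair. Subgroups
#' with a single outcome class get `NA` metrics (with a message).
#'
#' @param cohort a scored cohort with outcomes.
#' @param threshold operating threshold; `NULL` derives the full-cohort
#'   Youden optimum.
#' @return list with `table` (per-subgroup metrics) and `delong`
#'   (comparison results).
#' @export
run_subgroup_analysis <- function(cohort, threshold = NULL) {
  scores <- cohort$wase; labels <- cohort$injured
  if (is.null(scores) || is.null(labels))
    stop("cohort must carry `wase` scores and `injured` outcomes")
  if (is.null(threshold))
    threshold <- youden_threshold(roc_curve(scores, labels))
  age_band <- ifelse(cohort$age <= 25, "18-25", "26-35")
  groups <- list(sex = cohort$sex, age = age_band, sport = cohort$sport)

  rows <- list(); samples <- list()
  for (gv in names(groups)) {
    for (lev in sort(unique(groups[[gv]]))) {
      sel <- groups[[gv]] == lev
      if (length(unique(labels[sel])) < 2) {
        message("subgroup ", lev, " has a single outcome class; metrics absent")
        rows[[paste(gv, lev)]] <- data.frame(
          variable = gv, subgroup = lev, n = sum(sel), auc = NA_real_,
          sensitivity = NA_real_, specificity = NA_real_,
          accuracy = NA_real_)
        next
      }
      cm <- confusion_metrics(scores[sel], labels[sel], threshold)
      rows[[paste(gv, lev)]] <- data.frame(
        variable = gv, subgroup = lev, n = sum(sel),
        auc = roc_auc(scores[sel], labels[sel]),
        sensitivity = cm$sensitivity, specificity = cm$specificity,
        accuracy = cm$accuracy)
      samples[[lev]] <- list(scores = scores[sel], labels = labels[sel])
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  pair_test <- function(a, b) {
    if (is.null(samples[[a]]) || is.null(samples[[b]])) return(NULL)
    delong_test(samples[[a]]$scores, samples[[a]]$labels,
                samples[[b]]$scores, samples[[b]]$labels)
  }
  delong <- list(sex = pair_test("male", "female"),
                 age = pair_test("18-25", "26-35"))
  sports <- intersect(c("running", "jumping", "cutting"), names(samples))
  if (length(sports) >= 2) {
    pairs <- utils::combn(sports, 2, simplify = FALSE)
    sp <- lapply(pairs, function(p) pair_test(p[1], p[2]))
    names(sp) <- vapply(pairs, paste, "", collapse = "_vs_")
    aucs <- vapply(sports, function(s)
      roc_auc(samples[[s]]$scores, samples[[s]]$labels), numeric(1))
    hi <- sports[which.max(aucs)]; lo <- sports[which.min(aucs)]
    delong$sport_pairs <- sp
    delong$sport <- pair_test(hi, lo)
    delong$sport_headline <- paste(hi, "vs", lo)
  }
  list(table = tab, delong = delong, threshold = threshold)
}

#' Weight-sensitivity analysis on a fixed cohort
#'
#' Holds the cohort draw and the simulated outcomes fixed and re-runs only
#' the scoring + AUC step under perturbed weight vectors: each of the four
#' weights perturbed by +/-`delta` (then renormalized to sum 1), plus
#' `n_configs` random weight vectors drawn uniformly in the +/-`delta` box
#' around the defaults and renormalized. Reports the AUC change of every
#' configuration against the default-weights AUC.
#'
#' @param cohort a cohort with measured components and `injured` outcomes.
#' @param weights the reference [wase_weights].
#' @param delta perturbation size (> 0 for perturbations; 0 allowed as the
#'   identity check).
#' @param n_configs number of random configurations.
#' @param seed seed for the random configurations.
#' @return list with `perturbations` and `random` data.frames,
#'   `auc_default`, `max_abs_delta_auc` (over the single-weight
#'   perturbations) and `max_abs_delta_auc_random`.
#' @export
run_weight_sensitivity <- function(cohort, weights = default_weights(),
                                   delta = 0.05, n_configs = 100L,
                                   seed = 42L) {
  if (is.null(cohort$injured))
    stop("cohort must carry `injured` outcomes")
  if (delta < 0) stop("`delta` must be non-negative")
  X <- as.matrix(cohort[c("fv", "ta", "ld", "ba")])
  labels <- cohort$injured
  auc_of <- function(w) roc_auc(drop(X %*% w), labels)
  w0 <- as.numeric(weights)
  auc0 <- auc_of(w0)

  rows <- list()
  for (i in 1:4) for (dir in c(-1, 1)) {
    w <- w0
    w[i] <- w[i] + dir * delta
    if (w[i] <= 0 || w[i] >= 1)
      stop("perturbation pushes weight ", i, " out of (0, 1)")
    w <- w / sum(w)
    rows[[length(rows) + 1L]] <- data.frame(
      component = c("fv", "ta", "ld", "ba")[i],
      direction = ifelse(dir > 0, "+", "-"),
      w_fv = w[1], w_ta = w[2], w_ld = w[3], w_ba = w[4],
      auc = auc_of(w), delta_auc = auc_of(w) - auc0)
  }
  pert <- do.call(rbind, rows)

  rand <- NULL
  if (n_configs > 0) {
    set.seed(substream_seed(seed, "weight_configs"))
    rw <- lapply(seq_len(n_configs), function(i) {
      w <- w0 + stats::runif(4, -delta, delta)
      w <- pmax(w, 1e-6)
      w / sum(w)
    })
    rand <- data.frame(
      config = seq_len(n_configs),
      t(vapply(rw, identity, numeric(4))))
    names(rand)[2:5] <- c("w_fv", "w_ta", "w_ld", "w_ba")
    rand$auc <- vapply(rw, auc_of, numeric(1))
    rand$delta_auc <- rand$auc - auc0
  }
  list(perturbations = pert, random = rand, auc_default = auc0,
       max_abs_delta_auc = max(abs(pert$delta_auc)),
       max_abs_delta_auc_random = if (is.null(rand)) NA_real_
                                  else max(abs(rand$delta_auc)))
}

#' Run the complete validation study
#'
#' End-to-end pipeline: generate the virtual cohort, score it, calibrate
#' the logistic injury linkage to the configured prevalence and expected
#' AUC, simulate outcomes once, then evaluate: Youden operating point with
#' bootstrap CIs, stratified cross-validation, subgroup analysis with
#' DeLong comparisons, Hosmer-Lemeshow calibration, and weight-sensitivity
#' analysis. With `replicates > 1` the headline metrics (prevalence, AUC,
#' sensitivity, specificity, accuracy, CV mean AUC) are additionally
#' averaged over replicate seeds; the detailed tables come from the first
#' replicate. The whole study is a pure function of (config, seed).
#'
#' @param config a [study_config()].
#' @return object of class `wase_study`.
#' @export
run_full_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  reps <- lapply(seq_len(config$replicates), function(r) {
    rep_seed <- if (r == 1L) config$seed
                else substream_seed(config$seed, paste0("replicate_", r))
    run_one_replicate(config, rep_seed, detail = (r == 1L))
  })
  headline <- do.call(rbind, lapply(reps, `[[`, "headline"))
  first <- reps[[1L]]
  structure(list(
    config = config,
    config_digest = config_digest(config),
    population = first$population,
    linkage = first$linkage,
    metrics = first$metrics,
    cv = first$cv,
    subgroups = first$subgroups,
    calibration = first$calibration,
    sensitivity = first$sensitivity,
    cohort = first$cohort,
    replicates = headline,
    replicate_mean = colMeans(headline[-1]),
    replicate_sd = if (nrow(headline) > 1)
      vapply(headline[-1], stats::sd, numeric(1)) else NULL),
    class = "wase_study")
}

run_one_replicate <- function(config, rep_seed, detail = FALSE) {
  pop <- config$population
  pop$seed <- as.integer(substream_seed(rep_seed, "cohort"))
  cohort <- generate_cohort(pop)
  cohort <- score_cohort(cohort, config$weights)
  linkage <- calibrate_linkage(cohort, config$target_prevalence,
                               config$target_auc)
  cohort <- simulate_injuries(cohort, linkage,
                              seed = substream_seed(rep_seed, "injuries"))
  scores <- cohort$wase; labels <- cohort$injured
  roc <- roc_curve(scores, labels)
  thr <- youden_threshold(roc)
  cm <- confusion_metrics(scores, labels, thr)
  cv <- run_cross_validation(cohort, config$cv_folds,
                             seed = substream_seed(rep_seed, "cv"))
  headline <- data.frame(
    seed = rep_seed, prevalence = mean(labels), auc = roc$auc,
    threshold = thr, sensitivity = cm$sensitivity,
    specificity = cm$specificity, accuracy = cm$accuracy,
    cv_mean_auc = unname(cv$mean["auc"]))
  out <- list(headline = headline)
  if (detail) {
    out$population <- summarize_population(cohort)
    out$linkage <- linkage
    out$metrics <- evaluate_scores(scores, labels, threshold = thr,
                                   B = config$bootstrap_B,
                                   seed = substream_seed(rep_seed, "boot"))
    out$cv <- cv
    out$subgroups <- run_subgroup_analysis(cohort, threshold = thr)
    out$calibration <- hosmer_lemeshow(cohort$p_injury, labels,
                                       config$hl_bins)
    out$sensitivity <- run_weight_sensitivity(
      cohort, config$weights, config$sensitivity_delta,
      config$n_weight_configs, seed = substream_seed(rep_seed, "weights"))
    out$cohort <- cohort
  }
  out
}

summarize_population <- function(cohort) {
  list(n = nrow(cohort),
       age_mean = mean(cohort$age), age_sd = stats::sd(cohort$age),
       sex_counts = table(cohort$sex),
       sport_counts = table(cohort$sport),
       train_mean = mean(cohort$train_hours),
       train_sd = stats::sd(cohort$train_hours),
       injury_rate = if (is.null(cohort$injured)) NA_real_
                     else mean(cohort$injured),
       component_ranges = vapply(
         cohort[c("fv", "ta", "ld", "ba")], range, numeric(2)))
}

#' @export
print.wase_study <- function(x, ...) {
  cat("WASe validation study (config", x$config_digest, ")\n")
  p <- x$population
  cat(sprintf("  cohort n = %d; age %.1f +/- %.1f; injury rate %.3f\n",
              p$n, p$age_mean, p$age_sd, p$injury_rate))
  print(x$metrics)
  cat(sprintf("  CV (%d folds): AUC %.3f +/- %.3f\n",
              nrow(x$cv$folds), x$cv$mean["auc"], x$cv$sd["auc"]))
  cat(sprintf("  Calibration: chi2 = %.2f (df %d, p = %.3f)\n",
              x$calibration$chi2, x$calibration$df, x$calibration$p_value))
  cat(sprintf("  Weight sensitivity: max |dAUC| = %.4f over +/-%.2f perturbations\n",
              x$sensitivity$max_abs_delta_auc,
              x$config$sensitivity_delta))
  if (nrow(x$replicates) > 1) {
    m <- x$replicate_mean
    cat(sprintf("  Replicate means (%d seeds): prevalence %.3f, AUC %.3f, sens %.3f, spec %.3f, acc %.3f, CV AUC %.3f\n",
                nrow(x$replicates), m["prevalence"], m["auc"],
                m["sensitivity"], m["specificity"], m["accuracy"],
                m["cv_mean_auc"]))
  }
  invisible(x)
}
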