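#' Rank-sum AUC with midrank tie correction
#'
#' The area under the ROC curve computed as the Mann-Whitney statistic with
#' midranks, equivalent to pair counting: (wins + half ties) / (n1 * n0).
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels 0/1 outcome labels; both classes must be present.
#' @return scalar AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  check_two_class(scores, labels)
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' Thresholds descend through the unique score values (classification rule:
#' positive iff `score > threshold`), appending `-Inf` so the curve runs
#' from (0, 0) to (1, 1).
#'
#' @inheritParams roc_auc
#' @return object of class `wase_roc`: `thresholds`, `tpr`, `fpr`, `auc`,
#'   `n_cases`, `n_controls`.
#' @export
roc_curve <- function(scores, labels) {
  check_two_class(scores, labels)
  thr <- c(sort(unique(scores), decreasing = TRUE), -Inf)
  cases <- scores[labels == 1]; controls <- scores[labels == 0]
  tpr <- vapply(thr, function(t) mean(cases > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(controls > t), numeric(1))
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr,
                 auc = roc_auc(scores, labels),
                 n_cases = length(cases), n_controls = length(controls)),
            class = "wase_roc")
}

#' @export
print.wase_roc <- function(x, ...) {
  cat(sprintf("ROC curve: AUC = %.4f (%d cases / %d controls, %d cut-points)\n",
              x$auc, x$n_cases, x$n_controls, length(x$thresholds)))
  invisible(x)
}

#' Youden-optimal operating threshold
#'
#' Returns the threshold maximizing Youden's J = tpr - fpr. Ties in J are
#' broken toward the higher sensitivity, then toward the lower threshold.
#'
#' @param roc a [roc_curve()] result.
#' @return scalar threshold.
#' @export
youden_threshold <- function(roc) {
  if (!length(roc$thresholds)) stop("empty ROC curve")
  j <- roc$tpr - roc$fpr
  cand <- which(j > max(j) - 1e-12)
  cand <- cand[roc$tpr[cand] > max(roc$tpr[cand]) - 1e-12]
  min(roc$thresholds[cand])
}

#' Confusion-matrix metrics at a threshold
#'
#' Classifies positive iff `score > threshold` (strict) and reports
#' sensitivity, specificity, PPV, NPV and accuracy. A metric whose
#' denominator is zero is reported as `NA` (absent), not 0.
#'
#' @inheritParams roc_auc
#' @param threshold finite classification threshold.
#' @return object of class `metric_report` with the counts (`tp`, `fp`,
#'   `tn`, `fn`), the metrics, `threshold`, `n_cases`, `n_controls`.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  if (!is.finite(threshold)) stop("`threshold` must be finite")
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  pos <- scores > threshold
  tp <- sum(pos & labels == 1); fn <- sum(!pos & labels == 1)
  fp <- sum(pos & labels == 0); tn <- sum(!pos & labels == 0)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn, threshold = threshold,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    accuracy = (tp + tn) / length(scores),
    n_cases = tp + fn, n_controls = tn + fp),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Operating point (score > %.4f): %d cases / %d controls\n",
              x$threshold, x$n_cases, x$n_controls))
  for (m in c("auc", "sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    if (is.null(x[[m]])) next
    ci <- x$ci[[m]]
    cat(sprintf("  %-11s %s%s\n", m,
                ifelse(is.na(x[[m]]), "NA", sprintf("%.3f", x[[m]])),
                if (!is.null(ci) && !anyNA(ci))
                  sprintf(" (95%% CI %.3f-%.3f)", ci[1], ci[2]) else ""))
  }
  invisible(x)
}

#' Stratified percentile-bootstrap confidence interval
#'
#' Cases and controls are resampled separately (preserving their counts);
#' the 2.5 and 97.5 percentiles of the `B` resampled statistics form the
#' interval. Resamples on which the statistic is undefined (`NA`/`NaN`) are
#' redrawn, with a retry cap. If only one class is present the resampling
#' degenerates to a simple bootstrap of that class.
#'
#' @param statistic `function(scores, labels)` returning a scalar.
#' @param scores,labels evaluation data.
#' @param B number of resamples (>= 1).
#' @param seed seed for the resampling substream.
#' @param level confidence level.
#' @return numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(statistic, scores, labels, B = 2000L, seed = 42L,
                         level = 0.95) {
  stopifnot(B >= 1, length(scores) == length(labels))
  set.seed(substream_seed(seed, "bootstrap"))
  i1 <- which(labels == 1); i0 <- which(labels == 0)
  stats_b <- numeric(B)
  for (b in seq_len(B)) {
    val <- NA_real_
    for (try in 1:100) {
      idx <- c(if (length(i1)) sample(i1, replace = TRUE),
               if (length(i0)) sample(i0, replace = TRUE))
      val <- statistic(scores[idx], labels[idx])
      if (is.finite(val)) break
    }
    if (!is.finite(val))
      stop("statistic undefined on 100 consecutive resamples")
    stats_b[b] <- val
  }
  alpha <- (1 - level) / 2
  unname(stats::quantile(stats_b, c(alpha, 1 - alpha)))
}

#' Unpaired DeLong comparison of two AUCs
#'
#' Compares the AUCs of two independent samples (e.g. disjoint subgroups)
#' using the placement-value (structural-components) variance estimator:
#' for each sample, `var(AUC) = var(V10)/n1 + var(V01)/n0` where `V10`/`V01`
#' are the case/control placement values, and
#' `z = (auc_a - auc_b) / sqrt(var_a + var_b)` with a two-sided normal p.
#'
#' @param scores_a,labels_a first sample.
#' @param scores_b,labels_b second sample.
#' @return object of class `delong_result`: `auc_a`, `auc_b`, `var_a`,
#'   `var_b`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, labels_a, scores_b, labels_b) {
  a <- delong_components(scores_a, labels_a)
  b <- delong_components(scores_b, labels_b)
  v <- a$var + b$var
  d <- a$auc - b$auc
  if (v <= 0) {
    if (abs(d) < 1e-12) {
      z <- 0
    } else {
      stop("degenerate placement variance; DeLong test undefined")
    }
  } else {
    z <- d / sqrt(v)
  }
  structure(list(auc_a = a$auc, auc_b = b$auc, var_a = a$var, var_b = b$var,
                 z = z, p_value = 2 * stats::pnorm(-abs(z))),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong (unpaired): AUC %.4f vs %.4f, z = %.3f, p = %.4f\n",
              x$auc_a, x$auc_b, x$z, x$p_value))
  invisible(x)
}

# placement values for one sample
delong_components <- function(scores, labels) {
  check_two_class(scores, labels)
  x <- scores[labels == 1]; y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  v10 <- vapply(x, function(xi) (sum(y < xi) + 0.5 * sum(y == xi)) / n,
                numeric(1))
  v01 <- vapply(y, function(yj) (sum(x > yj) + 0.5 * sum(x == yj)) / m,
                numeric(1))
  auc <- mean(v10)
  var_auc <- (if (m > 1) stats::var(v10) / m else 0) +
    (if (n > 1) stats::var(v01) / n else 0)
  list(auc = auc, var = var_auc)
}

#' Hosmer-Lemeshow calibration test
#'
#' Participants are sorted by predicted probability and split into `g`
#' equal-count bins (sizes by largest remainder; tied probabilities are kept
#' in the same bin). The statistic is
#' `chi2 = sum_bins (O1-E1)^2/E1 + (O0-E0)^2/E0` on `df = g - 2` with an
#' upper-tail chi-square p-value. Bins with an expected count of zero in
#' either class are merged with their neighbor (with a message).
#'
#' @param probs predicted probabilities in `[0, 1]`.
#' @param outcomes 0/1 observed outcomes.
#' @param g number of bins (>= 2).
#' @return object of class `calibration_table`: a per-bin data.frame
#'   (`n`, `mean_pred`, `obs_rate`, `expected`, `observed`), `chi2`, `df`,
#'   `p_value`.
#' @export
hosmer_lemeshow <- function(probs, outcomes, g = 10L) {
  stopifnot(length(probs) == length(outcomes), g >= 2,
            all(outcomes %in% c(0, 1)))
  if (any(probs < 0) || any(probs > 1)) stop("probabilities must be in [0, 1]")
  n <- length(probs)
  o <- order(probs)
  p <- probs[o]; y <- outcomes[o]
  sizes <- diff(floor(n * (0:g) / g))
  bin <- rep(seq_len(g), sizes)
  # keep tied probabilities together: pull each tie group into its first bin
  grp <- cumsum(c(TRUE, diff(p) != 0))
  bin <- stats::ave(bin, grp, FUN = min)
  tab <- data.frame(
    bin = sort(unique(bin)),
    n = as.vector(rowsum(rep(1, n), bin)),
    mean_pred = as.vector(rowsum(p, bin)) / as.vector(rowsum(rep(1, n), bin)),
    expected = as.vector(rowsum(p, bin)),
    observed = as.vector(rowsum(y, bin)))
  tab$obs_rate <- tab$observed / tab$n
  # merge bins with a zero expected count in either class
  repeat {
    e0 <- tab$n - tab$expected
    bad <- which(tab$expected == 0 | e0 == 0)
    if (!length(bad) || nrow(tab) <= 2) break
    i <- bad[1]
    j <- if (i == 1) 2L else i - 1L
    message("hosmer_lemeshow: merging bin ", tab$bin[i],
            " into neighbor (zero expected count)")
    tab$n[j] <- tab$n[j] + tab$n[i]
    tab$expected[j] <- tab$expected[j] + tab$expected[i]
    tab$observed[j] <- tab$observed[j] + tab$observed[i]
    tab <- tab[-i, , drop = FALSE]
    tab$mean_pred <- tab$expected / tab$n
    tab$obs_rate <- tab$observed / tab$n
  }
  g_eff <- nrow(tab)
  e1 <- tab$expected; o1 <- tab$observed
  e0 <- tab$n - e1; o0 <- tab$n - o1
  terms <- ifelse(e1 > 0, (o1 - e1)^2 / e1, 0) +
    ifelse(e0 > 0, (o0 - e0)^2 / e0, 0)
  chi2 <- sum(terms)
  df <- g_eff - 2L
  p_value <- if (df >= 1) stats::pchisq(chi2, df, lower.tail = FALSE)
             else NA_real_
  tab$bin <- seq_len(g_eff)
  rownames(tab) <- NULL
  structure(list(table = tab[c("bin", "n", "mean_pred", "obs_rate",
                               "expected", "observed")],
                 chi2 = chi2, df = df, p_value = p_value),
            class = "calibration_table")
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow: chi2 = %.3f on %d df, p = %s\n",
              x$chi2, x$df,
              ifelse(is.na(x$p_value), "NA", sprintf("%.3f", x$p_value))))
  print(x$table, digits = 4)
  invisible(x)
}

#' Full metric report with bootstrap confidence intervals
#'
#' Derives the Youden threshold (unless one is supplied), computes AUC and
#' the confusion metrics at that threshold, and attaches stratified
#' percentile-bootstrap CIs for AUC, sensitivity, specificity, PPV, NPV and
#' accuracy.
#'
#' @inheritParams roc_auc
#' @param threshold operating threshold; `NULL` derives the Youden optimum.
#' @param B bootstrap resamples; 0 skips the CIs.
#' @param seed bootstrap seed.
#' @return a `metric_report` with `auc` and a `ci` list.
#' @export
evaluate_scores <- function(scores, labels, threshold = NULL, B = 2000L,
                            seed = 42L) {
  roc <- roc_curve(scores, labels)
  if (is.null(threshold)) threshold <- youden_threshold(roc)
  rep <- confusion_metrics(scores, labels, threshold)
  rep$auc <- roc$auc
  if (B > 0) {
    stat_fns <- list(
      auc = function(s, l) roc_auc(s, l),
      sensitivity = function(s, l) confusion_metrics(s, l, threshold)$sensitivity,
      specificity = function(s, l) confusion_metrics(s, l, threshold)$specificity,
      ppv = function(s, l) confusion_metrics(s, l, threshold)$ppv,
      npv = function(s, l) confusion_metrics(s, l, threshold)$npv,
      accuracy = function(s, l) confusion_metrics(s, l, threshold)$accuracy)
    rep$ci <- lapply(seq_along(stat_fns), function(i)
      bootstrap_ci(stat_fns[[i]], scores, labels, B = B,
                   seed = substream_seed(seed, names(stat_fns)[i])))
    names(rep$ci) <- names(stat_fns)
  }
  rep
}

check_two_class <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("`scores` and `labels` must have equal length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0)
    stop("both classes (cases and controls) must be present")
  invisible(TRUE)
}
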