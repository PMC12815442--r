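# Shared fixtures, built in code.

# A small fully populated cohort data.frame with known scores and outcomes,
# bypassing the generator (for evaluation-layer tests).
make_toy_cohort <- function(n = 60, seed = 7, prevalence = 0.4) {
  set.seed(seed)
  n1 <- round(n * prevalence)
  injured <- sample(rep(c(1L, 0L), c(n1, n - n1)))
  wase <- runif(n, 0.05, 0.30) + 0.08 * injured
  data.frame(
    id = seq_len(n),
    age = runif(n, 18, 35),
    sex = sample(c("male", "female"), n, replace = TRUE),
    sport = sample(c("running", "jumping", "cutting"), n, replace = TRUE),
    train_hours = runif(n, 2, 15),
    fv_true = runif(n, 0.08, 0.25), ta_true = runif(n, 0.05, 0.20),
    ld_true = runif(n, 0.10, 0.28), ba_true = runif(n, 0.06, 0.22),
    fv = runif(n, 0.08, 0.25), ta = runif(n, 0.05, 0.20),
    ld = runif(n, 0.10, 0.28), ba = runif(n, 0.06, 0.22),
    wase = wase,
    p_injury = plogis(-1.5 + 3 * scale(wase)[, 1]),
    injured = injured,
    stringsAsFactors = FALSE)
}

# Brute-force AUC by explicit pair enumeration (independent oracle).
pair_count_auc <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  tot <- 0
  for (xi in x) for (yj in y)
    tot <- tot + (xi > yj) + 0.5 * (xi == yj)
  tot / (length(x) * length(y))
}

# Small default-study runner used by several files.
fast_study_config <- function(...) {
  study_config(bootstrap_B = 0L, n_weight_configs = 0L, ...)
}
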