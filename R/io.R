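#' Run metadata embedded in every output file
#'
#' A stable record of what produced an output: package version, digest of
#' the canonicalized configuration, master seed, and the named per-stage
#' substream seeds. Deterministic for a given (config, seed) so that
#' repeated runs produce byte-identical files.
#'
#' @param config a `study_config` or `population_config` (or any list).
#' @param seed master seed of the run.
#' @return named list of class `run_metadata`.
#' @export
run_metadata <- function(config, seed) {
  stages <- c("demographics", "components", "noise", "outcomes",
              "cv_folds", "bootstrap", "weight_configs")
  structure(list(
    tool = "wase",
    version = as.character(utils::packageVersion("wase")),
    config_digest = config_digest(config),
    seed = as.integer(seed),
    substreams = stats::setNames(
      lapply(stages, function(s) substream_seed(seed, s)), stages)),
    class = "run_metadata")
}

#' Write / read a cohort as CSV
#'
#' The CSV carries the documented column set
#' `id,age,sex,sport,train_hours,fv_true,ta_true,ld_true,ba_true,fv,ta,ld,ba`
#' plus `wase`, `p_injury`, `injured` when present (measured components
#' under the bare names), preceded by `#`-prefixed run-metadata comment
#' lines. Numbers are written with 17 significant digits so the file
#' round-trips exactly. `read_cohort()` validates the column set, numeric
#' domains (components within plausibility bounds, `injured` in {0, 1},
#' `sex`/`sport` labels) and reports offending row numbers.
#'
#' @param cohort a `wase_cohort` data.frame.
#' @param path output path.
#' @param metadata a [run_metadata()]; derived from the cohort's attributes
#'   when omitted.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a `wase_cohort`.
#' @export
write_cohort <- function(cohort, path, metadata = NULL) {
  if (is.null(metadata)) {
    cfg <- attr(cohort, "config")
    seed <- attr(cohort, "seed")
    metadata <- run_metadata(if (is.null(cfg)) list() else cfg,
                             if (is.null(seed)) 0L else seed)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", metadata_lines(metadata)), con)
  df <- as.data.frame(cohort)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "id" &
    names(df) != "injured"
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

metadata_lines <- function(md) {
  c(paste0("tool: ", md$tool, " ", md$version),
    paste0("config_digest: ", md$config_digest),
    paste0("seed: ", md$seed),
    paste0("substreams: ",
           paste(names(md$substreams), unlist(md$substreams),
                 sep = "=", collapse = " ")))
}

#' @rdname write_cohort
#' @param bounds 4 x 2 plausibility bounds used to validate the component
#'   columns on read.
#' @export
read_cohort <- function(path,
                        bounds = matrix(c(0, 0.5), 4, 2, byrow = TRUE)) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("id", "age", "sex", "sport", "train_hours",
                "fv_true", "ta_true", "ld_true", "ba_true",
                "fv", "ta", "ld", "ba")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("cohort CSV missing column(s): ", paste(missing, collapse = ", "))
  numcols <- c("age", "train_hours", "fv_true", "ta_true", "ld_true",
               "ba_true", "fv", "ta", "ld", "ba", "wase", "p_injury")
  for (cl in intersect(numcols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (length(bad))
      stop("non-numeric value in column `", cl, "` on row ", bad[1])
    df[[cl]] <- v
  }
  for (i in seq_along(c("fv", "ta", "ld", "ba"))) {
    cl <- c("fv", "ta", "ld", "ba")[i]
    for (suffix in c("", "_true")) {
      col <- paste0(cl, suffix)
      bad <- which(df[[col]] < bounds[i, 1] | df[[col]] > bounds[i, 2])
      if (length(bad))
        stop("column `", col, "` outside plausibility bounds on row ", bad[1])
    }
  }
  bad <- which(!df$sex %in% c("male", "female"))
  if (length(bad)) stop("unknown sex label on row ", bad[1])
  bad <- which(!df$sport %in% c("running", "jumping", "cutting"))
  if (length(bad)) stop("unknown sport label on row ", bad[1])
  if ("injured" %in% names(df)) {
    bad <- which(!df$injured %in% c(0L, 1L))
    if (length(bad))
      stop("column `injured` must be 0/1; violation on row ", bad[1])
  }
  if ("p_injury" %in% names(df)) {
    bad <- which(df$p_injury < 0 | df$p_injury > 1)
    if (length(bad)) stop("`p_injury` outside [0, 1] on row ", bad[1])
  }
  if (anyDuplicated(df$id)) stop("participant ids must be unique")
  structure(df, class = c("wase_cohort", "data.frame"))
}

#' Serialize a study report
#'
#' `study_report_json()` renders the full [run_full_study()] result (minus
#' the raw cohort) as canonical JSON with embedded run metadata;
#' `study_report_markdown()` renders the human-readable report with the
#' population, performance, cross-validation, subgroup, calibration and
#' sensitivity tables; `write_study_report()` writes both (plus per-table
#' CSVs and the ROC curve CSV) into a directory.
#'
#' @param study a `wase_study`.
#' @return `study_report_json()` a JSON string; `study_report_markdown()` a
#'   character vector of lines; `write_study_report()` the directory,
#'   invisibly.
#' @export
study_report_json <- function(study) {
  md <- run_metadata(study$config, study$config$seed)
  x <- list(
    metadata = unclass_deep(md),
    population = lapply(study$population, function(v)
      if (inherits(v, "table")) as.list(v) else v),
    linkage = unclass(study$linkage),
    metrics = unclass(study$metrics),
    cross_validation = study$cv,
    subgroups = list(table = study$subgroups$table,
                     threshold = study$subgroups$threshold,
                     delong = delong_summaries(study$subgroups$delong)),
    calibration = unclass(study$calibration),
    sensitivity = study$sensitivity,
    replicates = study$replicates,
    replicate_mean = as.list(study$replicate_mean),
    replicate_sd = as.list(study$replicate_sd))
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = 17, pretty = TRUE,
                   dataframe = "rows", na = "null")
}

delong_md <- function(dl) {
  fmt_one <- function(name, d) {
    if (is.null(d)) return(character(0))
    sprintf("- %s: AUC %.3f vs %.3f, z = %.3f, p = %.3f", name,
            d$auc_a, d$auc_b, d$z, d$p_value)
  }
  c("DeLong comparisons (unpaired):",
    fmt_one("male vs female", dl$sex),
    fmt_one("age 18-25 vs 26-35", dl$age),
    if (!is.null(dl$sport)) fmt_one(dl$sport_headline, dl$sport))
}

delong_summaries <- function(dl) {
  f <- function(d) if (is.null(d)) NULL else unclass(d)
  out <- list(sex = f(dl$sex), age = f(dl$age), sport = f(dl$sport),
              sport_headline = dl$sport_headline)
  if (!is.null(dl$sport_pairs)) out$sport_pairs <- lapply(dl$sport_pairs, f)
  out
}

#' @rdname study_report_json
#' @export
study_report_markdown <- function(study) {
  p <- study$population
  m <- study$metrics
  fmt <- function(x, d = 3) ifelse(is.na(x), "NA", sprintf(paste0("%.", d, "f"), x))
  ci <- function(name) {
    if (is.null(m$ci[[name]])) return("")
    sprintf(" (%s-%s)", fmt(m$ci[[name]][1]), fmt(m$ci[[name]][2]))
  }
  lines <- c(
    "# WASe validation study report",
    "",
    sprintf("Config digest: `%s`; master seed %d.", study$config_digest,
            study$config$seed),
    "",
    "## Population",
    "",
    "| Characteristic | Value |",
    "| --- | --- |",
    sprintf("| Sample size | %d |", p$n),
    sprintf("| Age (years) | %.1f +/- %.1f |", p$age_mean, p$age_sd),
    sprintf("| Sex | %s |",
            paste(names(p$sex_counts), p$sex_counts, collapse = ", ")),
    sprintf("| Sport | %s |",
            paste(names(p$sport_counts), p$sport_counts, collapse = ", ")),
    sprintf("| Training hours/week | %.1f +/- %.1f |", p$train_mean, p$train_sd),
    sprintf("| Injury rate | %.1f%% (%d cases) |", 100 * p$injury_rate,
            round(p$injury_rate * p$n)),
    "",
    "## Performance",
    "",
    "| Metric | Value | 95% CI |",
    "| --- | --- | --- |",
    sprintf("| AUC | %s |%s |", fmt(m$auc), ci("auc")),
    sprintf("| Sensitivity | %s |%s |", fmt(m$sensitivity), ci("sensitivity")),
    sprintf("| Specificity | %s |%s |", fmt(m$specificity), ci("specificity")),
    sprintf("| PPV | %s |%s |", fmt(m$ppv), ci("ppv")),
    sprintf("| NPV | %s |%s |", fmt(m$npv), ci("npv")),
    sprintf("| Accuracy | %s |%s |", fmt(m$accuracy), ci("accuracy")),
    "",
    sprintf("Operating threshold (Youden): %.5f.", m$threshold),
    "",
    "## Cross-validation",
    "",
    "| Fold | AUC | Sensitivity | Specificity | Accuracy |",
    "| --- | --- | --- | --- | --- |",
    sprintf("| %d | %s | %s | %s | %s |", study$cv$folds$fold,
            fmt(study$cv$folds$auc), fmt(study$cv$folds$sensitivity),
            fmt(study$cv$folds$specificity), fmt(study$cv$folds$accuracy)),
    sprintf("| Mean +/- SD | %s +/- %s | %s +/- %s | %s +/- %s | %s +/- %s |",
            fmt(study$cv$mean["auc"]), fmt(study$cv$sd["auc"], 3),
            fmt(study$cv$mean["sensitivity"]), fmt(study$cv$sd["sensitivity"], 3),
            fmt(study$cv$mean["specificity"]), fmt(study$cv$sd["specificity"], 3),
            fmt(study$cv$mean["accuracy"]), fmt(study$cv$sd["accuracy"], 3)),
    "",
    "## Subgroups",
    "",
    "| Variable | Subgroup | N | AUC | Sensitivity | Specificity |",
    "| --- | --- | --- | --- | --- | --- |",
    sprintf("| %s | %s | %d | %s | %s | %s |",
            study$subgroups$table$variable, study$subgroups$table$subgroup,
            study$subgroups$table$n, fmt(study$subgroups$table$auc),
            fmt(study$subgroups$table$sensitivity),
            fmt(study$subgroups$table$specificity)),
    "",
    delong_md(study$subgroups$delong),
    "",
    "## Calibration",
    "",
    sprintf("Hosmer-Lemeshow chi2 = %.2f on %d df, p = %s.",
            study$calibration$chi2, study$calibration$df,
            fmt(study$calibration$p_value)),
    "",
    "## Weight sensitivity",
    "",
    sprintf("Max |dAUC| over +/-%.2f single-weight perturbations: %.4f.",
            study$config$sensitivity_delta,
            study$sensitivity$max_abs_delta_auc),
    sprintf("Max |dAUC| over %d random configurations: %.4f.",
            study$config$n_weight_configs,
            study$sensitivity$max_abs_delta_auc_random))
  if (nrow(study$replicates) > 1) {
    rm_ <- study$replicate_mean
    lines <- c(lines, "", "## Replicate means",
               sprintf(paste("Over %d replicate seeds: prevalence %.3f,",
                             "AUC %.3f, sensitivity %.3f, specificity %.3f,",
                             "accuracy %.3f, CV mean AUC %.3f."),
                       nrow(study$replicates), rm_["prevalence"], rm_["auc"],
                       rm_["sensitivity"], rm_["specificity"],
                       rm_["accuracy"], rm_["cv_mean_auc"]))
  }
  lines
}

#' @rdname study_report_json
#' @param dir output directory (created if absent).
#' @export
write_study_report <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(study_report_json(study), file.path(dir, "report.json"))
  writeLines(study_report_markdown(study), file.path(dir, "report.md"))
  md <- metadata_lines(run_metadata(study$config, study$config$seed))
  write_table_csv <- function(df, name) {
    con <- file(file.path(dir, name), "w")
    on.exit(close(con))
    writeLines(paste0("# ", md), con)
    utils::write.csv(df, con, row.names = FALSE)
  }
  write_table_csv(study$cv$folds, "cv_folds.csv")
  write_table_csv(study$subgroups$table, "subgroups.csv")
  write_table_csv(study$calibration$table, "calibration.csv")
  write_table_csv(study$sensitivity$perturbations, "sensitivity.csv")
  if (!is.null(study$cohort)) {
    roc <- roc_curve(study$cohort$wase, study$cohort$injured)
    write_table_csv(data.frame(fpr = roc$fpr, tpr = roc$tpr), "roc.csv")
    write_cohort(study$cohort, file.path(dir, "cohort.csv"))
  }
  invisible(dir)
}
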