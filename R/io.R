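# CSV dialects, trial-config files, run reports and the two pipelines.

#' Read a cohort CSV
#'
#' Expected header: `subject_id,group,lifespan_days,event`; the `event` column
#' is optional and defaults to 1 (death observed) with a notice.
#'
#' @param path Path to the CSV file.
#' @return A [cohort_table].
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "lifespan_days")
  if (!all(need %in% names(df))) {
    stop("cohort CSV must have header subject_id,group,lifespan_days[,event]")
  }
  if (!"event" %in% names(df)) {
    message("cohort CSV has no event column; assuming all deaths observed (event = 1)")
    df$event <- 1L
  }
  bad <- which(!is.finite(df$lifespan_days) | df$lifespan_days <= 0 |
                 df$lifespan_days != round(df$lifespan_days))
  if (length(bad)) {
    stop("line ", bad[1] + 1L, ": lifespan_days must be a positive integer")
  }
  bad_ev <- which(!df$event %in% c(0, 1))
  if (length(bad_ev)) stop("line ", bad_ev[1] + 1L, ": event must be 0 or 1")
  cohort_table(df$subject_id, df$group, df$lifespan_days, df$event)
}

#' Write a cohort CSV
#' @param cohort A [cohort_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  out <- data.frame(
    subject_id = cohort$subject_id, group = cohort$group,
    lifespan_days = as.integer(cohort$time), event = as.integer(cohort$event)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dose-response CSV
#'
#' Expected header: `group,cell_id,concentration_mM,response_pApF`.
#'
#' @param path Path to the CSV file.
#' @return Data frame with the four columns, validated.
#' @export
read_dose_response_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "cell_id", "concentration_mM", "response_pApF")
  if (!all(need %in% names(df))) {
    stop("dose-response CSV must have header group,cell_id,concentration_mM,response_pApF")
  }
  bad <- which(!is.finite(df$concentration_mM) | df$concentration_mM < 0)
  if (length(bad)) stop("line ", bad[1] + 1L, ": concentration_mM must be >= 0")
  bad_r <- which(!is.finite(df$response_pApF))
  if (length(bad_r)) stop("line ", bad_r[1] + 1L, ": response_pApF must be finite")
  df[, need]
}

#' Write a dose-response CSV
#' @param data Data frame with columns `group`, `cell_id`, `concentration_mM`,
#'   `response_pApF`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dose_response_csv <- function(data, path) {
  need <- c("group", "cell_id", "concentration_mM", "response_pApF")
  stopifnot(all(need %in% names(data)))
  utils::write.csv(data[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial configuration file
#'
#' Plain-text `key = value` format with one `group = label, n, multiplier`
#' line per cohort, e.g.
#' ```
#' b = 0.006
#' control_mean_days = 886
#' group = Control, 335, 1
#' group = DR, 60, 0.265
#' ```
#' The baseline hazard `a` is calibrated so the analytic mean equals
#' `control_mean_days`.
#'
#' @param path Path to the config file.
#' @param seed Master seed for the resulting [trial_config].
#' @return A [trial_config].
#' @export
read_trial_config <- function(path, seed) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop("malformed config line")
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  b <- as.numeric(vals[keys == "b"][1])
  cm <- as.numeric(vals[keys == "control_mean_days"][1])
  if (!is.finite(b) || !is.finite(cm)) stop("config must set b and control_mean_days")
  gl <- strsplit(vals[keys == "group"], ",", fixed = TRUE)
  if (!length(gl)) stop("config must declare at least one group")
  groups <- do.call(rbind, lapply(gl, function(x) {
    if (length(x) != 3L) stop("group line must be 'label, n, multiplier'")
    data.frame(label = trimws(x[1]), n = as.integer(x[2]),
               multiplier = as.numeric(x[3]), stringsAsFactors = FALSE)
  }))
  trial_config(calibrate_gompertz(cm, b = b), groups, seed = seed)
}

#' Write a trial configuration file
#' @param config A [trial_config].
#' @param path Output path.
#' @param control_mean_days Analytic control mean recorded in the file
#'   (default: recomputed from the config's Gompertz parameters).
#' @return `path`, invisibly.
#' @export
write_trial_config <- function(config, path,
                               control_mean_days = gompertz_mean(config$gompertz)) {
  stopifnot(inherits(config, "trial_config"))
  lines <- c(
    sprintf("b = %.10g", config$gompertz$b),
    sprintf("control_mean_days = %.10g", control_mean_days),
    sprintf("group = %s, %d, %.10g",
            config$groups$label, config$groups$n, config$groups$multiplier)
  )
  writeLines(lines, path)
  invisible(path)
}

run_report <- function(analysis, inputs, results, warnings = character()) {
  structure(
    list(
      tool = "lifeconv",
      version = as.character(utils::packageVersion("lifeconv")),
      analysis = analysis, inputs = inputs, results = results,
      warnings = warnings
    ),
    class = "run_report"
  )
}

file_digest <- function(path) {
  if (is.null(path) || !file.exists(path)) return(NA_character_)
  unname(tools::md5sum(path))
}

#' Run the full longevity analysis pipeline
#'
#' Simulated-or-real cohort in, Fig-style summary out: per-group mean
#' lifespans, percent of control, exact convolution-test and log-rank
#' p-values, an optional pooled row, and Kaplan-Meier curves per group.
#'
#' @param cohort A [cohort_table], or a path to a cohort CSV.
#' @param control_label Label of the control group.
#' @param pool Optional pooling spec, see [summarize_cohorts].
#' @param two_sided Passed to the exact test.
#' @return A `run_report` whose `results` hold the `summary`
#'   ([summarize_cohorts]) and a named list of `km` curves.
#' @export
run_longevity_pipeline <- function(cohort, control_label, pool = NULL,
                                   two_sided = FALSE) {
  path <- NULL
  if (is.character(cohort)) { path <- cohort; cohort <- read_cohort_csv(cohort) }
  summary <- summarize_cohorts(cohort, control_label, pool = pool,
                               two_sided = two_sided)
  km <- lapply(split(cohort, cohort$group), function(sub) {
    km_curve(sub$time, sub$event)
  })
  run_report(
    analysis = "longevity",
    inputs = list(cohort_csv = path, cohort_md5 = file_digest(path),
                  control_label = control_label,
                  pooled = if (is.null(pool)) NULL else pool$label,
                  two_sided = two_sided),
    results = list(summary = summary, km = km)
  )
}

#' Run the dose-response analysis pipeline
#'
#' Fits a Hill curve per group; when exactly two groups are selected the
#' curves are compared by the extra sum-of-squares F test.
#'
#' @param data Dose-response data frame, or path to a dose-response CSV.
#' @param groups Character vector of group labels to analyse (default: all).
#' @param mode Comparison mode, see [compare_curves].
#' @return A `run_report` whose `results` hold per-group `fits` and, for two
#'   groups, a `comparison`.
#' @export
run_dose_response_pipeline <- function(data, groups = NULL,
                                       mode = "all-shared") {
  path <- NULL
  if (is.character(data)) { path <- data; data <- read_dose_response_csv(data) }
  if (is.null(groups)) groups <- unique(data$group)
  missing_g <- setdiff(groups, data$group)
  if (length(missing_g)) stop("groups not found: ", paste(missing_g, collapse = ", "))
  fits <- lapply(groups, function(g) {
    sub <- data[data$group == g, ]
    fit_hill(sub$concentration_mM, sub$response_pApF)
  })
  names(fits) <- groups
  comparison <- NULL
  if (length(groups) == 2L) {
    a <- data[data$group == groups[1], ]
    b <- data[data$group == groups[2], ]
    comparison <- compare_curves(a$concentration_mM, a$response_pApF,
                                 b$concentration_mM, b$response_pApF,
                                 mode = mode)
  }
  run_report(
    analysis = "dose_response",
    inputs = list(dose_response_csv = path, dose_response_md5 = file_digest(path),
                  groups = groups, mode = mode),
    results = list(fits = fits, comparison = comparison)
  )
}

# flatten S3 result objects into plain lists for JSON
report_payload <- function(report) {
  strip <- function(x) {
    if (inherits(x, "hill_fit")) {
      return(list(params = unclass(x$params), se = as.list(x$se),
                  rss = x$rss, df = x$df, n = x$n))
    }
    if (inherits(x, "curve_comparison")) {
      return(list(F = x$F, df_num = x$df_num, df_den = x$df_den,
                  p_value = x$p_value, mode = x$mode,
                  ss_null = x$ss_null, ss_full = x$ss_full,
                  degenerate = x$degenerate,
                  fitA = strip(x$fitA), fitB = strip(x$fitB)))
    }
    if (inherits(x, "mean_lifespan_test") || inherits(x, "logrank_test")) {
      return(lapply(unclass(x), strip))
    }
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  strip(unclass(report))
}

#' Serialize a run report to JSON
#'
#' @param report A `run_report`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "run_report"))
  json <- jsonlite::toJSON(report_payload(report), auto_unbox = TRUE,
                           digits = NA, null = "null", na = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s (lifeconv %s)\n", x$analysis, x$version))
  if (x$analysis == "longevity") {
    print(x$results$summary)
  } else {
    for (g in names(x$results$fits)) {
      cat(sprintf("-- %s --\n", g)); print(x$results$fits[[g]])
    }
    if (!is.null(x$results$comparison)) print(x$results$comparison)
  }
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
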