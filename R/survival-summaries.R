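# Standard survival comparators and the per-group cohort summary table.
# Kaplan-Meier and log-rank computations delegate to the survival package;
# the exact convolution test supplies the per-group mean-lifespan p-values.

#' Assemble and validate a cohort table
#'
#' A cohort table holds one row per animal: `subject_id`, `group`, `time`
#' (lifespan in days, `> 0`) and `event` (1 = death observed, 0 =
#' right-censored).
#'
#' @param subject_id Character vector of unique animal labels.
#' @param group Character vector of group labels.
#' @param time Positive lifespans in days.
#' @param event 0/1 event indicators (default all 1).
#' @return A `data.frame` of class `cohort_table`.
#' @export
cohort_table <- function(subject_id, group, time, event = rep(1L, length(time))) {
  n <- length(time)
  stopifnot(length(subject_id) == n, length(group) == n, length(event) == n)
  if (anyDuplicated(subject_id)) stop("subject_id must be unique")
  if (any(!is.finite(time)) || any(time <= 0)) stop("lifespans must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  out <- data.frame(
    subject_id = as.character(subject_id), group = as.character(group),
    time = as.numeric(time), event = as.integer(event),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Kaplan-Meier product-limit survival curve
#'
#' @param time Positive event/censoring times in days.
#' @param event 0/1 indicators (1 = death); default all deaths.
#' @return A `km_curve` object: data frame with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival` (non-increasing, starting from 1).
#' @examples
#' km_curve(c(2, 4))
#' @export
km_curve <- function(time, event = rep(1L, length(time))) {
  if (length(time) == 0L) stop("no observations")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "none")
  out <- data.frame(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, survival = fit$surv
  )
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank (Mantel-Haenszel) test
#'
#' Tie-aware log-rank comparison with the hypergeometric variance; the
#' chi-square statistic has 1 degree of freedom. A group with no events is
#' allowed (the statistic is computed over the available event times); two
#' groups with no events at all is an error.
#'
#' @param time Positive times in days for both groups combined.
#' @param group Two-level group labels aligned with `time`.
#' @param event 0/1 indicators (default all 1).
#' @return A `logrank_test` object: `statistic`, `df`, `p_value`, and named
#'   `observed` / `expected` death counts per group.
#' @examples
#' logrank_test(c(1, 2, 3, 4), c("A", "A", "B", "B"))
#' @export
logrank_test <- function(time, group, event = rep(1L, length(time))) {
  group <- as.character(group)
  labs <- unique(group)
  if (length(labs) != 2L) stop("logrank_test compares exactly two groups")
  if (length(time) == 0L || !all(table(group) >= 1L)) stop("both groups must be non-empty")
  if (sum(event) == 0L) stop("no events")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  obs <- as.numeric(sd$obs); exp_ <- as.numeric(sd$exp)
  names(obs) <- names(exp_) <- sub("^group=", "", names(sd$n))
  structure(
    list(
      statistic = as.numeric(sd$chisq), df = 1L,
      p_value = stats::pchisq(as.numeric(sd$chisq), df = 1, lower.tail = FALSE),
      observed = obs, expected = exp_
    ),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f (df = %d), p = %.4g\n",
              x$statistic, x$df, x$p_value))
  tab <- rbind(observed = x$observed, expected = round(x$expected, 3))
  print(tab)
  invisible(x)
}

#' Tumour/lesion prevalence as an integer percent
#'
#' @param affected Number of affected animals (`0 <= affected <= total`).
#' @param total Number examined (`> 0`).
#' @return `round(100 * affected / total)`, ties rounded half-to-even.
#' @examples
#' prevalence_percent(58, 88)  # 66
#' @export
prevalence_percent <- function(affected, total) {
  if (length(total) != 1L || total <= 0) stop("empty denominator")
  if (affected < 0 || affected > total) stop("affected must lie in [0, total]")
  round(100 * affected / total)
}

#' Per-group cohort summary: mean lifespan, percent of control, p-values
#'
#' Produces the standard whole-life trial table: one row per group with its
#' size, mean lifespan, percent of the control mean (rounded to the nearest
#' integer for display; the unrounded value is kept in
#' `percent_of_control_raw`), the exact convolution-test p-value and the
#' log-rank p-value versus control. An optional pooled row concatenates a set
#' of treated groups. The exact test requires complete lifespans, so any
#' censored record in the control or in a tested group is an error.
#'
#' @param cohort A [cohort_table] (or data frame with the same columns).
#' @param control_label Label of the reference group.
#' @param pool Optional named list `list(label = , groups = )` defining a
#'   pooled row, e.g. all supplemented groups as one cohort.
#' @param two_sided Passed to [convolution_mean_test].
#' @return A `cohort_summary` data frame with columns `group`, `n`,
#'   `mean_days`, `percent_of_control`, `percent_of_control_raw`, `p_exact`,
#'   `p_logrank`. The control row has percent 100 and `NA` p-values.
#' @export
summarize_cohorts <- function(cohort, control_label, pool = NULL,
                              two_sided = FALSE) {
  stopifnot(is.data.frame(cohort),
            all(c("group", "time", "event") %in% names(cohort)))
  if (!control_label %in% cohort$group) stop("control group not found")
  ctrl <- cohort[cohort$group == control_label, ]
  if (any(ctrl$event == 0)) stop("exact mean test requires complete lifespans")
  control <- ctrl$time
  control_mean <- mean(round(control))

  groups <- setdiff(unique(cohort$group), control_label)
  one_row <- function(label, sub) {
    if (any(sub$event == 0)) stop("exact mean test requires complete lifespans")
    tst <- convolution_mean_test(control, sub$time, two_sided = two_sided)
    lr <- logrank_test(
      c(ctrl$time, sub$time),
      c(rep(control_label, nrow(ctrl)), rep(label, nrow(sub))),
      c(ctrl$event, sub$event)
    )
    pct <- 100 * mean(round(sub$time)) / control_mean
    data.frame(
      group = label, n = nrow(sub), mean_days = mean(round(sub$time)),
      percent_of_control = round(pct), percent_of_control_raw = pct,
      p_exact = tst$p_value, p_logrank = lr$p_value,
      stringsAsFactors = FALSE
    )
  }

  rows <- list(data.frame(
    group = control_label, n = nrow(ctrl), mean_days = control_mean,
    percent_of_control = 100, percent_of_control_raw = 100,
    p_exact = NA_real_, p_logrank = NA_real_, stringsAsFactors = FALSE
  ))
  for (g in groups) rows[[length(rows) + 1L]] <- one_row(g, cohort[cohort$group == g, ])
  if (!is.null(pool)) {
    missing_g <- setdiff(pool$groups, cohort$group)
    if (length(missing_g)) stop("pooled groups not found: ", paste(missing_g, collapse = ", "))
    sub <- cohort[cohort$group %in% pool$groups, ]
    rows[[length(rows) + 1L]] <- one_row(pool$label, sub)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  fmt <- function(p) ifelse(is.na(p), "-", formatC(p, format = "g", digits = 3))
  tab <- data.frame(
    group = x$group, n = x$n,
    `mean (days)` = formatC(x$mean_days, format = "f", digits = 1),
    `% of control` = x$percent_of_control,
    p_exact = fmt(x$p_exact), p_logrank = fmt(x$p_logrank),
    check.names = FALSE
  )
  cat("Mean survival by cohort (percent of control mean)\n")
  print(tab, row.names = FALSE)
  invisible(x)
}
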