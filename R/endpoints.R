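# Group-level endpoint statistics: median/IQR summaries, rank-based group
# comparisons (delegating to the package's Mann-Whitney machinery), and
# Kaplan-Meier survival with the log-rank (Mantel-Cox) test.  Survival
# curves and the log-rank statistic come from the survival package; the
# median-survival convention (earliest time with estimate <= 0.5) is applied
# to the returned step function.

#' Median/IQR summary of one group
#'
#' @param values Nonempty numeric vector of per-subject measurements.
#' @param group_label Label carried into result tables.
#' @param quantile_type Quantile convention for the IQR (default 7, linear
#'   interpolation between order statistics).
#' @return A list of class `group_summary`: `group_label`, `n`, `median`,
#'   `iqr_low`, `iqr_high`, `values`.
#' @export
summarize_group <- function(values, group_label = "", quantile_type = 7) {
  values <- as.numeric(values)
  bbb_assert(length(values) >= 1 && all(is.finite(values)),
             "bbbmap_data_error", "summarize_group: empty or non-finite input")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = quantile_type))
  structure(list(group_label = group_label, n = length(values),
                 median = q[2], iqr_low = q[1], iqr_high = q[3],
                 values = values),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: n = %d, median %.4g (IQR %.4g-%.4g)\n", x$group_label,
              x$n, x$median, x$iqr_low, x$iqr_high))
  invisible(x)
}

#' Compare two groups by the Mann-Whitney U test
#'
#' Unpaired rank comparison of the raw per-subject values (accepts
#' `group_summary` objects or numeric vectors).
#'
#' @param summary_a,summary_b `group_summary` objects or numeric vectors.
#' @inheritParams mwu_test
#' @return An `mwu_result`.
#' @export
compare_groups <- function(summary_a, summary_b,
                           alternative = c("two_sided", "a_greater",
                                           "b_greater"), ...) {
  alternative <- match.arg(alternative)
  va <- if (inherits(summary_a, "group_summary")) summary_a$values else summary_a
  vb <- if (inherits(summary_b, "group_summary")) summary_b$values else summary_b
  mwu_test(va, vb, alternative = alternative, ...)
}

#' Build a survival table
#'
#' @param subject_id,group_label,time,event Vectors of equal length; `time`
#'   must be positive, `event` 1 (endpoint reached) or 0 (censored).
#' @return A validated data frame of class `survival_table`.
#' @export
survival_table <- function(subject_id, group_label, time, event) {
  tab <- data.frame(subject_id = as.character(subject_id),
                    group_label = as.character(group_label),
                    time = as.numeric(time), event = as.integer(event),
                    stringsAsFactors = FALSE)
  bbb_assert(nrow(tab) > 0, "bbbmap_data_error", "empty survival table")
  bbb_assert(all(is.finite(tab$time)) && all(tab$time > 0),
             "bbbmap_data_error", "survival times must be positive")
  bbb_assert(all(tab$event %in% c(0L, 1L)), "bbbmap_data_error",
             "event flags must be 0 (censored) or 1 (event)")
  class(tab) <- c("survival_table", "data.frame")
  tab
}

#' Read a survival table from CSV
#'
#' Expects columns `subject_id`, `group_label` (or `group`), `time`,
#' `event`.
#' @param path CSV file path.
#' @return A `survival_table`.
#' @export
read_survival_table <- function(path) {
  bbb_assert(file.exists(path), "bbbmap_data_error", "no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"group_label" %in% names(df) && "group" %in% names(df)) {
    df$group_label <- df$group
  }
  need <- c("subject_id", "group_label", "time", "event")
  bbb_assert(all(need %in% names(df)), "bbbmap_data_error",
             "survival CSV must have columns %s", paste(need, collapse = ", "))
  survival_table(df$subject_id, df$group_label, df$time, df$event)
}

#' Read a per-subject endpoint value table from CSV
#'
#' Generic loader for tabulated per-subject measurements (relative volumes,
#' radiance, behavioral scores). Expects columns `subject_id`, `group_label`
#' (or `group`) and the named value column; optional bounds are validated on
#' load (for example `c(0, 18)` for a neurological severity score).
#'
#' @param path CSV file.
#' @param value_col Name of the value column (default `"value"`).
#' @param bounds Optional `c(low, high)` inclusive range the values must lie
#'   in; violations are a data error.
#' @param integer_valued Require whole-number values (scores).
#' @return A data frame with `subject_id`, `group_label`, `value`.
#' @export
read_endpoint_values <- function(path, value_col = "value", bounds = NULL,
                                 integer_valued = FALSE) {
  bbb_assert(file.exists(path), "bbbmap_data_error", "no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"group_label" %in% names(df) && "group" %in% names(df)) {
    df$group_label <- df$group
  }
  need <- c("subject_id", "group_label", value_col)
  bbb_assert(all(need %in% names(df)), "bbbmap_data_error",
             "endpoint CSV must have columns %s", paste(need, collapse = ", "))
  v <- df[[value_col]]
  bbb_assert(is.numeric(v) && all(is.finite(v)), "bbbmap_data_error",
             "column '%s' must be finite numeric", value_col)
  if (!is.null(bounds)) {
    bbb_assert(all(v >= bounds[1] & v <= bounds[2]), "bbbmap_data_error",
               "column '%s' outside [%g, %g]", value_col, bounds[1], bounds[2])
  }
  if (integer_valued) {
    bbb_assert(all(v == round(v)), "bbbmap_data_error",
               "column '%s' must be integer-valued", value_col)
  }
  data.frame(subject_id = as.character(df$subject_id),
             group_label = as.character(df$group_label), value = v,
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier estimate for one group
#'
#' Product-limit estimate with the standard convention that events precede
#' censorings at tied times. The median survival is the earliest time at
#' which the estimate drops to 0.5 or below; when the curve never reaches
#' 0.5 (for example when every subject is censored) the median is `NA` and
#' `median_defined` is `FALSE`.
#'
#' @param table A `survival_table`.
#' @param group_label Group to estimate; `NULL` uses all rows.
#' @return A list of class `km_estimate`: `steps` (data frame `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`), `median`, `median_defined`,
#'   `n`, `group_label`.
#' @export
km_estimate <- function(table, group_label = NULL) {
  bbb_assert(inherits(table, "survival_table"), "bbbmap_data_error",
             "table must be a survival_table")
  rows <- if (is.null(group_label)) table else
    table[table$group_label == group_label, ]
  bbb_assert(nrow(rows) >= 1, "bbbmap_data_error",
             "group '%s' has no rows", group_label %||% "(all)")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = rows,
                           conf.type = "none")
  steps <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv)
  reached <- steps$surv <= 0.5 & steps$n_event > 0
  med_def <- any(reached)
  med <- if (med_def) min(steps$time[reached]) else NA_real_
  structure(list(steps = steps, median = med, median_defined = med_def,
                 n = nrow(rows), group_label = group_label %||% "(all)"),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier [%s]: n = %d, median survival %s\n",
              x$group_label, x$n,
              if (x$median_defined) format(x$median) else "not reached"))
  invisible(x)
}

#' Log-rank (Mantel-Cox) test across groups
#'
#' Chi-squared statistic from observed-minus-expected events over the pooled
#' event times, with `k - 1` degrees of freedom.
#'
#' @param table A `survival_table` with at least two groups and at least one
#'   event.
#' @return A list of class `logrank_result`: `chisq`, `df`, `p`, `n`,
#'   `groups`.
#' @export
logrank_test <- function(table) {
  bbb_assert(inherits(table, "survival_table"), "bbbmap_data_error",
             "table must be a survival_table")
  groups <- unique(table$group_label)
  bbb_assert(length(groups) >= 2, "bbbmap_data_error",
             "log-rank test needs at least two groups")
  bbb_assert(sum(table$event) >= 1, "bbbmap_data_error",
             "log-rank test needs at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group_label,
                           data = table)
  df <- length(groups) - 1L
  structure(list(chisq = unname(sd$chisq), df = df,
                 p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 n = nrow(table), groups = groups),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank (Mantel-Cox): chi-squared = %.4g, df = %d, p = %.4g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}
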