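#' Phase-duration summary stratified by TAT compliance
#'
#' Summarizes the pre-analytical, analytical + post-analytical, and overall
#' TAT durations for the whole log and for the two compliance strata
#' (reported within the TAT limit vs. after it): counts, percentage of total
#' (two decimals), and mean / sample (n-1) standard deviation per phase. An
#' empty stratum keeps `n = 0` with `NA` moments.
#'
#' @param log a non-empty [event_log()].
#' @param limit TAT guideline in minutes; defaults to the log's own limit.
#' @return an object of class `phase_summary`: a `data.frame` with one row
#'   per stratum (`overall`, `within_limit`, `after_limit`) and columns `n`,
#'   `percent`, `pre_mean`, `pre_sd`, `post_mean`, `post_sd`, `tat_mean`,
#'   `tat_sd`.
#' @export
phase_summary <- function(log, limit = tat_limit(log)) {
  stopifnot(inherits(log, "event_log"))
  if (nrow(log) == 0L) stop("cannot summarize an empty event log")
  d <- durations(log)
  within <- d$overall_tat <= limit
  one <- function(sel) {
    n <- sum(sel)
    moments <- function(v) {
      if (n == 0L) c(NA_real_, NA_real_)
      else c(mean(v[sel]), stats::sd(v[sel]))
    }
    pre <- moments(d$pre_analytical)
    post <- moments(d$analytical_post)
    tat <- moments(d$overall_tat)
    data.frame(n = n, percent = round(100 * n / nrow(d), 2),
               pre_mean = pre[1], pre_sd = pre[2],
               post_mean = post[1], post_sd = post[2],
               tat_mean = tat[1], tat_sd = tat[2])
  }
  out <- rbind(one(rep(TRUE, nrow(d))), one(within), one(!within))
  out <- cbind(stratum = c("overall", "within_limit", "after_limit"), out)
  rownames(out) <- NULL
  structure(out, tat_limit = limit,
            class = c("phase_summary", "data.frame"))
}

#' @export
print.phase_summary <- function(x, ...) {
  cat(sprintf("<phase_summary> TAT limit %g min\n", attr(x, "tat_limit")))
  fmt <- function(m, s) {
    ifelse(is.na(m), "-", sprintf("%.2f ± %.2f", m, s))
  }
  df <- data.frame(
    stratum = x$stratum,
    n = sprintf("%d (%.2f%%)", x$n, x$percent),
    pre_analytical = fmt(x$pre_mean, x$pre_sd),
    analytical_post = fmt(x$post_mean, x$post_sd),
    overall_tat = fmt(x$tat_mean, x$tat_sd)
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' Boxplot statistics with 1.5 x IQR outlier fences
#'
#' Quartiles use the linear-interpolation convention between order statistics
#' (`stats::quantile()` type 7). Whiskers extend to the most extreme data
#' points within 1.5 x IQR of the box edges; everything beyond is an outlier.
#'
#' @param values non-empty numeric vector (e.g. overall TATs in minutes).
#' @return an object of class `boxplot_stats`: a list with `q1`, `median`,
#'   `q3`, `iqr`, `whisker_low`, `whisker_high`, `outliers`, `n`.
#' @examples
#' boxplot_stats(1:100)$median # 50.5
#' @export
boxplot_stats <- function(values) {
  if (!is.numeric(values) || length(values) == 0L || anyNA(values)) {
    stop("`values` must be a non-empty numeric vector without NA")
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  structure(
    list(q1 = q[1], median = q[2], q3 = q[3], iqr = iqr,
         whisker_low = min(values[inside]),
         whisker_high = max(values[inside]),
         outliers = sort(values[!inside]),
         n = length(values)),
    class = "boxplot_stats"
  )
}

#' @export
print.boxplot_stats <- function(x, ...) {
  cat(sprintf(
    "<boxplot_stats> n = %d: q1 %.2f | median %.2f | q3 %.2f (IQR %.2f)\n",
    x$n, x$q1, x$median, x$q3, x$iqr))
  cat(sprintf("  whiskers [%.2f, %.2f]; %d outlier(s)\n",
              x$whisker_low, x$whisker_high, length(x$outliers)))
  invisible(x)
}

#' Per-duty task-switching report across periods
#'
#' Tabulates switches per 100 works for each duty and period, and -- when
#' more than one period is present -- the change versus the previous period:
#' the rate delta and the efficiency gain, defined as the reduction in
#' switched tasks relative to the current period's total workload
#' (`100 * (switched_prev - switched) / total_works`; a 20,000-task
#' reduction against a 50,000-task workload is a 40% gain).
#'
#' @param counts a `data.frame` with columns `period`, `duty`,
#'   `total_works`, `switched`. Periods are compared in their order of first
#'   appearance.
#' @return a `data.frame` with columns `period`, `duty`, `total_works`,
#'   `switched`, `per_100`, and (for multi-period input) `delta_per_100` and
#'   `efficiency_gain_pct` (`NA` in the first period).
#' @export
duty_switch_report <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("period", "duty", "total_works", "switched") %in%
                  names(counts)))
  if (nrow(counts) == 0L) stop("`counts` must have at least one row")
  bad <- counts$total_works <= 0 | counts$switched < 0 |
    counts$switched > counts$total_works
  if (any(bad)) {
    stop("invalid counts in row(s): ", paste(which(bad), collapse = ", "),
         " (need 0 <= switched <= total_works, total_works > 0)")
  }
  periods <- unique(as.character(counts$period))
  out <- counts[order(match(as.character(counts$period), periods),
                      as.character(counts$duty)), , drop = FALSE]
  out$per_100 <- 100 * out$switched / out$total_works
  if (length(periods) > 1L) {
    out$delta_per_100 <- NA_real_
    out$efficiency_gain_pct <- NA_real_
    for (i in seq_len(nrow(out))) {
      p_idx <- match(as.character(out$period[i]), periods)
      if (p_idx == 1L) next
      prev <- out[as.character(out$period) == periods[p_idx - 1L] &
                    as.character(out$duty) == as.character(out$duty[i]), ]
      if (nrow(prev) == 1L) {
        out$delta_per_100[i] <- out$per_100[i] - prev$per_100
        out$efficiency_gain_pct[i] <-
          100 * (prev$switched - out$switched[i]) / out$total_works[i]
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Batch-deadline alert schedule
#'
#' The monitoring-system view of a batched log: one alert per batch at the
#' moment its accumulated samples should be loaded into the analyzer. That
#' is the batch deadline `x_k + M`, or the anchor's own Receipt-2 time when
#' that is later (waiting never accelerates a loading, so at `M = 0` alerts
#' coincide with the original `y` times).
#'
#' @param batched a `batched_log`.
#' @return a `data.frame` ordered by alert time with columns `alert_time`,
#'   `batch_index`, `n_samples`, and list-column `sample_ids`.
#' @export
monitor_alerts <- function(batched) {
  stopifnot(inherits(batched, "batched_log"))
  anchors <- attr(batched, "anchors")
  if (nrow(anchors) == 0L) {
    return(data.frame(alert_time = numeric(0), batch_index = integer(0),
                      n_samples = integer(0)))
  }
  members <- split(batched$sample_id, batched$batch_index)
  out <- data.frame(
    alert_time = pmax(anchors$deadline, anchors$anchor_y),
    batch_index = anchors$batch_index,
    n_samples = as.integer(lengths(members)[as.character(anchors$batch_index)])
  )
  out$sample_ids <- I(unname(members[as.character(anchors$batch_index)]))
  out <- out[order(out$alert_time, out$batch_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}
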