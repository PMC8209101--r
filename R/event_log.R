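#' Construct a sample event log
#'
#' An event log holds one record per sample with the three LIS timestamps
#' recorded inside the laboratory: `x`, arrival at the laboratory
#' ("Receipt 1"); `y`, loading of the pre-treated sample into the analyzer
#' ("Receipt 2"); and `z`, report of the result to the hospital information
#' system. All timestamps are real-valued minutes on a single monotone clock.
#' Records are stored sorted ascending by `x` (ties broken by `y`, then
#' `sample_id`), and every record must satisfy `x <= y <= z`.
#'
#' @param sample_id character vector of unique sample labels.
#' @param x,y,z numeric vectors of timestamps in minutes (Receipt 1,
#'   Receipt 2, report). Must be finite, non-negative, and `x <= y <= z`
#'   record-wise.
#' @param tat_limit TAT guideline in minutes; a sample is compliant when
#'   `z - x <= tat_limit` (the comparison is closed: "one hour or less").
#'   Default 60.
#'
#' @return An object of class `event_log`: a `data.frame` with columns
#'   `sample_id`, `x`, `y`, `z` and attribute `tat_limit`.
#' @examples
#' log <- event_log(c("A", "B", "C"),
#'                  x = c(0, 8, 40), y = c(10, 20, 52), z = c(25, 36, 66))
#' durations(log)
#' @export
event_log <- function(sample_id, x, y, z, tat_limit = 60) {
  df <- data.frame(
    sample_id = as.character(sample_id),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    stringsAsFactors = FALSE
  )
  new_event_log(df, tat_limit = tat_limit)
}

# Validates, sorts and classes a raw data.frame of records.
new_event_log <- function(df, tat_limit = 60) {
  stopifnot(is.data.frame(df),
            all(c("sample_id", "x", "y", "z") %in% names(df)))
  if (!is.numeric(tat_limit) || length(tat_limit) != 1L || tat_limit <= 0) {
    stop("`tat_limit` must be a single positive number of minutes")
  }
  problems <- validate_records(df)
  if (length(problems)) {
    stop("invalid event-log records:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("sample_ids must be unique; duplicated: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  ord <- order(df$x, df$y, df$sample_id)
  df <- df[ord, c("sample_id", "x", "y", "z"), drop = FALSE]
  rownames(df) <- NULL
  structure(df, tat_limit = tat_limit, class = c("event_log", "data.frame"))
}

# One message per offending row, with its (input) row number.
validate_records <- function(df) {
  n <- nrow(df)
  if (n == 0L) return(character(0))
  probs <- character(0)
  bad_finite <- !is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z)
  bad_neg <- !bad_finite & (df$x < 0 | df$y < 0 | df$z < 0)
  bad_order <- !bad_finite & (df$x > df$y | df$y > df$z)
  for (i in which(bad_finite)) {
    probs <- c(probs, sprintf("row %d: non-finite timestamp", i))
  }
  for (i in which(bad_neg)) {
    probs <- c(probs, sprintf("row %d: negative timestamp", i))
  }
  for (i in which(bad_order)) {
    probs <- c(probs, sprintf(
      "row %d (%s): requires x <= y <= z, got x=%g y=%g z=%g",
      i, df$sample_id[i], df$x[i], df$y[i], df$z[i]))
  }
  probs
}

#' TAT guideline of an event log
#' @param log an `event_log`.
#' @return the TAT limit in minutes.
#' @export
tat_limit <- function(log) {
  lim <- attr(log, "tat_limit")
  if (is.null(lim)) 60 else lim
}

#' Per-sample phase durations
#'
#' Decomposes each record into the pre-analytical phase (`y - x`:
#' centrifugation, de-capping, racking), the analytical plus post-analytical
#' phase (`z - y`), and the overall turnaround time (`z - x`). The two phases
#' sum to the overall TAT by construction.
#'
#' @param log an `event_log`.
#' @return a `data.frame` with columns `sample_id`, `pre_analytical`,
#'   `analytical_post`, `overall_tat`, in record order.
#' @export
durations <- function(log) {
  stopifnot(inherits(log, "event_log"))
  data.frame(
    sample_id = log$sample_id,
    pre_analytical = log$y - log$x,
    analytical_post = log$z - log$y,
    overall_tat = log$z - log$x,
    stringsAsFactors = FALSE
  )
}

#' Read a sample event log from delimited text
#'
#' Two timestamp dialects are supported: plain numeric minutes, or ISO-8601
#' date-times, which are converted to minutes elapsed since the earliest
#' Receipt 1 in the file (that wall-clock origin is retained in attribute
#' `wall_origin` so duty shifts can still be labeled).
#'
#' Records with a missing Receipt 1 are excluded from the log rather than
#' imputed -- `x` anchors both the TAT and the batching rule -- and their
#' count is retained in attribute `n_excluded_missing_receipt1`. Any other
#' malformed record (unparseable timestamp, `x > y`, or `y > z`) is a
#' validation error; all offending rows are collected and reported together
#' with their row numbers.
#'
#' @param path path to a delimited text file with a header row.
#' @param columns named character vector mapping the internal names
#'   `sample_id`, `x`, `y`, `z` to column names in the file.
#' @param timestamps `"minutes"` (numeric) or `"datetime"` (ISO-8601).
#' @param tat_limit TAT guideline in minutes (default 60).
#' @param sep field separator (default `","`).
#' @return an `event_log`.
#' @seealso [write_event_log()]
#' @export
read_event_log <- function(path,
                           columns = c(sample_id = "sample_id",
                                       x = "x", y = "y", z = "z"),
                           timestamps = c("minutes", "datetime"),
                           tat_limit = 60, sep = ",") {
  timestamps <- match.arg(timestamps)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  required <- c("sample_id", "x", "y", "z")
  if (!all(required %in% names(columns))) {
    stop("`columns` must name all of: ", paste(required, collapse = ", "))
  }
  missing_cols <- setdiff(unname(columns[required]), names(raw))
  if (length(missing_cols)) {
    stop("column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) stop("empty event log: ", path, " has no data rows")

  df <- data.frame(
    sample_id = raw[[columns[["sample_id"]]]],
    stringsAsFactors = FALSE
  )
  wall_origin <- NULL
  if (timestamps == "minutes") {
    for (f in c("x", "y", "z")) {
      df[[f]] <- suppressWarnings(as.numeric(raw[[columns[[f]]]]))
    }
  } else {
    parsed <- lapply(c("x", "y", "z"), function(f) {
      v <- raw[[columns[[f]]]]
      out <- as.POSIXct(v, tz = "UTC",
                        tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                       "%Y-%m-%d %H:%M:%OS",
                                       "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
      out[is.na(v) | v == ""] <- NA
      out
    })
    names(parsed) <- c("x", "y", "z")
    wall_origin <- suppressWarnings(min(parsed$x, na.rm = TRUE))
    for (f in c("x", "y", "z")) {
      df[[f]] <- as.numeric(difftime(parsed[[f]], wall_origin, units = "mins"))
    }
  }

  # Missing Receipt 1 is tolerated upstream of the lab's analytics; such
  # records are excluded (not imputed) and tallied.
  x_raw <- raw[[columns[["x"]]]]
  missing_x <- is.na(df$x) & (is.na(x_raw) | trimws(x_raw) == "")
  n_excluded <- sum(missing_x)
  df <- df[!missing_x, , drop = FALSE]
  if (nrow(df) == 0L) stop("empty event log: all rows lacked Receipt 1")

  log <- new_event_log(df, tat_limit = tat_limit)
  attr(log, "n_excluded_missing_receipt1") <- n_excluded
  if (!is.null(wall_origin)) attr(log, "wall_origin") <- wall_origin
  log
}

#' Write an event log as CSV
#'
#' Timestamps are written in minutes with full precision, so that
#' `read_event_log()` recovers the log to within 1e-6 minutes.
#'
#' @param log an `event_log`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "event_log"))
  df <- as.data.frame(log)[, c("sample_id", "x", "y", "z"), drop = FALSE]
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> %d samples, TAT limit %g min\n",
              nrow(x), tat_limit(x)))
  excl <- attr(x, "n_excluded_missing_receipt1")
  if (!is.null(excl) && excl > 0) {
    cat(sprintf("  (%d record(s) excluded: missing Receipt 1)\n", excl))
  }
  if (nrow(x) > 0) {
    print(utils::head(as.data.frame(x), 10))
    if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  }
  invisible(x)
}
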