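#' Count task switches in a labeled task sequence
#'
#' A task switch is any adjacent change of task *type* in the order the
#' worker performs them; sample indices are irrelevant. For a technician
#' alternating between pre-treatment (`P`) and analytical (`A`) work, the
#' sequence P A P P A A P A contains 5 switches, while the fully blocked
#' P P P P A A A A contains 1. Equivalently, the count is the number of
#' maximal runs of equal labels minus one, so it is invariant under any
#' relabeling of the task alphabet.
#'
#' @param labels non-empty vector of task-type labels (character, factor, or
#'   anything coercible to character); `NA` labels are not allowed.
#' @return non-negative integer number of switches.
#' @examples
#' count_switches(c("P", "A", "P", "P", "A", "A", "P", "A")) # 5
#' count_switches(rep(c("P", "A"), each = 4))                # 1
#' @export
count_switches <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("task sequence must be non-empty")
  if (anyNA(labels)) stop("task sequence must not contain NA labels")
  if (length(labels) == 1L) return(0L)
  sum(labels[-1L] != labels[-length(labels)])
}

#' Task switches per 100 works
#'
#' The paper-style normalized switching burden: `100 * switched /
#' total_works`. Also used for the efficiency-gain arithmetic (a reduction of
#' 20,000 switched tasks against a total workload of 50,000 is a 40% gain).
#'
#' @param total_works positive total number of works.
#' @param switched number of switched works, between 0 and `total_works`.
#' @return rate per 100 works.
#' @export
switches_per_100 <- function(total_works, switched) {
  if (!is.numeric(total_works) || length(total_works) != 1L ||
      is.na(total_works) || total_works <= 0) {
    stop("`total_works` must be a single positive count")
  }
  if (!is.numeric(switched) || length(switched) != 1L || is.na(switched) ||
      switched < 0 || switched > total_works) {
    stop("`switched` must lie between 0 and `total_works`")
  }
  100 * switched / total_works
}

#' Label a time of day with its duty or staffing window
#'
#' Two partitions of the 24-hour day are supported, both with half-open
#' `[start, end)` windows so that every instant receives exactly one label:
#'
#' * `"duty"` -- the technician duty rota: day 07:00-15:00, evening
#'   15:00-23:00, night 23:00-07:00.
#' * `"staffing"` -- the staffing windows: 07:00-17:00 with 4 workers,
#'   17:00-22:00 with 3, 22:00-07:00 with 2.
#'
#' @param time a `POSIXct` vector, a character vector of `"HH:MM"` /
#'   `"HH:MM:SS"` times, or a numeric vector of hours of day (taken modulo
#'   24).
#' @param scheme `"duty"` or `"staffing"`.
#' @return character vector of window labels.
#' @examples
#' label_duty("14:59")                      # "day"
#' label_duty("23:00")                      # "night" (half-open boundary)
#' label_duty("06:30", scheme = "staffing") # "night (2 workers)"
#' @export
label_duty <- function(time, scheme = c("duty", "staffing")) {
  scheme <- match.arg(scheme)
  h <- hour_of_day(time)
  if (scheme == "duty") {
    ifelse(h >= 7 & h < 15, "day",
           ifelse(h >= 15 & h < 23, "evening", "night"))
  } else {
    ifelse(h >= 7 & h < 17, "day (4 workers)",
           ifelse(h >= 17 & h < 22, "evening (3 workers)",
                  "night (2 workers)"))
  }
}

# Coerces POSIXct / "HH:MM[:SS]" / numeric hours to fractional hours in [0, 24).
hour_of_day <- function(time) {
  if (inherits(time, "POSIXt")) {
    lt <- as.POSIXlt(time)
    h <- lt$hour + lt$min / 60 + lt$sec / 3600
  } else if (is.character(time)) {
    parts <- strsplit(time, ":", fixed = TRUE)
    h <- vapply(parts, function(p) {
      p <- suppressWarnings(as.numeric(p))
      if (anyNA(p) || length(p) < 2L || length(p) > 3L) {
        stop("times must be given as 'HH:MM' or 'HH:MM:SS'")
      }
      p[1L] + p[2L] / 60 + if (length(p) == 3L) p[3L] / 3600 else 0
    }, numeric(1))
  } else if (is.numeric(time)) {
    h <- time
  } else {
    stop("`time` must be POSIXct, 'HH:MM' character, or numeric hours")
  }
  h %% 24
}
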