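#' Default hourly arrival-intensity profile
#'
#' A qualitative emulation of an emergency-room chemistry workload: arrivals
#' per hour peak during the daytime at roughly 2.4 times the small-hours
#' trough, integrating to about 194 samples per day (the order of magnitude
#' of a mid-size hospital's ER chemistry volume, ~70,000 samples/year). The
#' shape is a modeling choice, not a measured profile.
#'
#' @return numeric vector of 24 non-negative rates (samples/hour), one per
#'   hour of day starting at midnight.
#' @export
default_intensity <- function() {
  c(5, 4, 4, 4, 4, 4, 5, 7, 9, 11, 12, 12, 12, 12, 12, 11, 11, 10,
    10, 9, 8, 7, 6, 5)
}

#' Configuration for the synthetic event-log generator
#'
#' Defines the statistical structure of generated logs: a non-homogeneous
#' Poisson arrival process with piecewise-constant hourly intensity, and
#' independent per-sample phase durations drawn from a non-negative family
#' moment-matched to the configured mean and SD. The default duration
#' moments are 20.26 +/- 8.66 min for the pre-analytical phase and
#' 16.90 +/- 8.66 min for the analytical + post-analytical phase, typical of
#' ER clinical-chemistry operation under a 60-minute TAT guideline.
#'
#' @param horizon_days number of simulated days, `>= 1`.
#' @param hourly_intensity 24 non-negative arrival rates (samples/hour), at
#'   least one positive; see [default_intensity()].
#' @param pre_mean,pre_sd pre-analytical duration moments (minutes).
#' @param post_mean,post_sd analytical + post-analytical duration moments
#'   (minutes).
#' @param duration_family `"gamma"` (default) or `"lognormal"`; either is
#'   moment-matched. A zero SD gives constant durations.
#' @param tat_limit TAT guideline in minutes, default 60.
#' @param seed optional integer seed; may also be supplied to
#'   [generate_event_log()] directly.
#' @return an object of class `generator_config` (a list).
#' @export
generator_config <- function(horizon_days = 30,
                             hourly_intensity = default_intensity(),
                             pre_mean = 20.26, pre_sd = 8.66,
                             post_mean = 16.90, post_sd = 8.66,
                             duration_family = c("gamma", "lognormal"),
                             tat_limit = 60,
                             seed = NULL) {
  duration_family <- match.arg(duration_family)
  if (!is.numeric(horizon_days) || length(horizon_days) != 1L ||
      is.na(horizon_days) || horizon_days < 1) {
    stop("`horizon_days` must be a single number >= 1")
  }
  if (!is.numeric(hourly_intensity) || length(hourly_intensity) != 24L) {
    stop("`hourly_intensity` must be a numeric vector of 24 hourly rates")
  }
  if (any(!is.finite(hourly_intensity)) || any(hourly_intensity < 0) ||
      all(hourly_intensity == 0)) {
    stop("`hourly_intensity` rates must be >= 0 with at least one positive")
  }
  for (nm in c("pre_mean", "post_mean")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stop("`", nm, "` must be a single positive number of minutes")
    }
  }
  for (nm in c("pre_sd", "post_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("`", nm, "` must be a single non-negative number of minutes")
    }
  }
  if (!is.numeric(tat_limit) || length(tat_limit) != 1L || tat_limit <= 0) {
    stop("`tat_limit` must be a single positive number of minutes")
  }
  structure(
    list(horizon_days = as.integer(horizon_days),
         hourly_intensity = as.numeric(hourly_intensity),
         pre_mean = pre_mean, pre_sd = pre_sd,
         post_mean = post_mean, post_sd = post_sd,
         duration_family = duration_family,
         tat_limit = tat_limit,
         seed = seed),
    class = "generator_config"
  )
}

# Moment-matched non-negative durations. Gamma: shape = (m/s)^2, rate = m/s^2.
# Lognormal: sdlog^2 = log(1 + cv^2), meanlog = log(m) - sdlog^2 / 2.
draw_durations <- function(n, mean, sd, family) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  if (family == "gamma") {
    shape <- (mean / sd)^2
    stats::rgamma(n, shape = shape, rate = shape / mean)
  } else {
    sdlog2 <- log(1 + (sd / mean)^2)
    stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
  }
}

#' Generate a synthetic sample event log
#'
#' Arrivals are drawn from a non-homogeneous Poisson process with the
#' configured piecewise-constant hourly intensity (per-hour Poisson counts,
#' uniform placement within the hour); the pre-analytical and analytical +
#' post-analytical durations are drawn independently from the configured
#' moment-matched family, giving `y = x + pre` and `z = y + post`. Time zero
#' is midnight of the first simulated day, so wall-clock hours for duty
#' labeling are `(x / 60) %% 24`. The output is fully reproducible from the
#' seed.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; defaults to `config$seed`. Required from one of
#'   the two places.
#' @return an [event_log()].
#' @examples
#' log <- generate_event_log(generator_config(horizon_days = 2, seed = 42))
#' nrow(log)
#' @export
generate_event_log <- function(config = generator_config(),
                               seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(seed)) stop("a `seed` is required for reproducible generation")
  withr::with_seed(as.integer(seed), {
    rates <- rep(config$hourly_intensity, config$horizon_days)
    counts <- stats::rpois(length(rates), rates)
    hour_start <- (seq_along(rates) - 1L) * 60  # minutes from day-0 midnight
    x <- rep(hour_start, counts) + stats::runif(sum(counts)) * 60
    x <- sort(x)
    n <- length(x)
    pre <- draw_durations(n, config$pre_mean, config$pre_sd,
                          config$duration_family)
    post <- draw_durations(n, config$post_mean, config$post_sd,
                           config$duration_family)
    y <- x + pre
    z <- y + post
    ids <- sprintf("S%06d", seq_len(n))
    new_event_log(
      data.frame(sample_id = ids, x = x, y = y, z = z,
                 stringsAsFactors = FALSE),
      tat_limit = config$tat_limit
    )
  })
}

#' Generate a log with a known optimal waiting interval
#'
#' Constructs an event log whose equal-weight scalarized objective on the
#' default grid is minimized at a chosen interval `M_star`, for validating
#' the optimizer end to end. The construction places well-separated arrival
#' clusters whose Receipt-2 times span exactly `M_star` minutes (so the task
#' count reaches its minimum precisely when `M >= M_star`) and gives every
#' sample an analytical + post-analytical duration just under
#' `tat_limit - M_star` (so batch deadlines past `M_star` push anchors over
#' the TAT guideline, and compliance starts dropping precisely when
#' `M > M_star`). Both normalized objectives therefore vanish only at
#' `M_star`, which is the unique equal-weight argmin.
#'
#' @param M_star target optimal interval, with `0 < M_star <= tat_limit - 1`.
#' @param seed integer seed (jitters cluster placement and report slack).
#' @param tat_limit TAT guideline in minutes, default 60.
#' @param n_clusters number of arrival clusters, default 20.
#' @param cluster_size samples per cluster, default 12.
#' @return an [event_log()].
#' @export
generate_known_optimum_log <- function(M_star, seed, tat_limit = 60,
                                       n_clusters = 20, cluster_size = 12) {
  if (!is.numeric(M_star) || length(M_star) != 1L || is.na(M_star) ||
      M_star <= 0 || M_star > tat_limit - 1) {
    stop("`M_star` must satisfy 0 < M_star <= tat_limit - 1")
  }
  stopifnot(n_clusters >= 1, cluster_size >= 2)
  withr::with_seed(as.integer(seed), {
    # clusters 3 h apart: no batch at M <= tat_limit can reach across clusters
    starts <- (seq_len(n_clusters) - 1L) * 180 + stats::runif(n_clusters, 0, 30)
    offsets <- seq(0, M_star, length.out = cluster_size)
    x <- as.vector(outer(offsets, starts, `+`))
    y <- x  # pre-treated immediately; the waiting interval is the only delay
    slack <- tat_limit - M_star - 0.5 +
      stats::runif(length(x), 0.05, 0.45)
    z <- y + slack
    ids <- sprintf("K%04d", seq_along(x))
    new_event_log(
      data.frame(sample_id = ids, x = x, y = y, z = z,
                 stringsAsFactors = FALSE),
      tat_limit = tat_limit
    )
  })
}
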