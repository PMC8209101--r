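#' Min-max normalize a trade-off curve
#'
#' Puts the two objectives on a common dimensionless scale over the grid:
#' `f1`, the normalized TAT *dissatisfaction* `1 - r_M`, and `f2`, the
#' normalized task count `l_M`. Each is rescaled so its minimum over the grid
#' maps to 0 and its maximum to 1; an objective that is constant over the
#' grid maps to all zeros. Normalization is what makes weights on the two
#' objectives commensurable (the raw task count is in the hundreds or
#' thousands while the dissatisfaction rate lives in `[0, 1]`).
#'
#' @param curve a [tradeoff_curve()].
#' @return an object of class `normalized_curve`: the curve with columns
#'   `f1` and `f2` appended.
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "tradeoff_curve"))
  if (nrow(curve) == 0L) stop("cannot normalize an empty trade-off curve")
  rescale01 <- function(v) {
    lo <- min(v); hi <- max(v)
    if (hi == lo) rep(0, length(v)) else (v - lo) / (hi - lo)
  }
  out <- as.data.frame(curve)
  out$f1 <- rescale01(1 - out$r)
  out$f2 <- rescale01(out$l)
  structure(out,
            tat_limit = attr(curve, "tat_limit"),
            n_samples = attr(curve, "n_samples"),
            class = c("normalized_curve", "tradeoff_curve", "data.frame"))
}

#' Pareto-optimal points of a two-objective minimization
#'
#' A point is kept when no other point is at least as small in both
#' objectives and strictly smaller in one. Duplicated objective pairs do not
#' dominate each other; both are kept.
#'
#' @param f1,f2 numeric vectors of equal length (both minimized).
#' @return logical vector marking the non-dominated points.
#' @export
pareto_front <- function(f1, f2) {
  stopifnot(length(f1) == length(f2))
  n <- length(f1)
  keep <- logical(n)
  if (n == 0L) return(keep)
  # skyline sweep: ascending f1 (ties: ascending f2); a point survives iff it
  # strictly improves the best f2 seen so far, or duplicates the pair that set it
  ord <- order(f1, f2)
  best_f2 <- Inf
  best_f1 <- Inf
  for (i in ord) {
    if (f2[i] < best_f2) {
      keep[i] <- TRUE
      best_f2 <- f2[i]
      best_f1 <- f1[i]
    } else if (f2[i] == best_f2 && f1[i] == best_f1) {
      keep[i] <- TRUE
    }
  }
  keep
}

#' Scalarize a normalized trade-off curve and select M0
#'
#' Collapses the two normalized objectives into one value per grid interval,
#' `g(M) = w_tat * f1(M) + w_switch * f2(M)`, with non-negative weights
#' summing to 1, and selects the optimal interval `M0` as the grid argmin of
#' `g`. Ties are broken toward the smallest `M` (favoring TAT compliance when
#' indifferent); among exactly tied minimizers the smallest Pareto-optimal
#' one is preferred, so `M0` always lies on the Pareto front.
#'
#' @param norm a [normalize_curve()] result.
#' @param w_tat weight on normalized TAT dissatisfaction, `>= 0`.
#' @param w_switch weight on normalized task count, `>= 0`;
#'   `w_tat + w_switch` must equal 1.
#' @return an object of class `optimization_result`: a list with elements
#'   `weights`, `curve` (a `data.frame` of `M`, `f1`, `f2`, `g`), `M0`, and
#'   `pareto_set` (the non-dominated `M` values).
#' @examples
#' log <- generate_event_log(generator_config(horizon_days = 2, seed = 1))
#' res <- scalarize(normalize_curve(tradeoff_curve(log)), 0.5, 0.5)
#' res$M0
#' @export
scalarize <- function(norm, w_tat, w_switch) {
  stopifnot(inherits(norm, "normalized_curve"))
  if (!is.numeric(w_tat) || !is.numeric(w_switch) ||
      length(w_tat) != 1L || length(w_switch) != 1L ||
      is.na(w_tat) || is.na(w_switch) || w_tat < 0 || w_switch < 0 ||
      abs(w_tat + w_switch - 1) > 1e-8) {
    stop("weights must be non-negative and sum to 1")
  }
  g <- w_tat * norm$f1 + w_switch * norm$f2
  on_front <- pareto_front(norm$f1, norm$f2)
  minimizers <- which(g <= min(g) + 1e-12)
  pick <- minimizers[on_front[minimizers]]
  i0 <- if (length(pick)) pick[1L] else minimizers[1L]
  structure(
    list(
      weights = c(w_tat = w_tat, w_switch = w_switch),
      curve = data.frame(M = norm$M, f1 = norm$f1, f2 = norm$f2, g = g),
      M0 = norm$M[i0],
      pareto_set = norm$M[on_front]
    ),
    class = "optimization_result"
  )
}

#' Recommend a batch-waiting interval across weightings
#'
#' Runs the full pipeline -- trade-off curve, normalization, scalarization --
#' once per weight pair and reports each selected `M0` together with the
#' interval they span. The default weight pairs put 0.6/0.5/0.4 on TAT
#' dissatisfaction (and the complement on task switching): more weight on
#' task switching yields a longer recommended waiting interval.
#'
#' @param log an [event_log()].
#' @param M_grid grid of candidate intervals (minutes), default `0:60`.
#' @param weight_pairs list of `c(w_tat, w_switch)` pairs.
#' @return an object of class `interval_recommendation`: a `data.frame` with
#'   columns `w_tat`, `w_switch`, `M0`, plus attributes `interval`
#'   (`range(M0)`) and `curve` (the normalized trade-off curve).
#' @export
recommend_interval <- function(log, M_grid = 0:60,
                               weight_pairs = list(c(0.6, 0.4),
                                                   c(0.5, 0.5),
                                                   c(0.4, 0.6))) {
  stopifnot(inherits(log, "event_log"), length(weight_pairs) >= 1L)
  norm <- normalize_curve(tradeoff_curve(log, M_grid))
  rows <- lapply(weight_pairs, function(w) {
    if (length(w) != 2L) stop("each weight pair must have two elements")
    res <- scalarize(norm, w[1L], w[2L])
    data.frame(w_tat = w[1L], w_switch = w[2L], M0 = res$M0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            interval = range(out$M0),
            curve = norm,
            class = c("interval_recommendation", "data.frame"))
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf(
    "<optimization_result> weights (TAT %.2f, switch %.2f): M0 = %g min\n",
    x$weights[["w_tat"]], x$weights[["w_switch"]], x$M0))
  cat(sprintf("  Pareto-optimal intervals: %s\n",
              paste(x$pareto_set, collapse = ", ")))
  invisible(x)
}

#' @export
print.interval_recommendation <- function(x, ...) {
  cat("<interval_recommendation>\n")
  df <- as.data.frame(x)
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  w_tat = %.2f, w_switch = %.2f  ->  M0 = %g min\n",
                df$w_tat[i], df$w_switch[i], df$M0[i]))
  }
  iv <- attr(x, "interval")
  cat(sprintf("  recommended interval spans [%g, %g] min\n", iv[1], iv[2]))
  invisible(x)
}
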