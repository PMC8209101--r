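#' Batch Receipt-2 loadings under a waiting interval
#'
#' The core transformation. Given a waiting interval `M` (minutes), samples
#' are merged greedily into analyzer-loading batches: the earliest-arriving
#' unassigned sample `k` anchors a batch whose deadline is `x_k + M`, and
#' every unassigned later sample whose *original* Receipt-2 time satisfies
#' `y_i <= x_k + M` joins it. All batch members whose original `y` falls on
#' or before the deadline have their Receipt 2 moved to the deadline
#' (`y' = x_k + M`); an anchor whose own `y_k` already exceeds the deadline
#' keeps `y' = y_k` (waiting can only delay a loading, never accelerate it).
#' Report times are carried forward with the analytical + post-analytical
#' duration unchanged: `z' = y' + (z - y)`.
#'
#' Anchors are taken greedily in arrival order, so batch indices are
#' contiguous from 1 in anchor order and every sample belongs to exactly one
#' batch. Membership tests the original `y_i` (not `x_i`) against the
#' deadline, and the boundary `y_i = x_k + M` is inside the batch.
#'
#' @param log an [event_log()].
#' @param M waiting interval in minutes, `>= 0`. `M = 0` leaves any log in
#'   which each Receipt 2 strictly follows all earlier arrivals unchanged.
#' @return an object of class `batched_log`: a `data.frame` with columns
#'   `sample_id`, `x`, `y`, `z`, `y_prime`, `z_prime`, `batch_index`,
#'   `batch_deadline`, plus attributes `M`, `tat_limit`, and `anchors` (a
#'   `data.frame` with one row per batch: `batch_index`, `anchor_id`,
#'   `anchor_x`, `deadline`).
#' @examples
#' log <- event_log(c("A", "B", "C"),
#'                  x = c(0, 8, 40), y = c(10, 20, 52), z = c(25, 36, 66))
#' batch_receipts(log, M = 25) # two batches: {A,B} at y' = 25, {C} at y' = 65
#' @export
batch_receipts <- function(log, M) {
  stopifnot(inherits(log, "event_log"))
  if (!is.numeric(M) || length(M) != 1L || is.na(M) || M < 0) {
    stop("`M` must be a single non-negative number of minutes")
  }
  n <- nrow(log)
  x <- log$x; y <- log$y; z <- log$z
  y2 <- y
  batch <- integer(n)
  deadline_of <- numeric(n)

  anchor_idx <- integer(0)
  anchor_deadline <- numeric(0)

  un <- seq_len(n)  # unassigned, in x-order
  b <- 0L
  while (length(un)) {
    b <- b + 1L
    k <- un[1L]
    deadline <- x[k] + M
    joins <- y[un] <= deadline       # members by the printed rule
    y2[un[joins]] <- deadline        # includes the anchor iff y_k <= deadline
    joins[1L] <- TRUE                # the anchor always belongs to its batch
    ids <- un[joins]
    batch[ids] <- b
    deadline_of[ids] <- deadline
    anchor_idx[b] <- k
    anchor_deadline[b] <- deadline
    un <- un[!joins]
  }

  out <- data.frame(
    sample_id = log$sample_id, x = x, y = y, z = z,
    y_prime = y2, z_prime = y2 + (z - y),
    batch_index = batch, batch_deadline = deadline_of,
    stringsAsFactors = FALSE
  )
  anchors <- data.frame(
    batch_index = seq_len(b)[seq_along(anchor_idx)],
    anchor_id = log$sample_id[anchor_idx],
    anchor_x = x[anchor_idx],
    anchor_y = y[anchor_idx],
    deadline = anchor_deadline,
    stringsAsFactors = FALSE
  )
  structure(out, M = M, tat_limit = tat_limit(log), anchors = anchors,
            class = c("batched_log", "data.frame"))
}

#' Number of analyzer-loading tasks in a batched log
#'
#' Each batch is loaded into the analyzer as a single task, so the task count
#' for interval `M` -- the quantity traded off against TAT compliance -- is
#' the number of batches.
#'
#' @param batched a `batched_log`.
#' @return integer task count (0 for an empty log).
#' @export
count_tasks <- function(batched) {
  stopifnot(inherits(batched, "batched_log"))
  nrow(attr(batched, "anchors"))
}

#' TAT satisfaction rate of a batched log
#'
#' The fraction of samples whose modified turnaround time `z' - x` is within
#' the guideline (closed comparison: exactly at the limit counts as
#' compliant). An empty log is defined to be fully compliant.
#'
#' @param batched a `batched_log`.
#' @param limit TAT guideline in minutes; defaults to the log's own limit.
#' @return a rate in `[0, 1]`.
#' @export
tat_satisfaction <- function(batched, limit = attr(batched, "tat_limit")) {
  stopifnot(inherits(batched, "batched_log"))
  if (is.null(limit)) limit <- 60
  if (!is.numeric(limit) || length(limit) != 1L || is.na(limit) || limit <= 0) {
    stop("`limit` must be a single positive number of minutes")
  }
  if (nrow(batched) == 0L) return(1.0)
  mean(batched$z_prime - batched$x <= limit)
}

#' Trade-off curve over a grid of waiting intervals
#'
#' Evaluates, for each `M` in the grid, the task count `l_M` and the TAT
#' satisfaction rate `r_M` of the batched log. Longer waiting merges more
#' samples per loading (fewer tasks) at the cost of later reports (lower
#' compliance), so the curve traces the trade-off the optimizer resolves.
#'
#' @param log an [event_log()].
#' @param M_grid strictly increasing vector of non-negative intervals in
#'   minutes; default integer minutes 0 to 60 (the TAT guideline bounds the
#'   useful range).
#' @return an object of class `tradeoff_curve`: a `data.frame` with columns
#'   `M`, `l`, `r` and attributes `tat_limit`, `n_samples`.
#' @seealso [normalize_curve()], [scalarize()], [recommend_interval()]
#' @export
tradeoff_curve <- function(log, M_grid = 0:60) {
  stopifnot(inherits(log, "event_log"))
  if (length(M_grid) == 0L) stop("`M_grid` must be non-empty")
  if (any(!is.finite(M_grid)) || any(M_grid < 0)) {
    stop("`M_grid` values must be finite and >= 0")
  }
  if (length(M_grid) > 1L && any(diff(M_grid) <= 0)) {
    stop("`M_grid` must be strictly increasing")
  }
  lim <- tat_limit(log)
  pts <- lapply(M_grid, function(M) {
    b <- batch_receipts(log, M)
    c(l = count_tasks(b), r = tat_satisfaction(b, lim))
  })
  out <- data.frame(
    M = as.numeric(M_grid),
    l = vapply(pts, `[[`, numeric(1), "l"),
    r = vapply(pts, `[[`, numeric(1), "r")
  )
  structure(out, tat_limit = lim, n_samples = nrow(log),
            class = c("tradeoff_curve", "data.frame"))
}

#' @export
print.batched_log <- function(x, ...) {
  cat(sprintf("<batched_log> M = %g min: %d samples in %d batch(es)\n",
              attr(x, "M"), nrow(x), count_tasks(x)))
  if (nrow(x) > 0) {
    print(utils::head(as.data.frame(x), 10))
    if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  }
  invisible(x)
}
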