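# Shared fixtures and independent oracles, built in code.

make_log <- function(x, y, z, tat_limit = 60) {
  event_log(sprintf("s%03d", seq_along(x)), x = x, y = y, z = z,
            tat_limit = tat_limit)
}

# Random integer-timestamp log (caller controls the RNG seed).
random_int_log <- function(n, x_max = 200, pre_max = 60, post_max = 60) {
  x <- sort(sample(0:x_max, n, replace = TRUE))
  y <- x + sample(0:pre_max, n, replace = TRUE)
  z <- y + sample(0:post_max, n, replace = TRUE)
  make_log(x, y, z)
}

# Independent minute-stepping batching simulator: advance an integer clock;
# whenever the earliest unassigned sample's deadline x_k + M has arrived,
# release as one task every unassigned sample with original y <= deadline.
# Valid for integer timestamps and integer M.
oracle_batch <- function(log, M) {
  n <- nrow(log)
  x <- log$x
  y <- log$y
  y2 <- y
  batch <- integer(n)
  un <- rep(TRUE, n)
  b <- 0L
  if (n > 0) {
    for (t in 0:(max(x) + M)) {
      repeat {
        if (!any(un)) break
        idx <- which(un)
        k <- idx[which.min(x[idx])]
        deadline <- x[k] + M
        if (deadline > t) break
        b <- b + 1L
        mem <- which(un & y <= deadline)
        y2[mem] <- deadline
        ids <- union(k, mem)
        batch[ids] <- b
        un[ids] <- FALSE
      }
    }
  }
  list(y_prime = y2, batch_index = batch, n_batches = b)
}

# Brute-force O(n^2) non-domination check (both objectives minimized).
brute_pareto <- function(f1, f2) {
  vapply(seq_along(f1), function(i) {
    !any(f1 <= f1[i] & f2 <= f2[i] & (f1 < f1[i] | f2 < f2[i]))
  }, logical(1))
}
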