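ex_log <- function() {
  event_log(c("A", "B", "C"),
            x = c(0, 8, 40), y = c(10, 20, 52), z = c(25, 36, 66))
}

test_that("greedy batching merges samples reachable within the deadline", {
  b <- batch_receipts(ex_log(), M = 25)
  # anchor A at x = 0, deadline 25 captures B (y = 20); C anchors its own batch
  expect_equal(count_tasks(b), 2L)
  expect_equal(b$batch_index, c(1L, 1L, 2L))
  expect_equal(b$y_prime, c(25, 25, 65))
  expect_equal(b$z_prime, c(40, 41, 79))
  anchors <- attr(b, "anchors")
  expect_equal(anchors$anchor_id, c("A", "C"))
  expect_equal(anchors$deadline, c(25, 65))
})

test_that("M = 0 is the identity when each Receipt 2 follows earlier arrivals", {
  log <- ex_log()
  b <- batch_receipts(log, M = 0)
  expect_equal(count_tasks(b), 3L)
  expect_equal(b$y_prime, log$y)
  expect_equal(b$z_prime, log$z)
  expect_equal(b$batch_index, 1:3)
  expect_equal(tat_satisfaction(b, 60), 1.0)
})

test_that("the membership boundary y = deadline is inside the batch", {
  # B's Receipt 2 lands exactly on A's deadline
  log <- make_log(x = c(0, 5), y = c(2, 20), z = c(30, 40))
  b <- batch_receipts(log, M = 20)
  expect_equal(b$batch_index, c(1L, 1L))
  expect_equal(b$y_prime, c(20, 20))
})

test_that("an anchor past its own deadline keeps its Receipt 2", {
  # anchor pre-treatment (y - x = 100) exceeds any deadline x + M
  log <- make_log(x = c(0, 1), y = c(100, 2), z = c(120, 10))
  b <- batch_receipts(log, M = 5)
  expect_equal(b$batch_index, c(1L, 1L)) # the later sample still joins
  expect_equal(b$y_prime, c(100, 5))     # anchor unmoved, member at deadline
  expect_equal(b$z_prime - b$y_prime, log$z - log$y)
})

test_that("TAT satisfaction counts modified report times against the limit", {
  log <- event_log(c("A", "B", "C", "D"),
                   x = c(0, 8, 40, 41), y = c(10, 20, 52, 45),
                   z = c(25, 36, 66, 95))
  b <- batch_receipts(log, M = 25)
  expect_equal(count_tasks(b), 2L)
  # modified TATs: 40, 33, 39, 74 -> 3 of 4 within the hour
  expect_equal(b$z_prime - b$x, c(40, 33, 39, 74))
  expect_equal(tat_satisfaction(b, 60), 0.75)

  # single record over the limit stays over for any M
  one <- make_log(0, 10, 70)
  expect_equal(tat_satisfaction(batch_receipts(one, 15), 60), 0.0)
  expect_equal(count_tasks(batch_receipts(one, 15)), 1L)
})

test_that("degenerate inputs are handled: M < 0, bad limit, empty log", {
  expect_error(batch_receipts(ex_log(), -1), "non-negative")
  expect_error(tat_satisfaction(batch_receipts(ex_log(), 5), 0), "positive")
  empty <- tatbatch:::new_event_log(
    data.frame(sample_id = character(0), x = numeric(0),
               y = numeric(0), z = numeric(0)))
  b <- batch_receipts(empty, 10)
  expect_equal(count_tasks(b), 0L)
  expect_equal(tat_satisfaction(b, 60), 1.0)
})

test_that("tradeoff_curve composes the batching objectives over the grid", {
  log <- event_log(c("A", "B", "C", "D"),
                   x = c(0, 8, 40, 41), y = c(10, 20, 52, 45),
                   z = c(25, 36, 66, 95))
  tc <- tradeoff_curve(log, c(0, 25))
  expect_equal(tc$M, c(0, 25))
  expect_equal(tc$l, c(4, 2))
  expect_equal(tc$r, c(1.0, 0.75))

  expect_error(tradeoff_curve(log, numeric(0)), "non-empty")
  expect_error(tradeoff_curve(log, c(5, 5)), "strictly increasing")
  expect_error(tradeoff_curve(log, c(-1, 5)), ">= 0")
})

test_that("batching matches the minute-stepping simulator on random logs", {
  set.seed(2024)
  for (i in 1:60) {
    log <- random_int_log(sample(1:20, 1))
    M <- sample(0:60, 1)
    b <- batch_receipts(log, M)
    o <- oracle_batch(log, M)
    expect_equal(b$y_prime, o$y_prime)
    expect_equal(b$batch_index, o$batch_index)
    expect_equal(count_tasks(b), o$n_batches)
  }
})

test_that("batching only delays loadings and conserves the analytical phase", {
  set.seed(7)
  for (i in 1:25) {
    log <- random_int_log(sample(2:25, 1))
    for (M in c(0, 7, 31, 60)) {
      b <- batch_receipts(log, M)
      expect_true(all(b$y_prime >= b$y))
      expect_true(all(b$z_prime >= b$z))
      expect_equal(b$z_prime - b$y_prime, b$z - b$y)
      expect_true(all(b$x <= b$y_prime & b$y_prime <= b$z_prime))
      # every sample in exactly one batch, indices contiguous in anchor order
      expect_true(all(b$batch_index >= 1))
      expect_equal(sort(unique(b$batch_index)), seq_len(count_tasks(b)))
    }
  }
})

test_that("the task count is weakly decreasing in the waiting interval", {
  set.seed(11)
  for (i in 1:15) {
    log <- random_int_log(sample(5:30, 1))
    tc <- tradeoff_curve(log, seq(0, 60, by = 4))
    expect_true(all(diff(tc$l) <= 0))
  }
})
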