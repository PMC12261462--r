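# Synthetic-data generator: known drift, reproducibility, death schedules,
# and the held-out split.

test_that("linear drift moves the latent mean by vT (closed-form SDE mean)", {
  n <- 1000L
  sim <- simulate_timeseries(d = 2L, g = 10L, T = 2L, counts = c(50L, 50L, n),
                             drift_spec = "linear", noise = 0.2,
                             drift_scale = 1.5, seed = 3L)
  ZT <- sim$truth$latents[[3]]
  se <- sd(ZT[, 1]) / sqrt(n)
  expect_lt(abs(mean(ZT[, 1]) - 1.5 * 2), 3 * se + 1e-6)
  expect_lt(abs(mean(ZT[, 2])), 3 * sd(ZT[, 2]) / sqrt(n))
})

test_that("with vanishing noise the linear path matches the deterministic ODE", {
  sim <- simulate_timeseries(d = 2L, g = 5L, T = 1L, counts = c(5L, 5L),
                             drift_spec = "linear", noise = 0, dt = 1e-3, seed = 4L)
  Z0 <- matrix(rnorm(10, 0, 0.3), 5, 2)  # start distribution is N(0, 0.3^2)
  # Euler on a constant field is exact: terminal = start + v*T
  b <- synthetic_drift("linear", d = 2L, drift_scale = 1.5)
  expect_equal(unname(b(Z0, 0)[1, ]), c(1.5, 0))
  ZT <- sim$truth$latents[[2]]
  expect_equal(mean(ZT[, 1]), 1.5, tolerance = 3 * 0.3 / sqrt(5) + 1e-3)
})

test_that("the generator is bit-reproducible and hits counts exactly without killing", {
  a <- simulate_timeseries(seed = 9L)
  b <- simulate_timeseries(seed = 9L)
  expect_identical(a$data$matrices, b$data$matrices)
  expect_identical(a$truth$latents, b$truth$latents)
  expect_identical(a$truth$realized_counts, rep(300L, 5L) * 1L)
  c <- simulate_timeseries(seed = 10L)
  expect_false(identical(a$data$matrices[[1]], c$data$matrices[[1]]))
})

test_that("death schedules shrink later cohorts and match counts in expectation", {
  counts <- c(200L, 200L, 120L, 100L, 100L)
  sim <- simulate_timeseries(d = 2L, g = 10L, T = 4L, counts = counts,
                             drift_spec = "linear",
                             death_window = list(from = 1, to = 3, rate = 1.2),
                             seed = 15L)
  expect_true(all(abs(sim$truth$realized_counts - counts) <=
                    3 * sqrt(counts) + 1))
  expect_true(all(sim$truth$survival[3:5] < 1))
  # growth inside a pure-death window is contradictory
  expect_error(
    simulate_timeseries(d = 2L, g = 10L, T = 2L, counts = c(100L, 50L, 200L),
                        drift_spec = "linear",
                        death_window = list(from = 0.5, to = 2, rate = 1),
                        seed = 1L),
    "grow")
})

test_that("planted driver genes load on the drifting coordinate", {
  sim <- simulate_timeseries(d = 2L, g = 30L, T = 2L, counts = rep(100L, 3L),
                             drift_spec = "linear", seed = 6L)
  expect_identical(sim$truth$driver_genes, 1:5)
  expect_true(all(sim$truth$loading[1L, 1:5] > 0))
  expect_true(all(sim$truth$loading[1L, 6:30] == 0))
  # drivers rise over time, non-drivers stay flat
  rise <- colMeans(sim$data$matrices[[3]]) - colMeans(sim$data$matrices[[1]])
  expect_gt(min(rise[1:5]), max(abs(rise[6:30])))
})

test_that("heldout_split withholds interior timepoints and guards the boundary", {
  mk <- function(T) timeseries(lapply(0:T, function(t) matrix(t, 2, 3)), 0:T)
  hs <- heldout_split(mk(7L), c(3L, 6L))
  expect_identical(hs$train$timepoints, c(0L, 1L, 2L, 4L, 5L, 7L))
  expect_identical(hs$eval_store$timepoints, c(3L, 6L))
  hs2 <- heldout_split(mk(11L), c(4L, 6L, 8L))
  expect_length(hs2$train$timepoints, 9L)
  expect_error(heldout_split(mk(3L), 0L), "boundary")
  expect_error(heldout_split(mk(3L), 3L), "boundary")
  expect_error(heldout_split(mk(3L), 9L), "not present")
})
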