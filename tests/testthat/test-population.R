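# Prior kill rule, transition probabilities, status updates, population loss.

# a kill field with controllable prior and K: stats put every cell in/out of
# deviation range; the net's output bias sets K through the shifted softplus.
make_field <- function(d = 2L, K = 1, b = 0, prior_all = TRUE) {
  stats <- list(timepoints = c(0L, 1L),
                mean = list(rep(0, d), rep(if (prior_all) 100 else 0, d)),
                sd = list(rep(1, d), rep(1e-6, d)), pooled_sd = 1)
  f <- killrate_field(stats, b = b, hidden = 4L, tdim = 4L, seed = 1L)
  if (K == 0) f$offset <- Inf
  else f$net$b[[2L]] <- f$offset + log(exp(K) - 1)  # softplus inverse
  f
}

test_that("prior kill rate follows the 2-sd / 20% rule exactly", {
  d <- 100L
  Z_next <- rbind(rep(1, d), rep(-1, d))  # mean 0, sample sd sqrt(2) per feature
  # a cell equal to the next-timepoint mean never deviates
  expect_equal(prior_kill_rate(matrix(0, 1, d), Z_next), 0)
  # 30 of 100 features beyond 2 sd -> 0.30 exactly
  cell <- rep(0, d); cell[1:30] <- 5
  expect_equal(prior_kill_rate(matrix(cell, 1), Z_next), 0.30)
  # 15 of 100 deviating is under the 20% floor -> 0
  cell2 <- rep(0, d); cell2[1:15] <- 5
  expect_equal(prior_kill_rate(matrix(cell2, 1), Z_next), 0)
  expect_error(prior_kill_rate(matrix(0, 1, d), Z_next[1, , drop = FALSE]), ">= 2 cells")
})

test_that("transition probabilities multiply prior, modulation, and dt, then clip", {
  f1 <- make_field(K = 1)
  Z <- matrix(0, 3, 2)
  tp <- transition_probs(f1, Z, 0, dt = 0.01)
  expect_equal(tp$p_die, rep(0.01, 3), tolerance = 1e-9)   # k=1, K=1, dt=0.01
  expect_equal(tp$p_born, rep(0, 3))
  f0 <- make_field(K = 0, b = 1)
  tp0 <- transition_probs(f0, Z, 0, dt = 0.5)
  expect_equal(tp0$p_die, rep(0, 3))
  expect_equal(tp0$p_born, rep(0, 3))
  # raw values above 1 are clipped but retained
  fbig <- make_field(K = 1.7, b = 1.7)
  tpb <- transition_probs(fbig, Z, 0, dt = 1)
  expect_equal(tpb$p_die, rep(1, 3))
  expect_equal(tpb$raw_die, rep(1.7, 3), tolerance = 1e-9)
  expect_equal(tpb$raw_born, rep(1.7 * 1.7, 3), tolerance = 1e-9)
})

test_that("status updates are Bernoulli with the stated probabilities", {
  A <- rep(1, 10000)
  up <- update_statuses(A, p_die = rep(0.5, 10000), p_born = rep(0, 10000), seed = 3L)
  frac <- mean(up$A == 0)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
  expect_identical(sort(unique(up$A)), c(0, 1))
  # p = 0 leaves statuses unchanged; p_die = 1 kills everyone
  expect_identical(update_statuses(A, rep(0, 10000), rep(0, 10000), seed = 1L)$A, A)
  expect_true(all(update_statuses(A, rep(1, 10000), rep(0, 10000), seed = 1L)$A == 0))
  expect_error(update_statuses(c(1, 2), 0, 0), "binary")
  # the event log replays to the new status vector exactly
  A2 <- rep(c(1, 0), 50)
  up2 <- update_statuses(A2, rep(0.3, 100), rep(0.4, 100), seed = 9L)
  replay <- A2
  replay[up2$events$cell[up2$events$type == "death"]] <- 0
  replay[up2$events$cell[up2$events$type == "birth"]] <- 1
  expect_identical(replay, up2$A)
})

test_that("empirical mass change is (n_i - n_0)/max n", {
  tg <- population_target(c(100, 150, 50))
  expect_equal(empirical_mass_change(tg, 1L), 1 / 3)
  expect_equal(empirical_mass_change(tg, 2L), -1 / 3)
  expect_equal(empirical_mass_change(population_target(c(80, 80)), 1L), 0)
  expect_error(empirical_mass_change(tg, 0L), "intermediate")
  expect_error(empirical_mass_change(tg, 5L), "intermediate")
})

test_that("population loss: degenerate identities and permutation invariance", {
  br <- bridge_new(d = 2L, T = 2, eps = 0.3, n_steps = 10L, seed = 1L)
  Z0 <- matrix(rnorm(20), 10, 2)
  path <- bridge_simulate(br, Z0, "forward", seed = 5L)
  # K = 0 and balanced counts: perfect balance, no penalties, loss 0
  f0 <- make_field(K = 0)
  expect_equal(population_loss(f0, path, population_target(c(10, 10, 10), 0:2)), 0)
  # predicted change 0 vs target 0.5 -> loss 0.5 (single intermediate)
  expect_equal(population_loss(f0, path, population_target(c(100, 200), c(0L, 2L))), 0.5)
  # probabilities all within [0, 1]: penalty terms are exactly 0
  f1 <- make_field(K = 0.5)
  ev <- scbridge:::population_loss_eval(f1, path, population_target(c(10, 10, 10), 0:2))
  expect_equal(ev$value, sum(abs(ev$resid)))
  # permuting cell order leaves the loss unchanged
  perm <- sample(10)
  path2 <- path
  path2$Z <- lapply(path$Z, function(M) M[perm, , drop = FALSE])
  path2$A <- path$A[, perm]
  expect_equal(population_loss(f1, path2, population_target(c(10, 10, 10), 0:2)),
               population_loss(f1, path, population_target(c(10, 10, 10), 0:2)))
})

test_that("killed simulations log replayable events and warn when all die", {
  br <- bridge_new(d = 2L, T = 1, eps = 0.3, n_steps = 6L, seed = 2L)
  f <- make_field(K = 30)  # heavy killing, no births
  Z0 <- matrix(rnorm(30), 15, 2)
  expect_warning(p <- bridge_simulate(br, Z0, "forward", killer = f, seed = 8L),
                 "all cells dead")
  # replay the event log from the initial statuses
  A <- rep(1, 15)
  log <- p$events
  for (i in seq_len(nrow(log)))
    A[log$cell[i]] <- if (log$type[i] == "death") 0 else 1
  expect_identical(A, unname(p$A[nrow(p$A), ]))
})

test_that("training the modulation net reduces the population loss", {
  br <- bridge_new(d = 2L, T = 2, eps = 0.3, n_steps = 20L, seed = 3L)
  stats <- list(timepoints = 0:2, mean = list(rep(0, 2), rep(0, 2), rep(100, 2)),
                sd = list(rep(1, 2), rep(1, 2), rep(1e-6, 2)), pooled_sd = 1)
  f <- killrate_field(stats, b = 0, hidden = 8L, tdim = 4L, t_scale = 10, seed = 2L)
  rho0 <- matrix(rnorm(200), 100, 2)
  target <- population_target(c(100, 60, 60), 0:2)
  tr <- train_killrate(f, br, rho0, target, epochs = 80L, lr = 1e-2, seed = 4L)
  expect_lt(mean(tail(tr$history, 10)), mean(head(tr$history, 10)))
})
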