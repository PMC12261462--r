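# Drift evaluation, Euler-Maruyama simulation, divergence estimators,
# likelihood losses and their degenerate values, IPF mechanics.

test_that("drift evaluation: zero init, shape contract, continuity", {
  br <- bridge_new(d = 3L, T = 1, eps = 0.2, n_steps = 10L, seed = 1L)
  Z <- matrix(rnorm(15), 5, 3)
  expect_true(all(drift(br, Z, 0.5, "forward") == 0))
  expect_true(all(drift(br, Z, 0.5, "backward") == 0))
  br$fwd <- scbridge:::mlp_new(c(3L + 8L, 16L, 3L), act = "tanh")
  Q <- drift(br, Z, 0.5, "forward")
  expect_equal(dim(Q), c(5L, 3L))
  # continuity: small state change, small drift change
  expect_lt(max(abs(drift(br, Z + 1e-7, 0.5) - Q)), 1e-5)
  expect_error(drift(br, Z[, 1:2], 0.5), "latent dim")
})

test_that("simulation degenerate cases: frozen state and exact constant drift", {
  # eps = 0, drifts 0, f = 0: state never moves
  br <- bridge_new(d = 2L, T = 1, eps = 0, n_steps = 10L, seed = 1L)
  Z0 <- matrix(rnorm(8), 4, 2)
  p <- bridge_simulate(br, Z0, "forward", seed = 1L)
  for (i in seq_along(p$Z)) expect_identical(p$Z[[i]], Z0)
  # eps = 0 with constant base drift f = c: Euler is exact, Z_T - Z_0 = cT
  br2 <- bridge_new(d = 2L, T = 2, eps = 0, f = c(0.7, -0.3), n_steps = 20L, seed = 1L)
  p2 <- bridge_simulate(br2, Z0, "forward", seed = 1L)
  expect_equal(p2$Z[[21]] - Z0,
               matrix(rep(c(0.7, -0.3) * 2, each = 4), 4, 2), tolerance = 1e-12)
})

test_that("Brownian increments have variance eps^2 dt", {
  br <- bridge_new(d = 1L, T = 1, eps = 1, n_steps = 10L, seed = 1L)
  p <- bridge_simulate(br, matrix(0, 10000, 1), "forward", seed = 4L)
  v <- var(drop(p$Z[[2]] - p$Z[[1]]))
  se <- 0.1 * sqrt(2 / 9999)
  expect_lt(abs(v - 1^2 * 0.1), 3 * se)
})

test_that("simulation without killing conserves the live-cell count", {
  br <- bridge_new(d = 2L, T = 1, eps = 0.3, n_steps = 15L, seed = 2L)
  p <- bridge_simulate(br, matrix(rnorm(40), 20, 2), "forward", seed = 3L)
  expect_true(all(rowSums(p$A) == 20))
  pb <- bridge_simulate(br, matrix(rnorm(40), 20, 2), "backward", seed = 3L)
  expect_true(all(rowSums(pb$A) == 20))
})

test_that("with zero drifts forward and backward laws coincide", {
  br <- bridge_new(d = 1L, T = 1, eps = 0.5, n_steps = 20L, seed = 1L)
  Z0 <- matrix(rnorm(5000, 0, 0.01), ncol = 1)
  pf <- bridge_simulate(br, Z0, "forward", seed = 11L)
  pb <- bridge_simulate(br, Z0, "backward", seed = 12L)
  ks <- suppressWarnings(ks.test(drop(pf$Z[[21]]), drop(pb$Z[[1]])))
  expect_gt(ks$p.value, 0.01)
})

test_that("divergence: linear fields give the exact trace on every branch", {
  A <- matrix(c(2, 1, 0, -0.5, 1, 0.3, 0, 0, -3), 3, 3)
  Z <- matrix(rnorm(12), 4, 3)
  expect_equal(divergence(A, Z, method = "exact"), rep(sum(diag(A)), 4))
  expect_equal(divergence(A, Z, method = "hutchinson", m = 8L), rep(sum(diag(A)), 4))
  expect_equal(divergence(diag(3), Z, method = "exact"), rep(3, 4))
  f <- function(ZZ) ZZ %*% A
  expect_equal(divergence(f, Z, method = "fd"), rep(sum(diag(A)), 4), tolerance = 1e-7)
})

test_that("divergence of a random drift network agrees with finite differences", {
  br <- bridge_new(d = 5L, T = 1, eps = 0.2, n_steps = 10L, seed = 7L)
  br$fwd <- scbridge:::mlp_new(c(5L + 8L, 32L, 5L), act = "tanh")
  Z <- matrix(rnorm(50), 10, 5)
  fld <- drift_field(br, 0.4, "forward")
  dex <- divergence(fld, Z, method = "exact")
  dfd <- divergence(fld, Z, method = "fd")
  dhu <- divergence(fld, Z, method = "hutchinson", m = 8L)
  expect_lt(max(abs(dex - dfd)), 1e-4)
  expect_lt(max(abs(dhu - dfd)), 1e-4)
})

test_that("likelihood losses: zero drift gives zero, constant drift sums as printed", {
  br <- bridge_new(d = 2L, T = 1, eps = 0.5, n_steps = 10L, seed = 1L)
  Z0 <- matrix(rnorm(12), 6, 2)
  pb <- bridge_simulate(br, Z0, "backward", seed = 2L)
  pf <- bridge_simulate(br, Z0, "forward", seed = 2L)
  expect_equal(loss_div_forward(br, pb), 0)
  expect_equal(loss_div_backward(br, pf), 0)
  expect_error(loss_div_forward(br, pf), "backward")
  expect_error(loss_div_backward(br, pb), "forward")
  # Q = c constant (divergence 0), Qhat = 0, all cells live:
  # loss = dt * (#nodes) * n * 0.5 * ||c||^2
  cvec <- c(0.3, -0.4)
  brc <- constant_drift_bridge(2L, cvec, T = 1, eps = 0.5, n_steps = 10L)
  pb2 <- bridge_simulate(brc, Z0, "backward", seed = 3L)
  nodes <- length(pb2$Z)
  expect_equal(loss_div_forward(brc, pb2),
               0.1 * nodes * 6 * 0.5 * sum(cvec^2), tolerance = 1e-10)
})

test_that("dead cells contribute nothing to the likelihood losses", {
  br <- constant_drift_bridge(2L, c(1, 2), T = 1, eps = 0.5, n_steps = 6L)
  br$bwd$b[[2L]] <- c(0.5, 0.1)
  pb <- bridge_simulate(br, matrix(rnorm(10), 5, 2), "backward", seed = 4L)
  full <- loss_div_forward(br, pb)
  pb$A[, 3] <- 0  # kill cell 3 along the whole path
  masked <- loss_div_forward(br, pb)
  expect_equal(masked, full * 4 / 5, tolerance = 1e-10)
})

test_that("swapping the drift roles mirrors the two losses exactly", {
  br <- bridge_new(d = 2L, T = 1, eps = 0.4, n_steps = 8L, seed = 9L)
  br$fwd <- scbridge:::mlp_new(c(2L + 8L, 12L, 2L), act = "tanh")
  br$bwd <- scbridge:::mlp_new(c(2L + 8L, 12L, 2L), act = "tanh")
  path <- bridge_simulate(br, matrix(rnorm(16), 8, 2), "forward", seed = 5L)
  swapped <- br
  swapped$fwd <- br$bwd; swapped$bwd <- br$fwd
  mirrored <- path; mirrored$direction <- "backward"
  expect_equal(loss_div_backward(br, path), loss_div_forward(swapped, mirrored))
})

test_that("ipf: zero rounds is the identity, diagnostics mostly improve", {
  toy <- toy_ipf()
  br <- bridge_new(d = 1L, T = 1, eps = 0.5, n_steps = 20L, seed = 1L)
  out0 <- ipf_round(br, toy$rho0, toy$rhoT, rounds = 0L)
  expect_identical(out0$bridge$fwd$W, br$fwd$W)
  expect_identical(nrow(out0$diagnostics), 0L)
  dd <- toy$result$diagnostics$w2_terminal
  frac_down <- mean(diff(c(toy$round0$w2_terminal, dd)) < 0)
  expect_gte(frac_down, 0.7)
})
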