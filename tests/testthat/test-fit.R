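# Trainer mechanics: joint loss, phase parameter isolation, determinism,
# held-out evaluation plumbing.

tiny_fit_config <- function(seed = 1L) {
  scbridge_config(d = 3L, vae_hidden = c(16L), tdim = 4L, bridge_tdim = 4L,
                  n_steps = 8L, rounds = 1L, vae_epochs = 8L, inner_steps = 6L,
                  kill_epochs = 4L, sim_cells = 40L, batch = 64L,
                  replicates = 2L, seed = seed)
}

tiny_data <- function(seed = 2L) {
  simulate_timeseries(d = 2L, g = 12L, T = 2L, counts = rep(60L, 3L),
                      drift_spec = "linear", seed = seed)$data
}

test_that("joint loss vanishes when path, latents, and reconstruction agree", {
  v <- vae_new(g = 5L, d = 2L, hidden = c(4L), tdim = 4L, zero_out = TRUE)
  br <- bridge_new(d = 2L, T = 1, eps = 0, n_steps = 4L, seed = 1L)
  X <- matrix(0, 6, 5)                       # zero data
  path <- bridge_simulate(br, matrix(0, 6, 2), "forward", seed = 1L)
  expect_equal(joint_loss(v, path, X, 1), 0) # mu = 0 = path states, decode = 0 = X
  expect_gte(joint_loss(v, path, X + 1, 1), 0)
  expect_error(joint_loss(v, path, X, 0.37), "not on the path grid")
})

test_that("each optimisation phase touches only its own parameters", {
  data <- tiny_data()
  cfg <- tiny_fit_config()
  v <- vae_new(12L, d = 3L, hidden = c(16L), tdim = 4L, seed = 1L)
  v <- vae_pretrain(v, data, epochs = 5L, seed = 2L)
  ens <- scbridge:::encode_ensembles(v, data, 3L)
  br <- bridge_new(3L, T = 2, eps = 0.1, n_steps = 8L, tdim = 4L, seed = 4L)
  fp <- scbridge:::params_fingerprint

  out <- ipf_round(br, ens[[1]], ens[[3]], rounds = 1L, inner_steps = 4L, seed = 5L)
  expect_false(fp(out$bridge$fwd) == fp(br$fwd))
  expect_false(fp(out$bridge$bwd) == fp(br$bwd))
  # drift training never touches the VAE (it does not see it)

  stats <- scbridge:::latent_stats_new(ens, data$timepoints)
  kf <- killrate_field(stats, b = 0, hidden = 4L, tdim = 4L, seed = 6L)
  tk <- train_killrate(kf, out$bridge, ens[[1]],
                       population_target(c(60, 40, 40), 0:2), epochs = 5L, seed = 7L)
  expect_false(fp(tk$field$net) == fp(kf$net))
  expect_identical(tk$field$stats, kf$stats)    # only omega moves

  path <- bridge_simulate(out$bridge, ens[[1]], "forward", seed = 8L)
  js <- scbridge:::joint_vae_step(v, path, data, 1, 1e-3,
                                  list(e = scbridge:::adam_new(v$encoder),
                                       d = scbridge:::adam_new(v$decoder)), 9L)
  expect_false(fp(js$vae$encoder) == fp(v$encoder))
  expect_identical(out$bridge$fwd$W, ipf_round(br, ens[[1]], ens[[3]], rounds = 1L,
                                               inner_steps = 4L, seed = 5L)$bridge$fwd$W)
})

test_that("fitting is reproducible and zero rounds returns the pretrained state", {
  data <- tiny_data()
  f1 <- scbridge(data, tiny_fit_config(seed = 3L))
  f2 <- scbridge(data, tiny_fit_config(seed = 3L))
  fp <- scbridge:::params_fingerprint
  expect_identical(fp(f1$vae$encoder), fp(f2$vae$encoder))
  expect_identical(fp(f1$bridge$fwd), fp(f2$bridge$fwd))
  expect_identical(f1$report$kill_history, f2$report$kill_history)

  cfg0 <- tiny_fit_config(); cfg0$rounds <- 0L
  f0 <- scbridge(data, cfg0)
  expect_true(all(f0$bridge$fwd$W[[2]] == 0))  # drift untouched at zero rounds
  expect_identical(nrow(f0$report$diagnostics), 0L)
})

test_that("fit guards: boundary timepoints required, two-timepoint warning", {
  data <- tiny_data()
  shifted <- data; shifted$timepoints <- shifted$timepoints + 1L
  expect_error(scbridge(shifted, tiny_fit_config()), "timepoint 0")
  two <- data
  two$matrices <- two$matrices[c(1, 3)]; two$cell_ids <- two$cell_ids[c(1, 3)]
  two$timepoints <- two$timepoints[c(1, 3)]
  expect_warning(scbridge(two, tiny_fit_config()), "fewer than 3")
})

test_that("held-out evaluation reports replicate spread and a copy baseline", {
  sf <- shared_fit()
  tab <- evaluate_heldout(sf$fit, sf$eval_store, replicates = 2L, seed = 1L)
  expect_identical(tab$timepoint, 2L)
  expect_true(all(is.finite(tab$w2_mean)) && all(tab$w2_mean > 0))
  expect_true(all(is.finite(tab$baseline_copy_prev)))
  expect_match(tab$w2, "^[0-9.]+±[0-9.]+$")
  # identical predictions give distance zero (the trivial case)
  expect_equal(as.numeric(w2_distance(sf$eval_store$matrices[[1]],
                                      sf$eval_store$matrices[[1]])), 0,
               tolerance = 1e-5)
})

test_that("S3 surface: print, summary, predict, simulate, residuals", {
  sf <- shared_fit()
  expect_output(print(sf$fit), "Schrodinger bridge")
  expect_output(print(summary(sf$fit)), "boundary")
  pr <- predict(sf$fit, timepoints = c(0, 4), seed = 3L)
  expect_named(pr, c("t0", "t4"))
  expect_identical(ncol(pr$t0), 50L)
  st <- predict(sf$fit, timepoints = 4, type = "status", seed = 3L)
  expect_true(all(st$t4 %in% c(0, 1)))
  sims <- simulate(sf$fit, nsim = 2L, seed = 4L)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "sb_trajectory")
  res <- residuals(sf$fit)
  expect_length(res, 4L)
  expect_identical(dim(res[[1]]), dim(sf$train$matrices[[1]]))
})
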