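# Model fitting: VAE pretraining, IPF rounds with VAE co-training in the
# forward pass, kill-rate training, diagnostics, and held-out evaluation.

#' Training configuration
#'
#' Collects every tunable of [scbridge()] with the package defaults.
#'
#' @param d latent dimension.
#' @param vae_hidden,bridge_hidden,kill_hidden hidden widths.
#' @param tdim,bridge_tdim sinusoidal time-encoding dimensions (VAE / drift
#'   and kill nets).
#' @param beta KL weight of the VAE loss.
#' @param eps diffusion coefficient of the bridge SDEs.
#' @param f base drift (scalar or length-d).
#' @param n_steps Euler-Maruyama steps over `[0, T]`; rounded up to a multiple
#'   of T so every measured timepoint lies exactly on a grid node.
#' @param rounds IPF rounds.
#' @param vae_epochs,inner_steps,kill_epochs epochs for pretraining, per IPF
#'   pass, and kill-rate training per round.
#' @param lr_vae,lr_drift,lr_kill,lr_joint Adam learning rates.
#' @param lambda_joint weight of the joint VAE/bridge loss.
#' @param joint_every co-train the VAE every this many inner steps of the
#'   forward pass.
#' @param batch VAE minibatch size.
#' @param sim_cells cells per simulated path during training.
#' @param population learn birth/death dynamics (needs >= 3 measured
#'   timepoints).
#' @param b birth rate; `NULL` = 0 unless measured counts increase anywhere,
#'   then 1.
#' @param kill_state_dependent feed the latent state (not only time) to the
#'   kill-rate net.
#' @param replicates sampling replicates for held-out evaluation.
#' @param seed master seed; all phase seeds derive from it.
#' @param verbose print progress.
#' @return a list of class `scbridge_config`.
#' @export
scbridge_config <- function(d = 16L, vae_hidden = c(128L, 128L), bridge_hidden = 32L,
                            kill_hidden = 16L, tdim = 16L, bridge_tdim = 8L,
                            beta = 0.01, eps = 0.1, f = 0, n_steps = 100L,
                            rounds = 6L, vae_epochs = 200L, inner_steps = 120L,
                            kill_epochs = 40L, lr_vae = 1e-3, lr_drift = 1e-2,
                            lr_kill = 5e-3, lr_joint = 1e-4, lambda_joint = 1,
                            joint_every = 10L, batch = 128L, sim_cells = 256L,
                            population = TRUE, b = NULL,
                            kill_state_dependent = FALSE, replicates = 5L,
                            seed = 1L, verbose = FALSE) {
  cfg <- as.list(environment())
  stopifnot(cfg$eps > 0, cfg$beta >= 0, cfg$n_steps >= 2, cfg$rounds >= 0)
  class(cfg) <- "scbridge_config"
  cfg
}

encode_ensembles <- function(vae, data, seed) {
  lapply(seq_along(data$timepoints), function(k) {
    enc <- vae_encode(vae, data$matrices[[k]], data$timepoints[k])
    vae_sample_latent(enc, seed = derive_seed(seed, 300L + k))
  })
}

#' Joint VAE/bridge loss
#'
#' `W2(Z_phi_t, Zfwd_t) + W2(X_t, decode(Z_phi_t))`: the 2-Wasserstein
#' distance between the encoder latents at timepoint t and the forward-path
#' states at the matching grid node, plus the distance between the data and
#' its reconstruction. Penalises a latent space the bridge cannot traverse.
#'
#' @param vae an `sb_vae`.
#' @param path a forward `sb_trajectory`.
#' @param X cells x genes data measured at `t`.
#' @param t measured timepoint (must lie on the path grid).
#' @return scalar loss.
#' @export
joint_loss <- function(vae, path, X, t) {
  dt <- path$t_grid[2L] - path$t_grid[1L]
  node <- round(t / dt) + 1L
  if (node < 1L || node > length(path$Z) || is.null(path$Z[[node]]) ||
      abs(path$t_grid[node] - t) > 1e-9)
    stopf("timepoint %g is not on the path grid", t)
  enc <- vae_encode(vae, X, t)
  Zp <- path$Z[[node]][path$A[node, ] == 1, , drop = FALSE]
  w2a <- w2_distance(enc$mu, Zp)
  w2b <- w2_distance(X, vae_decode(vae, enc$mu, t))
  as.numeric(w2a + w2b)
}

# One VAE co-training step on the matched-pair surrogate of the joint loss:
# the W2 matchings are held fixed (Danskin) and the matched squared distances
# are differentiated through encoder mean and decoder.
joint_vae_step <- function(vae, path, data, lambda, lr, states, seed) {
  dt <- path$t_grid[2L] - path$t_grid[1L]
  gr_e <- NULL; gr_d <- NULL
  loss <- 0
  for (k in seq_along(data$timepoints)) {
    t <- data$timepoints[k]
    node <- round(t / dt) + 1L
    Zp <- path$Z[[node]]
    if (is.null(Zp)) next
    Zp <- Zp[path$A[node, ] == 1, , drop = FALSE]
    X <- data$matrices[[k]]
    m <- min(nrow(X), nrow(Zp), 256L)
    if (m < 2L) next
    ix <- with_seed(derive_seed(seed, 40L + k), sample(nrow(X), m))
    iz <- with_seed(derive_seed(seed, 80L + k), sample(nrow(Zp), m))
    Xb <- X[ix, , drop = FALSE]; Zb <- Zp[iz, , drop = FALSE]
    tf <- time_features(t, m, vae$tdim)
    ec <- mlp_forward(vae$encoder, cbind(Xb, tf), keep_cache = TRUE)
    mu <- ec$out[, seq_len(vae$d), drop = FALSE]
    dc <- mlp_forward(vae$decoder, cbind(mu, tf), keep_cache = TRUE)
    Xh <- dc$out
    D1 <- sq_dist_matrix(mu, Zb); m1 <- .solve_assignment(D1)
    D2 <- sq_dist_matrix(Xb, Xh); m2 <- .solve_assignment(D2)
    loss <- loss + sqrt(mean(D1[cbind(seq_len(m), m1)])) +
      sqrt(mean(D2[cbind(seq_len(m), m2)]))
    dmu_lat <- 2 * (mu - Zb[m1, , drop = FALSE]) / m
    dXh <- 2 * (Xh - Xb[order(m2), , drop = FALSE]) / (m * ncol(Xb))
    bd <- mlp_backward(vae$decoder, dc, lambda * dXh)
    dmu <- lambda * dmu_lat + bd$dX[, seq_len(vae$d), drop = FALSE]
    be <- mlp_backward(vae$encoder, ec, cbind(dmu, matrix(0, m, vae$d)))
    gr_e <- grads_add(gr_e, list(gW = be$gW, gb = be$gb))
    gr_d <- grads_add(gr_d, list(gW = bd$gW, gb = bd$gb))
  }
  if (!is.null(gr_e)) {
    up <- adam_step(vae$encoder, gr_e, states$e, lr); vae$encoder <- up$net; states$e <- up$state
    up <- adam_step(vae$decoder, gr_d, states$d, lr); vae$decoder <- up$net; states$d <- up$state
  }
  list(vae = vae, states = states, loss = loss)
}

#' Fit the trajectory model
#'
#' Runs the full training schedule on preprocessed time-series expression
#' data: (1) VAE pretraining on all measured timepoints; (2) `rounds` IPF
#' rounds, each a forward pass (backward simulations, forward-drift likelihood
#' loss, with the VAE co-trained on the joint loss), a backward pass (forward
#' simulations, backward-drift loss), and a kill-rate pass (population loss);
#' (3) per-round boundary-matching diagnostics. All randomness derives from
#' `config$seed`; a rerun with the same data and config is identical.
#'
#' @param data training `sc_timeseries` (preprocessed; held-out timepoints
#'   already removed, e.g. via [heldout_split()]).
#' @param config an [scbridge_config()].
#' @return an object of class `scbridge` with components `vae`, `bridge`,
#'   `killfield`, `ensembles` (per-timepoint latents), `latent_stats`,
#'   `target` (population counts), `report` (loss histories and per-round
#'   diagnostics), `data` (the training object), and `config`.
#' @seealso [predict.scbridge()], [evaluate_heldout()],
#'   [reconstruct_trajectory()], [drift_gene_scores()]
#' @export
scbridge <- function(data, config = scbridge_config()) {
  validate_timeseries(data)
  tps <- data$timepoints
  if (length(tps) < 2L) stopf("need at least the two boundary timepoints")
  if (min(tps) != 0L) stopf("training data must include timepoint 0")
  Tmax <- max(tps)
  counts <- n_cells(data)
  g <- length(data$gene_names)
  cfg <- config
  n_steps <- as.integer(ceiling(cfg$n_steps / Tmax) * Tmax)

  do_population <- cfg$population && length(tps) >= 3L
  if (cfg$population && length(tps) < 3L)
    warnf("fewer than 3 measured timepoints: skipping the population (kill-rate) phase")

  if (cfg$verbose) message("phase 1/3: VAE pretraining")
  vae <- vae_new(g, d = cfg$d, hidden = cfg$vae_hidden, tdim = cfg$tdim,
                 beta = cfg$beta, seed = derive_seed(cfg$seed, 1L))
  vae <- vae_pretrain(vae, data, epochs = cfg$vae_epochs, batch = cfg$batch,
                      lr = cfg$lr_vae, seed = derive_seed(cfg$seed, 2L),
                      verbose = cfg$verbose)

  ensembles <- encode_ensembles(vae, data, derive_seed(cfg$seed, 3L))
  stats <- latent_stats_new(ensembles, tps)
  bridge <- bridge_new(cfg$d, T = Tmax, eps = cfg$eps, f = cfg$f,
                       n_steps = n_steps, hidden = cfg$bridge_hidden,
                       tdim = cfg$bridge_tdim, seed = derive_seed(cfg$seed, 4L))
  target <- population_target(counts, tps)
  killfield <- NULL
  if (do_population) {
    b <- cfg$b %||% (if (any(diff(counts) > 0)) 1 else 0)
    killfield <- killrate_field(stats, b = b, hidden = cfg$kill_hidden,
                                tdim = cfg$bridge_tdim,
                                state_dependent = cfg$kill_state_dependent,
                                t_scale = n_steps / Tmax,
                                seed = derive_seed(cfg$seed, 5L))
  }

  diagnostics <- list()
  joint_hist <- numeric(0)
  kill_hist <- numeric(0)
  jstates <- list(e = adam_new(vae$encoder), d = adam_new(vae$decoder))
  if (cfg$rounds > 0L) for (r in seq_len(cfg$rounds)) {
    if (cfg$verbose) message(sprintf("phase 2/3: IPF round %d/%d", r, cfg$rounds))
    rho0 <- ensembles[[1L]]
    rhoT <- ensembles[[length(ensembles)]]
    # forward pass (train theta; co-train VAE on the joint loss)
    st <- adam_new(bridge$fwd)
    for (e in seq_len(cfg$inner_steps)) {
      s <- derive_seed(cfg$seed, r * 100000L + e)
      idx <- with_seed(s, sample(nrow(rhoT), min(cfg$sim_cells, nrow(rhoT))))
      path <- bridge_simulate(bridge, rhoT[idx, , drop = FALSE], "backward",
                              seed = derive_seed(s, 1L))
      pass <- div_loss_pass(bridge, path, "forward", want_grads = TRUE)
      if (!is.finite(pass$value)) stopf("non-finite forward-pass loss (round %d)", r)
      up <- adam_step(bridge$fwd, pass$grads, st, lr = cfg$lr_drift)
      bridge$fwd <- up$net; st <- up$state
      if (cfg$lambda_joint > 0 && e %% cfg$joint_every == 0L) {
        i0 <- with_seed(derive_seed(s, 2L), sample(nrow(rho0), min(cfg$sim_cells, nrow(rho0))))
        fpath <- bridge_simulate(bridge, rho0[i0, , drop = FALSE], "forward",
                                 killer = killfield, seed = derive_seed(s, 3L))
        js <- joint_vae_step(vae, fpath, data, cfg$lambda_joint, cfg$lr_joint,
                             jstates, derive_seed(s, 4L))
        vae <- js$vae; jstates <- js$states
        joint_hist <- c(joint_hist, js$loss)
      }
    }
    # backward pass (train theta-hat)
    st <- adam_new(bridge$bwd)
    for (e in seq_len(cfg$inner_steps)) {
      s <- derive_seed(cfg$seed, r * 100000L + 50000L + e)
      idx <- with_seed(s, sample(nrow(rho0), min(cfg$sim_cells, nrow(rho0))))
      path <- bridge_simulate(bridge, rho0[idx, , drop = FALSE], "forward",
                              killer = killfield, seed = derive_seed(s, 1L))
      pass <- div_loss_pass(bridge, path, "backward", want_grads = TRUE)
      if (!is.finite(pass$value)) stopf("non-finite backward-pass loss (round %d)", r)
      up <- adam_step(bridge$bwd, pass$grads, st, lr = cfg$lr_drift)
      bridge$bwd <- up$net; st <- up$state
    }
    # kill-rate pass
    if (do_population && cfg$kill_epochs > 0L) {
      tk <- train_killrate(killfield, bridge, rho0, target,
                           epochs = cfg$kill_epochs, lr = cfg$lr_kill,
                           sim_cells = cfg$sim_cells,
                           seed = derive_seed(cfg$seed, r * 100000L + 90000L))
      killfield <- tk$field
      kill_hist <- c(kill_hist, tk$history)
    }
    # re-encode: the VAE moved during co-training
    ensembles <- encode_ensembles(vae, data, derive_seed(cfg$seed, 300L))
    stats <- latent_stats_new(ensembles, tps)
    if (!is.null(killfield)) killfield$stats <- stats
    diagnostics[[r]] <- cbind(round = r, bridge_boundary_diag(
      bridge, ensembles[[1L]], ensembles[[length(ensembles)]],
      killer = killfield, seed = derive_seed(cfg$seed, 600L + r)))
  }

  structure(list(
    vae = vae, bridge = bridge, killfield = killfield,
    ensembles = ensembles, latent_stats = stats, target = target,
    data = data, config = cfg,
    report = list(vae_history = vae$history,
                  joint_history = joint_hist,
                  kill_history = kill_hist,
                  diagnostics = if (length(diagnostics)) do.call(rbind, diagnostics)
                                else data.frame())),
    class = "scbridge")
}

#' Evaluate held-out timepoints
#'
#' Reconstructs the trajectory from the measured t = 0 cells, decodes the
#' predictions at each held-out grid node, and reports the gene-space
#' 2-Wasserstein distance to the withheld data over sampling replicates
#' (mean, sd, and the conventional "m±s" string), alongside a naive baseline
#' that copies the nearest earlier measured timepoint.
#'
#' @param fit an [scbridge] fit.
#' @param eval_store the held-out store from [heldout_split()].
#' @param replicates sampling replicates.
#' @param seed RNG seed.
#' @return data frame, one row per held-out timepoint.
#' @export
evaluate_heldout <- function(fit, eval_store, replicates = fit$config$replicates,
                             seed = fit$config$seed) {
  dt <- fit$bridge$dt
  w2 <- matrix(NA_real_, replicates, length(eval_store$timepoints))
  w2lat <- w2
  for (r in seq_len(replicates)) {
    traj <- reconstruct_trajectory(fit, seed = derive_seed(seed, 5000L + r))
    for (q in seq_along(eval_store$timepoints)) {
      t <- eval_store$timepoints[q]
      node <- round(t / dt) + 1L
      live <- traj$A[node, ] == 1
      w2[r, q] <- as.numeric(w2_distance(traj$X[[node]][live, , drop = FALSE],
                                         eval_store$matrices[[q]]))
      enc <- vae_encode(fit$vae, eval_store$matrices[[q]], t)
      w2lat[r, q] <- as.numeric(w2_distance(traj$Z[[node]][live, , drop = FALSE], enc$mu))
    }
  }
  baseline <- vapply(eval_store$timepoints, function(t) {
    prev <- max(fit$data$timepoints[fit$data$timepoints < t])
    as.numeric(w2_distance(fit$data$matrices[[match(prev, fit$data$timepoints)]],
                           eval_store$matrices[[match(t, eval_store$timepoints)]]))
  }, 0)
  data.frame(timepoint = eval_store$timepoints,
             w2_mean = colMeans(w2), w2_sd = apply(w2, 2L, sd),
             w2 = sprintf("%.3f±%.3f", colMeans(w2), apply(w2, 2L, sd)),
             w2_latent_mean = colMeans(w2lat),
             baseline_copy_prev = baseline)
}

# ---- S3 methods -----------------------------------------------------------

#' @method print scbridge
#' @export
print.scbridge <- function(x, ...) {
  cat("Unbalanced diffusion Schrodinger bridge fit\n")
  cat(sprintf("  timepoints: %s (cells: %s)\n",
              paste(x$data$timepoints, collapse = ", "),
              paste(n_cells(x$data), collapse = ", ")))
  cat(sprintf("  genes: %d, latent dim: %d, eps: %g, grid: %d steps on [0, %g]\n",
              length(x$data$gene_names), x$config$d, x$config$eps,
              x$bridge$n_steps, x$bridge$T))
  cat(sprintf("  IPF rounds: %d; population dynamics: %s\n", x$config$rounds,
              if (is.null(x$killfield)) "off" else sprintf("on (b = %g)", x$killfield$b)))
  if (nrow(x$report$diagnostics)) {
    dd <- x$report$diagnostics
    cat(sprintf("  boundary W2 (terminal): %.4f -> %.4f over %d rounds\n",
                dd$w2_terminal[1L], dd$w2_terminal[nrow(dd)], nrow(dd)))
  }
  invisible(x)
}

#' @method summary scbridge
#' @export
summary.scbridge <- function(object, ...) {
  out <- list(fit = object,
              vae_final_loss = utils::tail(object$report$vae_history$loss, 1L),
              diagnostics = object$report$diagnostics,
              counts = n_cells(object$data))
  class(out) <- "summary.scbridge"
  out
}

#' @method print summary.scbridge
#' @export
print.summary.scbridge <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  VAE final pretraining loss: %.5f\n", x$vae_final_loss))
  if (nrow(x$diagnostics)) {
    cat("  per-round boundary diagnostics:\n")
    print(x$diagnostics, row.names = FALSE)
  }
  invisible(x)
}

#' Predict expression along the reconstructed trajectory
#'
#' @param object an [scbridge] fit.
#' @param newdata optional cells x genes matrix at t = 0 (default: the
#'   training t = 0 cells).
#' @param timepoints times to report (default: every measured timepoint;
#'   fractional times snap to the nearest grid node).
#' @param type `"expression"` (decoded), `"latent"`, or `"status"`.
#' @param seed RNG seed.
#' @param ... unused.
#' @return named list of matrices (or status vectors), one per requested time.
#' @export
predict.scbridge <- function(object, newdata = NULL, timepoints = NULL,
                             type = c("expression", "latent", "status"),
                             seed = object$config$seed, ...) {
  type <- match.arg(type)
  traj <- reconstruct_trajectory(object, X0 = newdata, seed = seed)
  tps <- timepoints %||% object$data$timepoints
  dt <- object$bridge$dt
  out <- lapply(tps, function(t) {
    node <- min(max(round(t / dt), 0L), object$bridge$n_steps) + 1L
    switch(type,
      expression = traj$X[[node]],
      latent = traj$Z[[node]],
      status = traj$A[node, ])
  })
  names(out) <- paste0("t", tps)
  out
}

#' Simulate latent trajectories from a fit
#'
#' Draws `nsim` forward trajectories (with birth/death if the fit has a
#' kill-rate field) from the encoded t = 0 boundary.
#'
#' @param object an [scbridge] fit.
#' @param nsim number of trajectories.
#' @param seed RNG seed.
#' @param ... unused.
#' @return list of `sb_trajectory`.
#' @export
simulate.scbridge <- function(object, nsim = 1L, seed = object$config$seed, ...) {
  lapply(seq_len(nsim), function(i)
    bridge_simulate(object$bridge, object$ensembles[[1L]], "forward",
                    killer = object$killfield, seed = derive_seed(seed, 8000L + i)))
}

#' VAE reconstruction residuals
#'
#' @param object an [scbridge] fit.
#' @param ... unused.
#' @return list of residual matrices (data minus reconstruction from the
#'   encoder mean), one per measured timepoint.
#' @export
residuals.scbridge <- function(object, ...) {
  lapply(seq_along(object$data$timepoints), function(k) {
    t <- object$data$timepoints[k]
    X <- object$data$matrices[[k]]
    enc <- vae_encode(object$vae, X, t)
    X - vae_decode(object$vae, enc$mu, t)
  })
}

#' Diagnostic plots for a fit
#'
#' Panel 1: VAE pretraining loss. Panel 2: per-round boundary W2
#' diagnostics. Panel 3 (d >= 2): the learned forward drift field over the
#' latent ensembles, drawn as arrows on the first two latent coordinates.
#'
#' @param x an [scbridge] fit.
#' @param which subset of panels.
#' @param ... unused.
#' @export
plot.scbridge <- function(x, which = 1:3, ...) {
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if (1 %in% which) {
    plot(x$report$vae_history$epoch, x$report$vae_history$loss, type = "l",
         xlab = "epoch", ylab = "VAE loss", main = "pretraining")
  }
  if (2 %in% which && nrow(x$report$diagnostics)) {
    dd <- x$report$diagnostics
    graphics::matplot(dd$round, cbind(dd$w2_terminal, dd$w2_initial), type = "b",
                      pch = 1, xlab = "IPF round", ylab = "boundary W2",
                      main = "boundary matching")
    graphics::legend("topright", c("terminal", "initial"), lty = 1:2, col = 1:2, bty = "n")
  }
  if (3 %in% which && x$config$d >= 2L) {
    Z <- do.call(rbind, x$ensembles)
    tt <- rep(x$data$timepoints, vapply(x$ensembles, nrow, 0L))
    idx <- seq(1L, nrow(Z), length.out = min(300L, nrow(Z)))
    plot(Z[, 1L], Z[, 2L], col = grDevices::grey(0.8), pch = 16, cex = 0.4,
         xlab = "latent 1", ylab = "latent 2", main = "forward drift")
    for (i in idx) {
      q <- drift(x$bridge, Z[i, , drop = FALSE], tt[i], "forward") * x$bridge$eps
      graphics::arrows(Z[i, 1L], Z[i, 2L], Z[i, 1L] + q[1L], Z[i, 2L] + q[2L],
                       length = 0.03, col = "steelblue")
    }
  }
  invisible(x)
}
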