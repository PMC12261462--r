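# Unbalanced dynamics: data-derived prior kill rates, the learned kill-rate
# modulation network K_omega, birth/death transition probabilities, the
# population loss, and the per-step status update used inside path simulation.

#' Prior kill rate from the next measured timepoint
#'
#' For each cell, the fraction of features deviating by more than two standard
#' deviations from the per-feature mean of the next measured timepoint's
#' cells; fractions below the 20% floor are set to 0 (such cells cannot be
#' killed by the prior).
#'
#' @param Z_t cells x d matrix of current states.
#' @param Z_next cells x d matrix of the next measured timepoint (>= 2 cells;
#'   the per-feature sd is undefined otherwise).
#' @param floor deviation-fraction floor below which the rate is 0.
#' @return per-cell rate vector in `[0, 1]`.
#' @export
prior_kill_rate <- function(Z_t, Z_next, floor = 0.2) {
  Z_t <- as.matrix(Z_t); Z_next <- as.matrix(Z_next)
  if (nrow(Z_next) < 2L)
    stopf("prior_kill_rate: need >= 2 cells at the next timepoint to define sd")
  mu <- colMeans(Z_next)
  sdv <- apply(Z_next, 2L, sd)
  prior_from_stats(Z_t, mu, sdv, floor)
}

prior_from_stats <- function(Z, mu, sdv, floor = 0.2) {
  sdv <- pmax(sdv, 1e-12)
  dev <- abs(sweep(Z, 2L, mu)) > sweep(matrix(1, nrow(Z), ncol(Z)), 2L, 2 * sdv, "*")
  frac <- rowMeans(dev)
  frac[frac < floor] <- 0
  frac
}

# per-timepoint latent summary used to evaluate the prior along the grid
latent_stats_new <- function(ensembles, timepoints) {
  list(timepoints = as.integer(timepoints),
       mean = lapply(ensembles, colMeans),
       sd = lapply(ensembles, function(Z) apply(Z, 2L, sd)),
       pooled_sd = mean(unlist(lapply(ensembles, function(Z) apply(Z, 2L, sd)))))
}

next_measured <- function(stats, t) {
  after <- which(stats$timepoints > t + 1e-9)
  if (length(after)) after[1L] else length(stats$timepoints)
}

#' Kill-rate field
#'
#' Bundles the data-derived prior kill rate (per measured timepoint latent
#' summaries), the learned modulation network `K_omega` (softplus output, so
#' the posterior rate `k * K` stays non-negative), and the birth rate `b`.
#'
#' @param stats per-timepoint latent summaries (means/sds), built internally
#'   from encoder outputs; see [prior_kill_rate()] for the prior rule.
#' @param b birth rate (negative death rate). Default 0; set to 1 when any
#'   measured count increases so K_omega can modulate both directions.
#' @param hidden hidden width of the modulation net.
#' @param tdim time-encoding dimension.
#' @param state_dependent also feed the latent state to the net (default
#'   time-only).
#' @param prior_floor deviation-fraction floor of the prior rule.
#' @param t_scale factor converting time to grid-step units for the net's
#'   sinusoidal time features (use `1/dt`).
#' @param seed initialisation seed.
#' @return object of class `sb_killfield`.
#' @export
killrate_field <- function(stats, b = 0, hidden = 16L, tdim = 8L,
                           state_dependent = FALSE, prior_floor = 0.2,
                           t_scale = 10, seed = 1L) {
  d_in <- tdim + if (state_dependent) length(stats$mean[[1L]]) else 0L
  net <- with_seed(seed, mlp_new(c(d_in, hidden, 1L), act = "tanh", zero_out = TRUE))
  structure(list(stats = stats, net = net, b = b, tdim = tdim,
                 state_dependent = state_dependent, prior_floor = prior_floor,
                 offset = 4, t_scale = t_scale,
                 jitter_sd = 0.05 * (stats$pooled_sd %||% 1)),
            class = "sb_killfield")
}

# Time enters in grid-step units (t * t_scale, with t_scale ~ 1/dt): the
# sinusoidal features then span many periods over [0, T], giving the net the
# resolution to localise the kill rate within single measured intervals.
killnet_input <- function(field, Z, t) {
  tf <- time_features(t * (field$t_scale %||% 1), nrow(Z), field$tdim)
  if (field$state_dependent) cbind(Z, tf) else tf
}

# K = softplus(raw - offset): the offset places the zero-initialised net at
# K ~ 0, so the untrained field is (near) the balanced reference process with
# no birth/death modulation, mirroring the zero-initialised drift nets.
killnet_K <- function(field, Z, t, keep_cache = FALSE) {
  X <- killnet_input(field, Z, t)
  off <- field$offset %||% 0
  if (keep_cache) {
    cache <- mlp_forward(field$net, X, keep_cache = TRUE)
    list(K = softplus(drop(cache$out) - off), raw = drop(cache$out) - off,
         cache = cache)
  } else {
    softplus(drop(mlp_forward(field$net, X)) - off)
  }
}

#' Birth/death transition probabilities
#'
#' Death: `clamp(k_prior(z, t) * K_omega(t) * dt)`; birth:
#' `clamp(b * K_omega(t) * dt)`, both clipped to the unit interval. The raw
#' (unclipped) values are also returned; their excess above 1 feeds the
#' regularisation terms of the population loss.
#'
#' @param field an `sb_killfield`.
#' @param Z cells x d states.
#' @param t scalar time.
#' @param dt step size.
#' @return `list(p_die, p_born, raw_die, raw_born)`; all per-cell vectors.
#' @export
transition_probs <- function(field, Z, t, dt) {
  Z <- as.matrix(Z)
  j <- next_measured(field$stats, t)
  kp <- prior_from_stats(Z, field$stats$mean[[j]], field$stats$sd[[j]], field$prior_floor)
  K <- killnet_K(field, Z, t)
  raw_die <- kp * K * dt
  raw_born <- rep_len(field$b * K * dt, nrow(Z))
  list(p_die = pmin(pmax(raw_die, 0), 1), p_born = pmin(pmax(raw_born, 0), 1),
       raw_die = raw_die, raw_born = raw_born, prior = kp, K = K)
}

#' Stochastic status update
#'
#' Each live cell dies with its death probability; each dead slot revives
#' with its birth probability. Returns the new binary status vector and an
#' event log (`cell`, `type`).
#'
#' @param A binary status vector (1 = live, 0 = dead).
#' @param p_die,p_born per-cell probabilities in `[0, 1]`.
#' @param seed RNG seed (`NULL`: ambient stream).
#' @export
update_statuses <- function(A, p_die, p_born, seed = NULL) {
  if (!all(A %in% c(0, 1))) stopf("statuses must be binary")
  n <- length(A)
  with_seed(seed, {
    u <- runif(n)
    die <- A == 1 & u < p_die
    born <- A == 0 & u < p_born
    A2 <- A
    A2[die] <- 0
    A2[born] <- 1
    events <- data.frame(cell = c(which(die), which(born)),
                         type = c(rep("death", sum(die)), rep("birth", sum(born))),
                         stringsAsFactors = FALSE)
    list(A = A2, events = events)
  })
}

# One simulation step of the birth/death mechanism: update statuses, place
# revived cells at a jittered copy of a uniformly chosen live cell (the
# cemetery state has no geometry, so re-entry copies the current marginal).
killer_step <- function(field, Z, A, t, dt) {
  tp <- transition_probs(field, Z, t, dt)
  up <- update_statuses(A, tp$p_die, tp$p_born)
  born <- up$events$cell[up$events$type == "birth"]
  live_src <- which(up$A == 1 & !(seq_along(up$A) %in% born))
  if (length(born)) {
    if (length(live_src)) {
      src <- live_src[sample.int(length(live_src), length(born), replace = TRUE)]
      Z[born, ] <- Z[src, , drop = FALSE] +
        matrix(rnorm(length(born) * ncol(Z), 0, field$jitter_sd), length(born), ncol(Z))
    } else {
      up$A[born] <- 0  # nothing to copy from; births void
      up$events <- up$events[up$events$type != "birth", , drop = FALSE]
    }
  }
  list(Z = Z, A = up$A, events = up$events, p_born_zero = all(tp$p_born == 0))
}

# ---- population target & loss --------------------------------------------

#' Population target from measured counts
#'
#' @param counts cells per measured timepoint (>= 1 each).
#' @param timepoints measured timepoint labels (default 0, 1, ...).
#' @return `list(counts, timepoints, intermediates, max_n)`; intermediate
#'   timepoints exclude t = 0.
#' @export
population_target <- function(counts, timepoints = seq_along(counts) - 1L) {
  if (any(counts < 1)) stopf("counts must be >= 1")
  list(counts = as.numeric(counts), timepoints = as.integer(timepoints),
       intermediates = as.integer(timepoints[-1L]), max_n = max(counts))
}

#' Empirical relative mass change up to a timepoint
#'
#' `(n_i - n_0) / max_i n_i` — the normalised change in observed cell numbers
#' that the accumulated birth/death probabilities must match.
#'
#' @param target a [population_target()].
#' @param i a measured intermediate timepoint.
#' @export
empirical_mass_change <- function(target, i) {
  j <- match(i, target$timepoints)
  if (is.na(j) || !(i %in% target$intermediates))
    stopf("timepoint %s is not a measured intermediate", i)
  (target$counts[j] - target$counts[1L]) / target$max_n
}

# shared evaluation of the discretized population loss; optionally with the
# per-node gradient wrt K_omega (statuses and states held fixed).
population_loss_eval <- function(field, path, target, want_grads = FALSE) {
  tg <- path$t_grid
  dt <- tg[2L] - tg[1L]
  S1 <- length(path$Z)
  n <- ncol(path$A)
  inter <- target$intermediates
  nodes <- round(inter / dt) + 1L
  if (any(abs((nodes - 1L) * dt - inter) > 1e-9))
    stopf("measured timepoints do not lie on the simulation grid")
  if (!length(inter)) {
    warnf("no intermediate timepoints; population loss is 0")
    return(list(value = 0, per_node = NULL))
  }
  # per-node ingredients
  contrib <- numeric(S1)       # mean over cells of (1-A) pb_clip - A pd_clip
  pen_die <- numeric(S1); pen_born <- numeric(S1)
  dcontrib <- numeric(S1)      # d contrib / d K at the node (straight-through)
  dpen <- numeric(S1)
  Ks <- numeric(S1)
  caches <- if (want_grads) vector("list", S1) else NULL
  for (i in seq_len(S1)) {
    Z <- path$Z[[i]]
    if (is.null(Z)) next
    a <- path$A[i, ]
    t <- tg[i]
    j <- next_measured(field$stats, t)
    kp <- prior_from_stats(Z, field$stats$mean[[j]], field$stats$sd[[j]], field$prior_floor)
    kk <- killnet_K(field, Z, t, keep_cache = want_grads)
    K <- if (want_grads) kk$K else kk
    if (want_grads) caches[[i]] <- kk
    raw_die <- kp * K * dt
    raw_born <- rep_len(field$b * K * dt, n)
    cd <- pmin(pmax(raw_die, 0), 1); cb <- pmin(pmax(raw_born, 0), 1)
    contrib[i] <- mean((1 - a) * cb - a * cd)
    pen_die[i] <- mean(raw_die - cd)
    pen_born[i] <- mean(raw_born - cb)
    if (want_grads) {
      in_die <- as.numeric(raw_die <= 1)   # straight-through through the clip
      in_born <- as.numeric(raw_born <= 1)
      dcontrib[i] <- mean((1 - a) * field$b * dt * in_born - a * kp * dt * in_die)
      dpen[i] <- mean(kp * dt * (1 - in_die)) + mean(field$b * dt * (1 - in_born))
    }
    Ks[i] <- mean(K)
  }
  value <- 0
  resid <- numeric(length(inter))
  for (q in seq_along(inter)) {
    rng <- seq_len(nodes[q])
    m <- sum(contrib[rng])
    c_i <- empirical_mass_change(target, inter[q])
    resid[q] <- m - c_i
    value <- value + abs(m - c_i) + sum(pen_die[rng]) + sum(pen_born[rng])
  }
  out <- list(value = value, resid = resid, contrib = contrib, K = Ks)
  if (want_grads) {
    # dL/dK at node i: mass terms for every intermediate whose window covers i,
    # plus the penalty multiplicity
    mult_pen <- vapply(seq_len(S1), function(i) sum(nodes >= i), 0)
    dK <- numeric(S1)
    for (q in seq_along(inter)) {
      rng <- seq_len(nodes[q])
      dK[rng] <- dK[rng] + sign(resid[q]) * dcontrib[rng]
    }
    dK <- dK + mult_pen * dpen
    grads <- NULL
    for (i in seq_len(S1)) {
      if (is.null(caches[[i]]) || dK[i] == 0) next
      kk <- caches[[i]]
      dout <- matrix(dK[i] / length(kk$raw) * plogis(kk$raw), ncol = 1L)
      g <- mlp_backward(field$net, kk$cache, dout)
      grads <- grads_add(grads, list(gW = g$gW, gb = g$gb))
    }
    out$grads <- grads
  }
  out
}

#' Population loss along a simulated path
#'
#' For each measured intermediate timepoint i, the absolute difference between
#' the accumulated predicted mass change (clipped birth probabilities of dead
#' slots minus clipped death probabilities of live cells, averaged over
#' cells and summed over grid steps up to i) and the empirical change
#' `(n_i - n_0)/max n`, plus the excess-probability penalties (raw minus
#' clipped) for both the death and birth terms.
#'
#' @param field an `sb_killfield`.
#' @param path a forward `sb_trajectory` with statuses.
#' @param target a [population_target()].
#' @return scalar loss.
#' @export
population_loss <- function(field, path, target) {
  if (path$direction != "forward") stopf("population_loss needs a forward path")
  population_loss_eval(field, path, target)$value
}

#' Train the kill-rate modulation network
#'
#' Repeatedly simulates the forward SDE with birth/death under the current
#' field, then takes an Adam step on the population loss with gradients
#' flowing only to the modulation net (statuses and states treated as fixed
#' per epoch; the clip uses a straight-through gradient).
#'
#' @param field an `sb_killfield`.
#' @param bridge an `sb_bridge`.
#' @param rho0 boundary latent sample to start forward paths from.
#' @param target a [population_target()].
#' @param epochs training epochs.
#' @param lr learning rate.
#' @param sim_cells cells per simulated path.
#' @param seed RNG seed.
#' @return `list(field, history)`.
#' @export
train_killrate <- function(field, bridge, rho0, target, epochs = 60L, lr = 5e-3,
                           sim_cells = 256L, seed = 1L) {
  st <- adam_new(field$net)
  hist <- numeric(epochs)
  for (e in seq_len(epochs)) {
    s <- derive_seed(seed, 7000L + e)
    idx <- with_seed(s, sample(nrow(rho0), min(sim_cells, nrow(rho0))))
    path <- bridge_simulate(bridge, rho0[idx, , drop = FALSE], "forward",
                            killer = field, seed = derive_seed(s, 1L))
    ev <- population_loss_eval(field, path, target, want_grads = TRUE)
    hist[e] <- ev$value
    if (!is.finite(ev$value)) stopf("non-finite population loss at epoch %d", e)
    if (!is.null(ev$grads)) {
      up <- adam_step(field$net, ev$grads, st, lr)
      field$net <- up$net; st <- up$state
    }
  }
  list(field = field, history = hist)
}
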