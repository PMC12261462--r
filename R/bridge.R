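# Diffusion Schrodinger bridge core: forward/backward drift networks,
# Euler-Maruyama path simulation on a uniform grid over [0, T], the
# divergence-based FB-SDE likelihood losses, and the iterative proportional
# fitting (IPF) alternating scheme.
#
# Drift networks have a single tanh hidden layer. This is deliberate: the
# likelihood loss contains the divergence of the drift, so training needs the
# parameter-gradient of a Jacobian trace. With one hidden layer both the
# divergence and its gradient have closed forms (see drift_divergence_*),
# avoiding second-order automatic differentiation entirely.

#' Create a bridge model
#'
#' Holds the forward drift network Q (approximating eps * grad log Psi), the
#' backward drift network Qhat, and the fixed constants: base drift `f`,
#' diffusion coefficient `eps`, and the uniform time grid. Drift output layers
#' are zero-initialised so the untrained bridge is the reference process
#' `dZ = f dt + eps dW`.
#'
#' @param d latent dimension.
#' @param T terminal time (the grid spans `[0, T]`).
#' @param eps diffusion coefficient (> 0). The single most
#'   performance-sensitive constant of the model.
#' @param f base drift: scalar or length-d vector (default 0).
#' @param n_steps number of Euler-Maruyama steps (>= 2; default 100).
#' @param hidden drift-network hidden width.
#' @param tdim sinusoidal time-encoding dimension for the drift nets.
#' @param seed parameter-initialisation seed.
#' @return object of class `sb_bridge`.
#' @export
bridge_new <- function(d, T, eps = 0.1, f = 0, n_steps = 100L, hidden = 32L,
                       tdim = 8L, seed = 1L) {
  if (eps < 0) stopf("eps must be >= 0 (0 is the degenerate deterministic case, usable for simulation only; training needs eps > 0)")
  if (n_steps < 2L) stopf("n_steps must be >= 2")
  if (T <= 0) stopf("T must be > 0")
  f <- rep_len(as.double(f), d)
  with_seed(seed, {
    fwd <- mlp_new(c(d + tdim, hidden, d), act = "tanh", zero_out = TRUE)
    bwd <- mlp_new(c(d + tdim, hidden, d), act = "tanh", zero_out = TRUE)
    structure(list(fwd = fwd, bwd = bwd, d = d, tdim = tdim, eps = eps, f = f,
                   n_steps = as.integer(n_steps), T = T, dt = T / n_steps,
                   t_grid = seq(0, T, length.out = n_steps + 1L)),
              class = "sb_bridge")
  })
}

drift_input <- function(Z, t, tdim) cbind(Z, time_features(t, nrow(Z), tdim))

#' Evaluate a drift network
#'
#' @param bridge an `sb_bridge`.
#' @param Z cells x d state matrix.
#' @param t scalar time in `[0, T]`.
#' @param direction `"forward"` for Q, `"backward"` for Qhat.
#' @return cells x d drift matrix; deterministic in (parameters, Z, t).
#' @export
drift <- function(bridge, Z, t, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  Z <- as.matrix(Z)
  if (ncol(Z) != bridge$d) stopf("expected latent dim %d, got %d", bridge$d, ncol(Z))
  net <- if (direction == "forward") bridge$fwd else bridge$bwd
  mlp_forward(net, drift_input(Z, t, bridge$tdim))
}

#' A drift network as a standalone vector field
#'
#' Wraps one of the bridge's drift networks (with its time input frozen at
#' `t`) as an object usable with [divergence()].
#' @param bridge an `sb_bridge`.
#' @param t scalar time.
#' @param direction which drift.
#' @export
drift_field <- function(bridge, t, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  net <- if (direction == "forward") bridge$fwd else bridge$bwd
  structure(list(net = net, t = t, tdim = bridge$tdim, d = bridge$d),
            class = "sb_driftfield")
}

# closed-form divergence of a one-hidden-layer tanh net wrt its state input
net_div_parts <- function(net, d) {
  W1z <- net$W[[1L]][seq_len(d), , drop = FALSE]   # d x H
  W2 <- net$W[[2L]]                                # H x d
  list(W1z = W1z, W2 = W2, s = rowSums(t(W1z) * W2))  # s_k = sum_j W1z[j,k] W2[k,j]
}

net_divergence <- function(net, Z, t, tdim) {
  d <- ncol(Z)
  parts <- net_div_parts(net, d)
  pre <- add_bias(drift_input(Z, t, tdim) %*% net$W[[1L]], net$b[[1L]])
  A <- tanh(pre)
  drop((1 - A^2) %*% parts$s)
}

net_jvp <- function(net, Z, t, tdim, v) {
  # J v where J = dQ/dz, for a fixed direction v (length d)
  d <- ncol(Z)
  parts <- net_div_parts(net, d)
  pre <- add_bias(drift_input(Z, t, tdim) %*% net$W[[1L]], net$b[[1L]])
  A <- tanh(pre)
  vW1 <- drop(v %*% parts$W1z)                     # length H
  ((1 - A^2) * matrix(vW1, nrow(Z), length(vW1), byrow = TRUE)) %*% parts$W2
}

#' Divergence of a vector field at a set of states
#'
#' Estimates `div Q(z) = sum_i dQ_i/dz_i` for each row of `Z`. For drift
#' networks ([drift_field()]) and linear fields (a d x d matrix `A`, the field
#' `z -> z A`), the `"exact"` branch is the closed-form Jacobian trace. The
#' `"hutchinson"` branch uses m probe directions: the coordinate basis
#' (exact) when `m >= d`, seeded Rademacher probes otherwise. Arbitrary R
#' functions `Z -> Q` are handled by central finite differences (`"fd"`).
#'
#' @param field an `sb_driftfield`, a d x d matrix, or a function.
#' @param Z cells x d state matrix.
#' @param method `"auto"` (exact when `d <= d_exact`, else Hutchinson),
#'   `"exact"`, `"hutchinson"`, or `"fd"`.
#' @param m number of Hutchinson probes.
#' @param d_exact dimension threshold for the auto switch.
#' @param seed probe seed.
#' @param h finite-difference step.
#' @return numeric vector, one divergence per row of `Z`.
#' @export
divergence <- function(field, Z, method = c("auto", "exact", "hutchinson", "fd"),
                       m = 8L, d_exact = 16L, seed = NULL, h = 1e-4) {
  method <- match.arg(method)
  Z <- as.matrix(Z)
  d <- ncol(Z)
  if (method == "auto") method <- if (d <= d_exact) "exact" else "hutchinson"

  if (is.function(field)) {
    if (method != "fd")
      method <- "fd"  # generic functions expose no Jacobian structure
    out <- numeric(nrow(Z))
    for (j in seq_len(d)) {
      E <- matrix(0, nrow(Z), d); E[, j] <- h
      out <- out + (field(Z + E)[, j] - field(Z - E)[, j]) / (2 * h)
    }
    return(out)
  }
  if (is.matrix(field)) {  # linear field z -> z %*% field
    if (method %in% c("exact", "fd")) return(rep(sum(diag(field)), nrow(Z)))
    pr <- hutch_probes(d, m, seed)
    est <- 0
    for (v in pr$probes) est <- est + sum(v * drop(field %*% v)) * pr$scale
    # field is state-independent: same value for every cell
    return(rep(est, nrow(Z)))
  }
  if (!inherits(field, "sb_driftfield")) stopf("unsupported field type")
  if (method %in% c("exact", "fd")) {
    if (method == "fd") {
      f <- function(ZZ) mlp_forward(field$net, drift_input(ZZ, field$t, field$tdim))
      return(divergence(f, Z, method = "fd", h = h))
    }
    return(net_divergence(field$net, Z, field$t, field$tdim))
  }
  pr <- hutch_probes(d, m, seed)
  est <- numeric(nrow(Z))
  for (v in pr$probes) {
    Jv <- net_jvp(field$net, Z, field$t, field$tdim, v)
    est <- est + drop(Jv %*% v) * pr$scale
  }
  est
}

# When m >= d the probe set collapses to the coordinate basis and the trace
# estimate is exact (sum over probes); otherwise seeded Rademacher probes with
# the usual 1/m average.
hutch_probes <- function(d, m, seed) {
  if (m >= d) {
    list(probes = lapply(seq_len(d), function(j) { v <- numeric(d); v[j] <- 1; v }),
         scale = 1)
  } else {
    list(probes = with_seed(seed, lapply(seq_len(m), function(.)
      sample(c(-1, 1), d, replace = TRUE))), scale = 1 / m)
  }
}

# ---- path simulation ------------------------------------------------------

#' Simulate a latent trajectory by Euler-Maruyama
#'
#' Forward: `dZ = [f + eps Q(Z, t)] dt + eps sqrt(dt) eta` from `Z0 ~ rho_0`
#' on the grid nodes `t_start .. T`. Backward: the time-reversed SDE
#' `dZ = [f - eps Qhat(Z, t)] dt + eps sqrt(dt) eta` started from `Z0 ~ rho_T`
#' and stepped down the grid. With a `killer` ([killrate_field()]), the
#' birth/death status update runs at every step: live cells die with the
#' death transition probability, dead slots revive at a jittered copy of a
#' random live cell, and all events are logged.
#'
#' @param bridge an `sb_bridge`.
#' @param Z0 starting cells x d matrix (boundary sample).
#' @param direction `"forward"` or `"backward"`.
#' @param killer optional `sb_killfield`.
#' @param seed RNG seed for the noise stream (and status updates).
#' @param t_start grid time to start a forward simulation from (default 0;
#'   must lie on the grid).
#' @return object of class `sb_trajectory`: `Z` (list of cells x d states per
#'   grid node), `A` ((n_steps+1) x cells status matrix), `events` data frame,
#'   `direction`, `t_grid`.
#' @export
bridge_simulate <- function(bridge, Z0, direction = c("forward", "backward"),
                            killer = NULL, seed = NULL, t_start = 0) {
  direction <- match.arg(direction)
  Z0 <- as.matrix(Z0)
  if (ncol(Z0) != bridge$d) stopf("expected latent dim %d, got %d", bridge$d, ncol(Z0))
  n <- nrow(Z0)
  S <- bridge$n_steps
  dt <- bridge$dt
  i_start <- round(t_start / dt)
  if (abs(i_start * dt - t_start) > 1e-9) stopf("t_start %g is not on the grid", t_start)

  Zs <- vector("list", S + 1L)
  A <- matrix(NA_real_, S + 1L, n)
  events <- list()
  with_seed(seed, {
    if (direction == "forward") {
      Z <- Z0; a <- rep(1, n)
      Zs[[i_start + 1L]] <- Z; A[i_start + 1L, ] <- a
      if (i_start < S) for (i in i_start:(S - 1L)) {
        t <- bridge$t_grid[i + 1L]
        if (!is.null(killer)) {
          up <- killer_step(killer, Z, a, t, dt)
          a <- up$A; Z <- up$Z
          if (nrow(up$events)) events[[length(events) + 1L]] <-
            cbind(step = i, up$events)
          if (all(a == 0) && up$p_born_zero) {
            warnf("all cells dead at step %d with zero birth probability; stopping path early", i)
            for (j in (i + 1L):S) { Zs[[j + 1L]] <- Z; A[j + 1L, ] <- a }
            break
          }
        }
        live <- a == 1
        Q <- drift(bridge, Z, t, "forward")
        step_mat <- sweep(bridge$eps * Q * dt, 2L, bridge$f * dt, "+") +
          bridge$eps * sqrt(dt) * matrix(rnorm(n * bridge$d), n, bridge$d)
        Z[live, ] <- Z[live, , drop = FALSE] + step_mat[live, , drop = FALSE]
        if (any(!is.finite(Z))) stopf("non-finite state at step %d", i + 1L)
        Zs[[i + 2L]] <- Z; A[i + 2L, ] <- a
      }
    } else {
      Z <- Z0; a <- rep(1, n)
      Zs[[S + 1L]] <- Z; A[S + 1L, ] <- a
      for (i in S:1L) {
        t <- bridge$t_grid[i + 1L]
        if (!is.null(killer)) {
          up <- killer_step(killer, Z, a, t, dt)
          a <- up$A; Z <- up$Z
          if (nrow(up$events)) events[[length(events) + 1L]] <-
            cbind(step = i, up$events)
        }
        live <- a == 1
        Qh <- drift(bridge, Z, t, "backward")
        # stepping down the grid (t decreasing), the backward SDE's drift
        # [f - eps Qhat] dt enters with dt < 0: the state update is
        # (eps Qhat - f) |dt|, the time reversal of the forward update
        step_mat <- sweep(bridge$eps * Qh * dt, 2L, -bridge$f * dt, "+") +
          bridge$eps * sqrt(dt) * matrix(rnorm(n * bridge$d), n, bridge$d)
        Z[live, ] <- Z[live, , drop = FALSE] + step_mat[live, , drop = FALSE]
        if (any(!is.finite(Z))) stopf("non-finite state at step %d", i - 1L)
        Zs[[i]] <- Z; A[i, ] <- a
      }
    }
  })
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(step = integer(0), cell = integer(0), type = character(0))
  structure(list(Z = Zs, A = A, events = ev, direction = direction,
                 t_grid = bridge$t_grid, i_start = i_start, seed = seed),
            class = "sb_trajectory")
}

#' @method print sb_trajectory
#' @export
print.sb_trajectory <- function(x, ...) {
  n <- ncol(x$A)
  cat(sprintf("<sb_trajectory> %s, %d cells, %d grid nodes, %d birth/death events\n",
              x$direction, n, length(x$Z), nrow(x$events)))
  invisible(x)
}

# ---- divergence losses ----------------------------------------------------

# One pass of the FB-SDE likelihood: value of
#   dt * sum_i sum_cells A_i * (1/2 |Q|^2 + eps div Q + <Q, Qother>)
# over the populated grid nodes of `path`, where Q is the `train` net and
# Qother the frozen opposite net; optionally also its parameter gradients.
div_loss_pass <- function(bridge, path, train = c("forward", "backward"),
                          want_grads = FALSE) {
  train <- match.arg(train)
  net <- if (train == "forward") bridge$fwd else bridge$bwd
  other <- if (train == "forward") bridge$bwd else bridge$fwd
  d <- bridge$d; dt <- bridge$dt
  parts <- net_div_parts(net, d)
  value <- 0
  grads <- NULL
  for (i in seq_along(path$Z)) {
    Z <- path$Z[[i]]
    if (is.null(Z)) next
    a <- path$A[i, ]
    t <- path$t_grid[i]
    Xin <- drift_input(Z, t, bridge$tdim)
    cache <- mlp_forward(net, Xin, keep_cache = TRUE)
    Q <- cache$out
    Qo <- mlp_forward(other, Xin)
    H <- cache$post[[1L]]                 # tanh activations
    divQ <- drop((1 - H^2) %*% parts$s)
    w <- a * dt
    value <- value + sum(w * (0.5 * rowSums(Q^2) + bridge$eps * divQ + rowSums(Q * Qo)))
    if (want_grads) {
      dQ <- (Q + Qo) * w
      g1 <- mlp_backward(net, cache, dQ)
      u <- w * bridge$eps
      ds <- colSums(u * (1 - H^2))                         # dL/ds_k
      gW2_div <- t(parts$W1z) * ds                          # H x d, rows scaled
      gW1_div <- matrix(0, nrow(net$W[[1L]]), ncol(net$W[[1L]]))
      gW1_div[seq_len(d), ] <- sweep(t(parts$W2), 2L, ds, "*")
      dPre <- (-2 * H * (1 - H^2)) * (u %o% parts$s)
      gW1_div <- gW1_div + crossprod(Xin, dPre)
      gb1_div <- colSums(dPre)
      g <- list(gW = list(g1$gW[[1L]] + gW1_div, g1$gW[[2L]] + gW2_div),
                gb = list(g1$gb[[1L]] + gb1_div, g1$gb[[2L]]))
      grads <- grads_add(grads, g)
    }
  }
  list(value = value, grads = grads)
}

#' Likelihood loss for the forward drift
#'
#' `dt * sum_i A_i (1/2 |Q_theta|^2 + eps div Q_theta + <Q_theta, Qhat>)`
#' evaluated along a backward-simulated path; dead cells (status 0)
#' contribute nothing. Gradients (used internally by [ipf_round()]) flow only
#' to the forward net.
#'
#' @param bridge an `sb_bridge`.
#' @param path an `sb_trajectory` with `direction == "backward"`.
#' @return scalar loss.
#' @export
loss_div_forward <- function(bridge, path) {
  if (path$direction != "backward")
    stopf("loss_div_forward needs a backward-simulated path")
  div_loss_pass(bridge, path, "forward")$value
}

#' Likelihood loss for the backward drift
#'
#' Mirror of [loss_div_forward()]: evaluated along a forward-simulated path,
#' training Qhat with Q frozen.
#'
#' @param bridge an `sb_bridge`.
#' @param path an `sb_trajectory` with `direction == "forward"`.
#' @return scalar loss.
#' @export
loss_div_backward <- function(bridge, path) {
  if (path$direction != "forward")
    stopf("loss_div_backward needs a forward-simulated path")
  div_loss_pass(bridge, path, "backward")$value
}

# ---- IPF ------------------------------------------------------------------

#' One round of iterative proportional fitting
#'
#' A round is (i) a forward pass: simulate the backward SDE from `rhoT` and
#' minimise the forward-drift likelihood loss; then (ii) a backward pass:
#' simulate the forward SDE from `rho0` and minimise the backward-drift loss.
#' Paths are re-simulated with fresh noise at every inner optimisation step,
#' and the opposite drift is frozen within each pass. Boundary-matching
#' diagnostics (W2 between the simulated and target boundary samples) are
#' computed after the round.
#'
#' @param bridge an `sb_bridge`.
#' @param rho0,rhoT samples (matrices) from the boundary distributions.
#' @param inner_steps Adam steps per pass.
#' @param lr learning rate.
#' @param sim_cells cells simulated per inner step (subsampled from the
#'   boundary sample).
#' @param killer optional `sb_killfield` applied during forward simulation.
#' @param seed RNG seed.
#' @param rounds number of rounds to run (0 returns the model unchanged).
#' @return `list(bridge, diagnostics)` where diagnostics is a data frame with
#'   one row per round: the two boundary W2s and the final pass losses.
#' @export
ipf_round <- function(bridge, rho0, rhoT, rounds = 1L, inner_steps = 150L,
                      lr = 1e-2, sim_cells = 256L, killer = NULL, seed = 1L) {
  rho0 <- as.matrix(rho0); rhoT <- as.matrix(rhoT)
  diag_rows <- list()
  if (rounds < 1L)
    return(list(bridge = bridge, diagnostics = data.frame()))
  for (r in seq_len(rounds)) {
    # forward pass: train theta on backward simulations
    st <- adam_new(bridge$fwd)
    loss_f <- NA_real_
    for (e in seq_len(inner_steps)) {
      s <- derive_seed(seed, r * 100000L + e)
      idx <- with_seed(s, sample(nrow(rhoT), min(sim_cells, nrow(rhoT))))
      path <- bridge_simulate(bridge, rhoT[idx, , drop = FALSE], "backward",
                              seed = derive_seed(s, 1L))
      pass <- div_loss_pass(bridge, path, "forward", want_grads = TRUE)
      if (!is.finite(pass$value)) stopf("diverging forward-pass loss at round %d", r)
      up <- adam_step(bridge$fwd, pass$grads, st, lr)
      bridge$fwd <- up$net; st <- up$state
      loss_f <- pass$value
    }
    # backward pass: train theta-hat on forward simulations
    st <- adam_new(bridge$bwd)
    loss_b <- NA_real_
    for (e in seq_len(inner_steps)) {
      s <- derive_seed(seed, r * 100000L + 50000L + e)
      idx <- with_seed(s, sample(nrow(rho0), min(sim_cells, nrow(rho0))))
      path <- bridge_simulate(bridge, rho0[idx, , drop = FALSE], "forward",
                              killer = killer, seed = derive_seed(s, 1L))
      pass <- div_loss_pass(bridge, path, "backward", want_grads = TRUE)
      if (!is.finite(pass$value)) stopf("diverging backward-pass loss at round %d", r)
      up <- adam_step(bridge$bwd, pass$grads, st, lr)
      bridge$bwd <- up$net; st <- up$state
      loss_b <- pass$value
    }
    diag_rows[[r]] <- cbind(round = r, bridge_boundary_diag(
      bridge, rho0, rhoT, killer = killer, seed = derive_seed(seed, 999L + r)),
      loss_fwd = loss_f, loss_bwd = loss_b)
  }
  list(bridge = bridge, diagnostics = do.call(rbind, diag_rows))
}

bridge_boundary_diag <- function(bridge, rho0, rhoT, killer = NULL, seed = NULL,
                                 max_cells = 512L) {
  i0 <- with_seed(seed, sample(nrow(rho0), min(max_cells, nrow(rho0))))
  iT <- with_seed(derive_seed(seed %||% 0L, 2L), sample(nrow(rhoT), min(max_cells, nrow(rhoT))))
  pf <- bridge_simulate(bridge, rho0[i0, , drop = FALSE], "forward",
                        killer = killer, seed = derive_seed(seed %||% 0L, 3L))
  pb <- bridge_simulate(bridge, rhoT[iT, , drop = FALSE], "backward",
                        seed = derive_seed(seed %||% 0L, 4L))
  ZT <- pf$Z[[length(pf$Z)]][pf$A[nrow(pf$A), ] == 1, , drop = FALSE]
  Z0 <- pb$Z[[1L]]
  data.frame(w2_terminal = as.numeric(w2_distance(ZT, rhoT)),
             w2_initial = as.numeric(w2_distance(Z0, rho0)))
}
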