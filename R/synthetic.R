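# Synthetic time-series single-cell data with known latent SDE dynamics,
# known birth/death schedule and a known latent -> gene map. Every downstream
# stage (VAE, bridge, kill-rate network, drift-gene ranking, perturbation) is
# testable against this ground truth without any external dataset.

#' Latent drift field of the synthetic generator
#'
#' @param drift_spec `"linear"` (constant velocity along coordinate 1),
#'   `"bistable"` (double-well relaxation of coordinate 1 to -1/+1), or
#'   `"branching"` (constant forward motion along coordinate 1 while
#'   coordinate 2 splits into two wells, a two-branch trajectory).
#' @param d latent dimension.
#' @param drift_scale magnitude of the deterministic motion per unit time.
#' @return a function `b(Z, t)` mapping an n x d state matrix to an n x d
#'   drift matrix.
#' @export
synthetic_drift <- function(drift_spec = c("linear", "bistable", "branching"),
                            d = 2L, drift_scale = 1.5) {
  drift_spec <- match.arg(drift_spec)
  force(d); force(drift_scale)
  switch(drift_spec,
    linear = function(Z, t) {
      B <- matrix(0, nrow(Z), d); B[, 1L] <- drift_scale; B
    },
    bistable = function(Z, t) {
      B <- matrix(0, nrow(Z), d)
      B[, 1L] <- drift_scale * Z[, 1L] * (1 - Z[, 1L]^2)
      B
    },
    branching = function(Z, t) {
      B <- matrix(0, nrow(Z), d)
      B[, 1L] <- drift_scale
      if (d >= 2L) B[, 2L] <- drift_scale * Z[, 2L] * (1 - Z[, 2L]^2)
      B
    })
}

em_paths <- function(b, Z0, t_end, dt, noise, keep_every = Inf) {
  # Euler-Maruyama integration of dz = b(z,t) dt + noise dW from 0 to t_end.
  n_steps <- max(0L, round(t_end / dt))
  Z <- Z0
  kept <- if (is.finite(keep_every)) list(Z0) else NULL
  if (n_steps > 0L) for (s in seq_len(n_steps)) {
    t <- (s - 1L) * dt
    Z <- Z + b(Z, t) * dt +
      noise * sqrt(dt) * matrix(rnorm(length(Z)), nrow(Z), ncol(Z))
    if (is.finite(keep_every) && s %% keep_every == 0L) kept[[length(kept) + 1L]] <- Z
  }
  list(Z = Z, path = kept)
}

#' Simulate time-series single-cell expression with known truth
#'
#' Cells follow the latent SDE `dz = b(z,t) dt + noise dW` from a common
#' N(0, 0.3^2 I) start; each measured timepoint is an independent cohort
#' (destructive sampling, as in sequencing). Expression is
#' `softplus(Z %*% loading + intercept + gene noise)`: non-negative and on the
#' scale of log-normalised data. The first `n_driver` genes load on the
#' drifting coordinate (the planted "driver" genes); the remaining genes load
#' on the non-drifting coordinates.
#'
#' With a `death_window = list(from, to, rate)`, cells whose drifting
#' coordinate lies in the lagging half of the cohort are killed at `rate` per
#' unit time inside the window; cohort sizes are inflated by a Monte-Carlo
#' estimate of the survival probability so the realised number of emitted
#' cells matches `counts` in expectation (exactly when there is no killing).
#'
#' @param d latent dimension (>= 2 for branching).
#' @param g gene count.
#' @param T last timepoint (integer; timepoints are 0..T).
#' @param counts integer vector of length T+1, target cells per timepoint.
#' @param drift_spec see [synthetic_drift()].
#' @param death_window optional `list(from=, to=, rate=)`.
#' @param noise latent diffusion coefficient.
#' @param drift_scale deterministic motion per unit time.
#' @param n_driver number of genes loading on the drifting coordinate.
#' @param gene_noise sd of per-gene Gaussian noise before the softplus.
#' @param dt fine integration step.
#' @param seed integer; the output is bit-identical for equal seeds.
#' @return `list(data = sc_timeseries, truth = sb_synthetic_truth)`; the truth
#'   carries the drift function, loading matrix, driver-gene indices, realised
#'   counts, survival estimates and terminal latent states.
#' @export
simulate_timeseries <- function(d = 2L, g = 50L, T = 4L, counts = rep(300L, T + 1L),
                                drift_spec = "linear", death_window = NULL,
                                noise = 0.2, drift_scale = 1.5, n_driver = 5L,
                                gene_noise = 0.1, dt = 0.02, seed = 1L) {
  if (length(counts) != T + 1L) stopf("counts must have length T+1 = %d", T + 1L)
  if (any(counts < 1L)) stopf("counts must all be >= 1")
  if (!is.null(death_window)) {
    if (!all(c("from", "to", "rate") %in% names(death_window)))
      stopf("death_window needs fields from, to, rate")
    # a pure-death schedule cannot produce growth inside its own window
    inside <- seq(0L, T - 1L) >= death_window$from & (seq(1L, T)) <= death_window$to
    if (death_window$rate > 0 && any(diff(counts)[inside] > 0))
      stopf("counts grow inside the death window, but the schedule is pure death")
  }
  with_seed(seed, {
    b <- synthetic_drift(drift_spec, d = d, drift_scale = drift_scale)

    # latent -> gene map: drivers on coordinate 1, the rest on coords 2..d
    L <- matrix(0, d, g)
    drv <- seq_len(min(n_driver, g))
    L[1L, drv] <- runif(length(drv), 1.2, 1.8)
    if (d >= 2L && g > length(drv)) {
      rest <- setdiff(seq_len(g), drv)
      for (j in rest) {
        k <- if (d == 2L) 2L else sample(2:d, 1L)
        L[k, j] <- rnorm(1L, 0, 0.8)
      }
    }
    intercept <- runif(g, 0.5, 1.5)

    kill_cfg <- death_window
    survival <- rep(1, T + 1L)
    if (!is.null(kill_cfg) && kill_cfg$rate > 0) {
      # probe pass: estimate survival probability to each measured timepoint
      n_probe <- 400L
      surv_hits <- matrix(0, n_probe, T + 1L); surv_hits[, 1L] <- 1
      Zp <- matrix(rnorm(n_probe * d, 0, 0.3), n_probe, d)
      alive <- rep(TRUE, n_probe)
      n_fine <- round(T / dt)
      for (s in seq_len(n_fine)) {
        t <- (s - 1L) * dt
        Zp[alive, ] <- Zp[alive, , drop = FALSE] + b(Zp[alive, , drop = FALSE], t) * dt +
          noise * sqrt(dt) * matrix(rnorm(sum(alive) * d), sum(alive), d)
        if (t >= kill_cfg$from && t < kill_cfg$to && any(alive)) {
          lag <- Zp[, 1L] < median(Zp[alive, 1L])
          p <- 1 - exp(-kill_cfg$rate * dt)
          die <- alive & lag & (runif(n_probe) < p)
          alive[die] <- FALSE
        }
        tp <- floor(t + dt + 1e-9)
        if (abs((s * dt) - round(s * dt)) < 1e-9 && round(s * dt) <= T)
          surv_hits[alive, round(s * dt) + 1L] <- 1
      }
      survival <- pmax(colMeans(surv_hits), 0.05)
    }

    mats <- vector("list", T + 1L)
    ids <- vector("list", T + 1L)
    latents <- vector("list", T + 1L)
    realized <- integer(T + 1L)
    terminal_paths <- NULL
    for (tp in 0:T) {
      margin <- if (survival[tp + 1L] < 1) 1.15 else 1  # over-provision, then subsample
      n_start <- max(1L, round(margin * counts[tp + 1L] / survival[tp + 1L]))
      Z <- matrix(rnorm(n_start * d, 0, 0.3), n_start, d)
      alive <- rep(TRUE, n_start)
      keep_path <- (tp == T)
      path <- if (keep_path) list(Z) else NULL
      n_fine <- round(tp / dt)
      if (n_fine > 0L) for (s in seq_len(n_fine)) {
        t <- (s - 1L) * dt
        Z[alive, ] <- Z[alive, , drop = FALSE] + b(Z[alive, , drop = FALSE], t) * dt +
          noise * sqrt(dt) * matrix(rnorm(sum(alive) * d), sum(alive), d)
        if (!is.null(kill_cfg) && kill_cfg$rate > 0 &&
            t >= kill_cfg$from && t < kill_cfg$to && any(alive)) {
          lag <- Z[, 1L] < median(Z[alive, 1L])
          die <- alive & lag & (runif(n_start) < 1 - exp(-kill_cfg$rate * dt))
          alive[die] <- FALSE
        }
        if (keep_path && s %% 5L == 0L) path[[length(path) + 1L]] <- Z
      }
      Zs <- Z[alive, , drop = FALSE]
      # sequencing draws a fixed number of cells from the surviving
      # population: subsample down to the requested cohort size (fewer only
      # if the death schedule left too few survivors)
      if (nrow(Zs) > counts[tp + 1L]) {
        keep_rows <- sample(nrow(Zs), counts[tp + 1L])
        Zs <- Zs[keep_rows, , drop = FALSE]
        if (keep_path) path <- lapply(path, function(P) P) # paths filtered below
      } else keep_rows <- seq_len(nrow(Zs))
      realized[tp + 1L] <- nrow(Zs)
      if (nrow(Zs) == 0L) stopf("death schedule killed every cell at timepoint %d", tp)
      X <- softplus(Zs %*% L + matrix(intercept, nrow(Zs), g, byrow = TRUE) +
                    matrix(rnorm(nrow(Zs) * g, 0, gene_noise), nrow(Zs), g))
      colnames(X) <- paste0("gene", seq_len(g))
      mats[[tp + 1L]] <- X
      ids[[tp + 1L]] <- paste0("t", tp, "_cell", seq_len(nrow(X)))
      latents[[tp + 1L]] <- Zs
      if (keep_path)
        terminal_paths <- lapply(path, function(P)
          P[alive, , drop = FALSE][keep_rows, , drop = FALSE])
    }
    data <- timeseries(mats, 0:T, paste0("gene", seq_len(g)), ids,
                       meta = list(source = "synthetic", drift_spec = drift_spec,
                                   seed = seed))
    truth <- structure(
      list(drift = b, drift_spec = drift_spec, drift_scale = drift_scale,
           loading = L, intercept = intercept, gene_noise = gene_noise,
           driver_genes = drv, counts = counts, realized_counts = realized,
           survival = survival, latents = latents, latent_paths = terminal_paths,
           death_window = death_window, noise = noise, seed = seed),
      class = "sb_synthetic_truth")
    list(data = data, truth = truth)
  })
}

#' Hold out timepoints for evaluation
#'
#' Removes the held-out timepoints from the training object (they stay absent
#' from `timepoints`/`matrices`) and returns them in a companion evaluation
#' store for later scoring. Boundary timepoints 0 and T cannot be held out:
#' the bridge needs both boundary marginals.
#'
#' @param data `sc_timeseries`.
#' @param holdout integer vector of timepoints to withhold.
#' @return `list(train = sc_timeseries, eval_store = list(timepoints, matrices,
#'   cell_ids))`.
#' @export
heldout_split <- function(data, holdout) {
  validate_timeseries(data)
  holdout <- as.integer(holdout)
  Tmax <- max(data$timepoints)
  if (any(holdout %in% c(0L, Tmax)))
    stopf("cannot hold out boundary timepoints (0 or %d)", Tmax)
  if (!all(holdout %in% data$timepoints))
    stopf("holdout timepoints not present: %s",
          paste(setdiff(holdout, data$timepoints), collapse = ", "))
  keep <- !(data$timepoints %in% holdout)
  eval_store <- list(timepoints = data$timepoints[!keep],
                     matrices = data$matrices[!keep],
                     cell_ids = data$cell_ids[!keep])
  data$matrices <- data$matrices[keep]
  data$cell_ids <- data$cell_ids[keep]
  data$timepoints <- data$timepoints[keep]
  data$meta$holdout <- holdout
  list(train = data, eval_store = eval_store)
}
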