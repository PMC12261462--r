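# Shared fixtures. Heavy trained models are built once per test run and
# memoised; everything is generated in code from fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small raw-count time series for IO / preprocessing tests
toy_counts_ts <- function(n_per_tp = 8L, g = 6L, tps = 0:2, seed = 1L) {
  set.seed(seed)
  mats <- lapply(tps, function(t)
    matrix(rpois(n_per_tp * g, lambda = 5 + t), n_per_tp, g,
           dimnames = list(NULL, paste0("g", seq_len(g)))))
  timeseries(mats, tps)
}

# brute-force W2 for |A| = |B| <= 7 by enumerating all permutations
perms_of <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

w2_bruteforce <- function(A, B) {
  n <- nrow(A)
  D <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(min(vapply(perms_of(seq_len(n)), function(p)
    mean(D[cbind(seq_len(n), p)]), 0)))
}

# a VAE whose encoder emits exactly (mu = mu0, sigma = 1) for every cell
constant_encoder_vae <- function(g = 6L, d = 2L, mu0 = 0) {
  v <- vae_new(g, d = d, hidden = c(4L), tdim = 4L, seed = 1L, zero_out = TRUE)
  L <- length(v$encoder$b)
  v$encoder$b[[L]][seq_len(d)] <- mu0
  v$encoder$b[[L]][d + seq_len(d)] <- log(exp(1) - 1)  # softplus^-1(1)
  v
}

# bridge whose forward drift is the constant vector cvec (divergence 0)
constant_drift_bridge <- function(d, cvec, T = 1, eps = 0.5, n_steps = 10L) {
  br <- bridge_new(d, T = T, eps = eps, n_steps = n_steps, seed = 1L)
  br$fwd$b[[2L]] <- rep_len(cvec, d)
  br
}

# ---- memoised trained models ---------------------------------------------

# 1-d two-Gaussian bridge task: N(-2, 0.1) -> N(2, 0.1)
toy_ipf <- function() memo("toy_ipf", function() {
  rho0 <- with_seed_test(101L, matrix(rnorm(500, -2, 0.1), ncol = 1L))
  rhoT <- with_seed_test(102L, matrix(rnorm(500, 2, 0.1), ncol = 1L))
  br <- bridge_new(d = 1L, T = 1, eps = 0.5, n_steps = 20L, seed = 1L)
  d0 <- scbridge:::bridge_boundary_diag(br, rho0, rhoT, seed = 9L)
  res <- ipf_round(br, rho0, rhoT, rounds = 5L, inner_steps = 150L, lr = 1e-2,
                   sim_cells = 256L, seed = 2L)
  list(rho0 = rho0, rhoT = rhoT, round0 = d0, result = res)
})

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# branching synthetic system, middle timepoint held out, full fit
shared_fit <- function() memo("shared_fit", function() {
  sim <- simulate_timeseries(d = 2L, g = 50L, T = 4L, counts = rep(300L, 5L),
                             drift_spec = "branching", seed = 11L)
  hs <- heldout_split(sim$data, 2L)
  cfg <- scbridge_config(d = 8L, vae_hidden = c(64L, 64L), tdim = 8L,
                         n_steps = 40L, rounds = 4L, vae_epochs = 80L,
                         inner_steps = 70L, kill_epochs = 0L, population = FALSE,
                         sim_cells = 192L, replicates = 3L, seed = 5L)
  list(sim = sim, train = hs$train, eval_store = hs$eval_store,
       fit = scbridge(hs$train, cfg))
})

# linear drift with a mid-trajectory death window, full fit with kill rates
pop_fit <- function() memo("pop_fit", function() {
  counts <- c(300L, 300L, 200L, 150L, 150L)
  sim <- simulate_timeseries(d = 2L, g = 50L, T = 4L, counts = counts,
                             drift_spec = "linear",
                             death_window = list(from = 1, to = 3, rate = 1.2),
                             seed = 21L)
  cfg <- scbridge_config(d = 4L, vae_hidden = c(64L, 64L), tdim = 8L,
                         n_steps = 40L, rounds = 3L, vae_epochs = 80L,
                         inner_steps = 60L, kill_epochs = 120L, lr_kill = 1e-2,
                         population = TRUE, sim_cells = 192L, seed = 21L)
  list(sim = sim, counts = counts, fit = scbridge(sim$data, cfg))
})

# a hand-built fit with a purely linear decoder and constant forward drift,
# for which the drift-gene projection has a closed form
linear_toy_fit <- function(W, q, d = 2L, g = 4L, T = 1, n_steps = 10L) {
  v <- vae_new(g, d = d, hidden = integer(0), tdim = 4L, zero_out = TRUE)
  v$decoder$W[[1L]][seq_len(d), ] <- W          # genes respond linearly to z
  br <- bridge_new(d, T = T, eps = 0.5, n_steps = n_steps, seed = 1L)
  br$fwd$b[[2L]] <- q                            # constant latent drift
  data <- timeseries(list(matrix(0, 5, g)), 0L, paste0("g", seq_len(g)))
  structure(list(vae = v, bridge = br, killfield = NULL,
                 ensembles = list(matrix(rnorm(10 * d), 10, d)),
                 data = data, config = scbridge_config(seed = 1L)),
            class = "scbridge")
}

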