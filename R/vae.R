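# Time-conditioned variational autoencoder.
#
# Encoder q(x||t) -> (mu, sigma) and decoder p(z||t) -> x_hat, both
# conditioned on a sinusoidal encoding of time so unmeasured (fractional)
# times are valid inputs. sigma is parameterised through a softplus for
# positivity; the latent is diagonal-Gaussian per dimension. Trained by
# minimising MSE(X, X_hat) + beta * KL(q || N(0, I)).

#' Create a time-conditioned VAE
#'
#' @param g number of genes (input dimension).
#' @param d latent dimension (must satisfy d < g).
#' @param hidden integer vector of hidden-layer widths shared by encoder and
#'   decoder; `integer(0)` gives purely linear maps (useful for closed-form
#'   checks).
#' @param tdim sinusoidal time-encoding dimension (even).
#' @param beta KL weight.
#' @param act hidden activation.
#' @param seed parameter-initialisation seed.
#' @param zero_out zero the output layers (mu = 0, sigma = softplus(0),
#'   constant decoder) — mainly for tests.
#' @return object of class `sb_vae`.
#' @export
vae_new <- function(g, d = 16L, hidden = c(128L, 128L), tdim = 16L, beta = 0.01,
                    act = "silu", seed = 1L, zero_out = FALSE) {
  if (d >= g) stopf("latent dimension d = %d must be < g = %d", d, g)
  if (beta < 0) stopf("beta must be >= 0")
  with_seed(seed, {
    enc <- mlp_new(c(g + tdim, hidden, 2L * d), act = act, zero_out = zero_out)
    dec <- mlp_new(c(d + tdim, hidden, g), act = act, zero_out = zero_out)
    structure(list(encoder = enc, decoder = dec, g = g, d = d, tdim = tdim,
                   beta = beta, act = act),
              class = "sb_vae")
  })
}

time_features <- function(t, n, tdim) {
  matrix(sinusoidal_encode(t, tdim), n, tdim, byrow = TRUE)
}

#' Encode expression to the latent posterior
#'
#' @param vae an `sb_vae`.
#' @param X cells x genes matrix on the training gene axis.
#' @param t scalar time (any real; unmeasured times are valid).
#' @return `list(mu, sigma)`, both cells x d; `sigma > 0` elementwise.
#' @export
vae_encode <- function(vae, X, t) {
  X <- as.matrix(X)
  if (ncol(X) != vae$g) stopf("expected %d genes, got %d", vae$g, ncol(X))
  out <- mlp_forward(vae$encoder, cbind(X, time_features(t, nrow(X), vae$tdim)))
  d <- vae$d
  list(mu = out[, seq_len(d), drop = FALSE],
       sigma = softplus(out[, d + seq_len(d), drop = FALSE]))
}

#' Reparameterised latent sample
#'
#' Draws `z = mu + sigma * eta`, `eta ~ N(0, I)`. With `noise` supplied the
#' draw is deterministic (`noise = 0` gives `z = mu`).
#'
#' @param enc output of [vae_encode()].
#' @param seed RNG seed (ignored when `noise` is given).
#' @param noise optional matrix (or scalar) of standard-normal draws.
#' @export
vae_sample_latent <- function(enc, seed = NULL, noise = NULL) {
  if (is.null(noise)) {
    noise <- with_seed(seed, matrix(rnorm(length(enc$mu)), nrow(enc$mu), ncol(enc$mu)))
  }
  enc$mu + enc$sigma * noise
}

#' Decode latents to expression
#'
#' @param vae an `sb_vae`.
#' @param Z cells x d latent matrix.
#' @param t scalar time.
#' @return cells x genes reconstruction.
#' @export
vae_decode <- function(vae, Z, t) {
  Z <- as.matrix(Z)
  if (ncol(Z) != vae$d) stopf("expected latent dim %d, got %d", vae$d, ncol(Z))
  mlp_forward(vae$decoder, cbind(Z, time_features(t, nrow(Z), vae$tdim)))
}

# closed-form KL(N(mu, sigma^2) || N(0, I)), summed over dims, averaged over cells
kl_gaussian <- function(mu, sigma) {
  mean(rowSums(0.5 * (mu^2 + sigma^2 - 1 - 2 * log(sigma))))
}

#' VAE loss (reconstruction + KL)
#'
#' `MSE(X, X_hat) + beta * KL(q(z|x) || N(0, I))` with the KL in closed form
#' for diagonal Gaussians; MSE is the mean over all matrix entries and KL the
#' per-cell mean of the summed per-dimension divergences.
#'
#' @param vae an `sb_vae`.
#' @param X cells x genes matrix.
#' @param t scalar time.
#' @param beta KL weight (default: the model's).
#' @param noise optional reparameterisation noise (for deterministic checks).
#' @param seed RNG seed for the reparameterisation draw.
#' @return `list(total, mse, kl)`.
#' @export
vae_loss <- function(vae, X, t, beta = vae$beta, noise = NULL, seed = NULL) {
  if (beta < 0) stopf("beta must be >= 0")
  enc <- vae_encode(vae, X, t)
  Z <- vae_sample_latent(enc, seed = seed, noise = noise)
  Xh <- vae_decode(vae, Z, t)
  mse <- mean((X - Xh)^2)
  kl <- kl_gaussian(enc$mu, enc$sigma)
  list(total = mse + beta * kl, mse = mse, kl = kl)
}

# Forward + analytic gradients for one minibatch. Returns loss components and
# gradient lists for encoder and decoder.
vae_grad <- function(vae, X, t, beta, noise) {
  n <- nrow(X); g <- vae$g; d <- vae$d
  tf <- time_features(t, n, vae$tdim)
  ec <- mlp_forward(vae$encoder, cbind(X, tf), keep_cache = TRUE)
  mu <- ec$out[, seq_len(d), drop = FALSE]
  sraw <- ec$out[, d + seq_len(d), drop = FALSE]
  sigma <- softplus(sraw)
  Z <- mu + sigma * noise
  dc <- mlp_forward(vae$decoder, cbind(Z, tf), keep_cache = TRUE)
  Xh <- dc$out
  mse <- mean((X - Xh)^2)
  kl <- kl_gaussian(mu, sigma)

  dXh <- 2 * (Xh - X) / (n * g)
  bd <- mlp_backward(vae$decoder, dc, dXh)
  dZ <- bd$dX[, seq_len(d), drop = FALSE]
  dmu <- dZ + beta * mu / n
  dsigma <- dZ * noise + beta * (sigma - 1 / sigma) / n
  dsraw <- dsigma * plogis(sraw)
  be <- mlp_backward(vae$encoder, ec, cbind(dmu, dsraw))
  list(total = mse + beta * kl, mse = mse, kl = kl,
       enc = list(gW = be$gW, gb = be$gb), dec = list(gW = bd$gW, gb = bd$gb))
}

#' Pre-train the VAE on measured timepoints
#'
#' Minibatch Adam on the VAE loss, with batches stratified by timepoint (each
#' batch carries a single valid time for the conditioning), an optional linear
#' KL warm-up, and early stopping on a loss plateau. Deterministic for a fixed
#' seed in single-threaded execution.
#'
#' @param vae an `sb_vae`.
#' @param data training `sc_timeseries` (held-out timepoints removed).
#' @param epochs maximum epochs (one epoch visits every timepoint once).
#' @param batch minibatch size.
#' @param lr Adam learning rate.
#' @param warmup epochs of linear KL warm-up (0 disables).
#' @param patience early-stop patience (epochs without relative improvement
#'   better than `tol`).
#' @param tol relative-improvement tolerance for the plateau check.
#' @param seed seed for batching and reparameterisation noise.
#' @param verbose print a line every 20 epochs.
#' @return the trained `sb_vae` with a `history` data.frame attached.
#' @export
vae_pretrain <- function(vae, data, epochs = 200L, batch = 128L, lr = 1e-3,
                         warmup = 20L, patience = 25L, tol = 1e-4,
                         seed = 1L, verbose = FALSE) {
  mats <- data$matrices
  tps <- data$timepoints
  st_e <- adam_new(vae$encoder); st_d <- adam_new(vae$decoder)
  hist <- numeric(0)
  best <- Inf; wait <- 0L
  with_seed(derive_seed(seed, 11L), {
    for (ep in seq_len(epochs)) {
      beta_ep <- if (warmup > 0L) vae$beta * min(1, ep / warmup) else vae$beta
      ep_loss <- 0; nb <- 0L
      for (k in seq_along(mats)) {
        X <- mats[[k]]
        idx <- sample(nrow(X))
        starts <- seq(1L, nrow(X), by = batch)
        for (s in starts) {
          rows <- idx[s:min(s + batch - 1L, nrow(X))]
          Xb <- X[rows, , drop = FALSE]
          eta <- matrix(rnorm(length(rows) * vae$d), length(rows), vae$d)
          gr <- vae_grad(vae, Xb, tps[k], beta_ep, eta)
          if (!is.finite(gr$total))
            stopf("vae_pretrain: non-finite loss at epoch %d (mse=%g, kl=%g)",
                  ep, gr$mse, gr$kl)
          up <- adam_step(vae$encoder, gr$enc, st_e, lr); vae$encoder <- up$net; st_e <- up$state
          up <- adam_step(vae$decoder, gr$dec, st_d, lr); vae$decoder <- up$net; st_d <- up$state
          ep_loss <- ep_loss + gr$total; nb <- nb + 1L
        }
      }
      ep_loss <- ep_loss / nb
      hist <- c(hist, ep_loss)
      if (verbose && ep %% 20L == 0L)
        message(sprintf("vae epoch %d loss %.5f", ep, ep_loss))
      if (ep_loss < best * (1 - tol)) { best <- ep_loss; wait <- 0L } else wait <- wait + 1L
      if (wait >= patience && ep > warmup) break
    }
  })
  vae$history <- data.frame(epoch = seq_along(hist), loss = hist)
  vae
}
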