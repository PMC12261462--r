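# Minimal dense-network toolkit with hand-derived backpropagation.
# All model components (VAE encoder/decoder, drift nets, kill-rate net,
# timepoint classifier) are small multilayer perceptrons; gradients are exact
# analytic expressions, and every source of randomness is routed through
# explicit seeds so training is bit-reproducible in a single-threaded run.

act_eval <- function(x, act) {
  switch(act,
    linear = x,
    tanh = tanh(x),
    silu = x * plogis(x),
    softplus = softplus(x),
    stopf("unknown activation '%s'", act))
}

# derivative evaluated at the pre-activation
act_deriv <- function(pre, act) {
  switch(act,
    linear = array(1, dim = dim(pre) %||% length(pre)),
    tanh = 1 - tanh(pre)^2,
    silu = { s <- plogis(pre); s * (1 + pre * (1 - s)) },
    softplus = plogis(pre),
    stopf("unknown activation '%s'", act))
}

# Fully-connected net: sizes = c(d_in, hidden..., d_out); hidden layers use
# `act`, the output layer is linear (heads apply their own nonlinearity).
# Weights are stored input-by-output so a batch X (n x d_in) propagates as
# X %*% W + b.
mlp_new <- function(sizes, act = "silu", zero_out = FALSE) {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- sizes[l]
    sdv <- sqrt(2 / (fan_in + sizes[l + 1L]))
    W[[l]] <- matrix(rnorm(fan_in * sizes[l + 1L], sd = sdv), fan_in, sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  if (zero_out) {
    W[[L]][] <- 0
    b[[L]][] <- 0
  }
  structure(list(W = W, b = b, act = act, sizes = sizes), class = "sb_mlp")
}

mlp_forward <- function(net, X, keep_cache = FALSE) {
  L <- length(net$W)
  A <- X
  pre <- if (keep_cache) vector("list", L) else NULL
  post <- if (keep_cache) vector("list", L) else NULL
  for (l in seq_len(L)) {
    P <- add_bias(A %*% net$W[[l]], net$b[[l]])
    A <- if (l < L) act_eval(P, net$act) else P
    if (keep_cache) { pre[[l]] <- P; post[[l]] <- A }
  }
  if (keep_cache) list(out = A, X = X, pre = pre, post = post) else A
}

# Backprop dL/d(out) through the net; returns parameter grads and dL/dX.
mlp_backward <- function(net, cache, dOut) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  dP <- dOut
  for (l in rev(seq_len(L))) {
    Aprev <- if (l == 1L) cache$X else cache$post[[l - 1L]]
    gW[[l]] <- crossprod(Aprev, dP)
    gb[[l]] <- colSums(dP)
    dA <- dP %*% t(net$W[[l]])
    if (l > 1L) dP <- dA * act_deriv(cache$pre[[l - 1L]], net$act)
  }
  list(gW = gW, gb = gb, dX = dA)
}

# ---- Adam ----------------------------------------------------------------

adam_new <- function(net) {
  zero_like <- function(p) lapply(p, function(x) { x[] <- 0; x })
  list(mW = zero_like(net$W), vW = zero_like(net$W),
       mb = zero_like(net$b), vb = zero_like(net$b), t = 0L)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$gW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$gW[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$gb[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$gb[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(net = net, state = state)
}

# elementwise sum of two gradient lists (same shapes)
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  list(gW = Map(`+`, a$gW, b$gW), gb = Map(`+`, a$gb, b$gb))
}

grads_scale <- function(a, s) list(gW = lapply(a$gW, `*`, s), gb = lapply(a$gb, `*`, s))

params_fingerprint <- function(net) {
  sum(vapply(net$W, function(w) sum(w * seq_along(w)), 0)) +
    sum(vapply(net$b, function(w) sum(w * seq_along(w)), 0))
}
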