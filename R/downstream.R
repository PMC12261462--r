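# Model outputs and downstream analyses: trajectory reconstruction,
# drift-gene ranking, relative population ratios, in-silico perturbation with
# a latent-space timepoint classifier, and live/dead differential expression.

#' Reconstruct a complete trajectory from t = 0
#'
#' Encodes the t = 0 cells, samples the forward SDE with birth/death up to
#' t = T, and decodes every grid node back to gene space, yielding expression
#' predictions at measured and unmeasured times plus per-cell statuses.
#'
#' @param fit an [scbridge] fit.
#' @param X0 optional cells x genes matrix at t = 0 (default: training t = 0).
#' @param t_start grid time to start from (measured; default 0). Cells are
#'   encoded at `t_start`.
#' @param seed RNG seed; equal seeds give identical trajectories.
#' @return object of class `sb_gene_trajectory`: `X` (decoded expression per
#'   grid node), `Z`, `A`, `events`, `t_grid`.
#' @export
reconstruct_trajectory <- function(fit, X0 = NULL, t_start = 0, seed = fit$config$seed) {
  if (is.null(X0)) {
    k <- match(t_start, fit$data$timepoints)
    if (is.na(k)) stopf("t_start = %g is not a measured timepoint", t_start)
    X0 <- fit$data$matrices[[k]]
  }
  X0 <- as.matrix(X0)
  if (ncol(X0) != length(fit$data$gene_names))
    stopf("X0 has %d genes; the model was trained on %d", ncol(X0),
          length(fit$data$gene_names))
  enc <- vae_encode(fit$vae, X0, t_start)
  Z0 <- vae_sample_latent(enc, seed = derive_seed(seed, 1L))
  traj <- bridge_simulate(fit$bridge, Z0, "forward", killer = fit$killfield,
                          seed = derive_seed(seed, 2L), t_start = t_start)
  X <- vector("list", length(traj$Z))
  for (i in seq_along(traj$Z)) {
    if (is.null(traj$Z[[i]])) next
    X[[i]] <- vae_decode(fit$vae, traj$Z[[i]], traj$t_grid[i])
    colnames(X[[i]]) <- fit$data$gene_names
  }
  structure(list(X = X, Z = traj$Z, A = traj$A, events = traj$events,
                 t_grid = traj$t_grid, direction = "forward", seed = seed),
            class = "sb_gene_trajectory")
}

#' @method print sb_gene_trajectory
#' @export
print.sb_gene_trajectory <- function(x, ...) {
  cat(sprintf("<sb_gene_trajectory> %d cells, %d grid nodes on [0, %g], %d events\n",
              ncol(x$A), length(x$X), max(x$t_grid), nrow(x$events)))
  invisible(x)
}

#' Rank genes by projected latent drift
#'
#' Projects the learned forward drift into gene space by a one-step decode
#' difference: per cell, `delta = decode(z + Q(z, t) dt, t) - decode(z, t)`;
#' the per-gene drift score is the mean of `delta` over cells (exact for a
#' linear decoder, where it equals `(W q) dt`). Genes with large positive
#' scores are interpreted as drivers of the deterministic trend. P-values
#' come from a two-sided one-sample Wilcoxon signed-rank test of the per-cell
#' projections against 0, Benjamini-Hochberg adjusted.
#'
#' @param fit an [scbridge] fit.
#' @param t timepoint at which to evaluate the drift.
#' @param Z optional cells x d latent matrix (default: the encoded ensemble of
#'   the nearest measured timepoint).
#' @param top_k how many top genes to flag (default 20).
#' @return data frame (gene, score, rank, p_value, p_adj, top) sorted by
#'   decreasing score.
#' @export
drift_gene_scores <- function(fit, t, Z = NULL, top_k = 20L) {
  if (is.null(Z)) {
    k <- which.min(abs(fit$data$timepoints - t))
    Z <- fit$ensembles[[k]]
  }
  Z <- as.matrix(Z)
  dt <- fit$bridge$dt
  Q <- drift(fit$bridge, Z, t, "forward")
  delta <- vae_decode(fit$vae, Z + Q * dt, t) - vae_decode(fit$vae, Z, t)
  score <- colMeans(delta)
  p <- apply(delta, 2L, function(x) {
    if (all(x == 0)) return(1)
    suppressWarnings(wilcox.test(x, mu = 0, exact = FALSE)$p.value)
  })
  padj <- p.adjust(p, "BH")
  ord <- order(score, decreasing = TRUE)
  data.frame(gene = fit$data$gene_names, score = score, rank = rank(-score),
             p_value = p, p_adj = padj,
             top = rank(-score) <= top_k)[ord, ]
}

#' Normalised relative population-change ratios
#'
#' Consecutive ratios `n_t / n_(t-1)` of observed counts (ground truth) or of
#' live-status sums along a predicted trajectory, divided by the maximum
#' ratio. The same normalisation applies to both, so predicted and true
#' vectors are directly comparable.
#'
#' @param x numeric vector of per-timepoint counts, or a status matrix
#'   (grid nodes x cells, as in `sb_trajectory$A`).
#' @param nodes when `x` is a status matrix: the grid-node indices of the
#'   measured timepoints at which to take the live-cell sums.
#' @return normalised ratio vector with attribute `max_ratio`.
#' @export
population_ratios <- function(x, nodes = NULL) {
  counts <- if (is.matrix(x)) {
    if (is.null(nodes)) stopf("nodes required for a status matrix")
    rowSums(x[nodes, , drop = FALSE])
  } else as.numeric(x)
  if (length(counts) < 2L) stopf("need at least 2 timepoints")
  if (any(counts[-length(counts)] == 0)) stopf("zero denominator in population ratio")
  r <- counts[-1L] / counts[-length(counts)]
  structure(r / max(r), max_ratio = max(r))
}

# ---- latent-space timepoint classifier ------------------------------------

#' Train a timepoint classifier on encoder latents
#'
#' One-hidden-layer MLP with softmax output, trained by Adam on the encoder
#' means of the measured cells with their timepoint labels; used to assign
#' trajectory cells to timepoints in perturbation experiments.
#'
#' @param fit an [scbridge] fit.
#' @param hidden hidden width.
#' @param epochs,lr,batch training settings.
#' @param seed RNG seed.
#' @return object of class `sb_classifier` with `predict` support via
#'   [classify_latents()].
#' @export
timepoint_classifier <- function(fit, hidden = 128L, epochs = 150L, lr = 1e-2,
                                 batch = 256L, seed = 1L) {
  mus <- lapply(seq_along(fit$data$timepoints), function(k)
    vae_encode(fit$vae, fit$data$matrices[[k]], fit$data$timepoints[k])$mu)
  X <- do.call(rbind, mus)
  y <- rep(seq_along(fit$data$timepoints), vapply(mus, nrow, 0L))
  K <- length(fit$data$timepoints)
  net <- with_seed(seed, mlp_new(c(ncol(X), hidden, K), act = "tanh"))
  st <- adam_new(net)
  n <- nrow(X)
  with_seed(derive_seed(seed, 1L), {
    for (ep in seq_len(epochs)) {
      idx <- sample(n, min(batch, n))
      cache <- mlp_forward(net, X[idx, , drop = FALSE], keep_cache = TRUE)
      logits <- cache$out
      logits <- logits - apply(logits, 1L, max)
      P <- exp(logits); P <- P / rowSums(P)
      dL <- P
      dL[cbind(seq_along(idx), y[idx])] <- dL[cbind(seq_along(idx), y[idx])] - 1
      g <- mlp_backward(net, cache, dL / length(idx))
      up <- adam_step(net, list(gW = g$gW, gb = g$gb), st, lr)
      net <- up$net; st <- up$state
    }
  })
  structure(list(net = net, timepoints = fit$data$timepoints), class = "sb_classifier")
}

#' Assign latent states to timepoints
#'
#' @param clf an [timepoint_classifier()] object.
#' @param Z cells x d latent matrix.
#' @return integer vector of assigned timepoint labels.
#' @export
classify_latents <- function(clf, Z) {
  logits <- mlp_forward(clf$net, as.matrix(Z))
  clf$timepoints[max.col(logits, ties.method = "first")]
}

# ---- in-silico perturbation ----------------------------------------------

#' Perturb a gene and classify the resulting trajectories
#'
#' For each perturbation level and trial: sample `n_cells` cells from the
#' measured `t_start` data, add the (signed) level to the chosen gene's value
#' before encoding, simulate perturbed and unperturbed groups forward to T
#' under shared seeds, classify the live cells at every measured grid node
#' from `t_start` on with a latent timepoint classifier, and tally the
#' assignments per timepoint. A per-timepoint two-sided t-test across trials
#' compares perturbed vs unperturbed counts. Perturbation levels are in the
#' units of the (typically z-scored) expression scale.
#'
#' @param fit an [scbridge] fit.
#' @param gene gene name.
#' @param levels signed perturbation levels (default `c(5, 10, 15, 20, 25)`;
#'   negative values underexpress).
#' @param t_start measured timepoint to perturb at.
#' @param n_cells cells sampled per trial (default 2000, capped at the number
#'   available).
#' @param n_trials trials per level (default 10).
#' @param clf optional pre-trained [timepoint_classifier()].
#' @param seed RNG seed.
#' @return object of class `sb_perturbation`: per-level list with `counts`
#'   (trial x timepoint x group array) and `tests` (per-timepoint t-test
#'   p-values), plus the inputs.
#' @export
perturb_and_classify <- function(fit, gene, levels = c(5, 10, 15, 20, 25),
                                 t_start, n_cells = 2000L, n_trials = 10L,
                                 clf = NULL, seed = fit$config$seed) {
  j <- match(gene, fit$data$gene_names)
  if (is.na(j)) stopf("gene '%s' not on the training gene axis", gene)
  k <- match(t_start, fit$data$timepoints)
  if (is.na(k)) stopf("t_start = %g is not a measured timepoint", t_start)
  X <- fit$data$matrices[[k]]
  if (is.null(clf)) clf <- timepoint_classifier(fit, seed = derive_seed(seed, 77L))
  dt <- fit$bridge$dt
  nodes <- round(fit$data$timepoints[fit$data$timepoints >= t_start] / dt) + 1L
  tps <- fit$data$timepoints
  out <- list()
  for (lv in levels) {
    counts <- array(0L, dim = c(n_trials, length(tps), 2L),
                    dimnames = list(NULL, paste0("t", tps), c("unperturbed", "perturbed")))
    for (tr in seq_len(n_trials)) {
      s <- derive_seed(seed, 1000L * match(lv, levels) + tr)
      rows <- with_seed(s, sample(nrow(X), min(n_cells, nrow(X)), replace = nrow(X) < n_cells))
      X0 <- X[rows, , drop = FALSE]
      Xp <- X0; Xp[, j] <- Xp[, j] + lv
      tallies <- lapply(list(X0, Xp), function(Xg) {
        enc <- vae_encode(fit$vae, Xg, t_start)
        Z0 <- vae_sample_latent(enc, seed = derive_seed(s, 11L))  # shared noise
        traj <- bridge_simulate(fit$bridge, Z0, "forward", killer = fit$killfield,
                                seed = derive_seed(s, 12L), t_start = t_start)
        assigned <- unlist(lapply(nodes, function(nd) {
          live <- traj$A[nd, ] == 1
          classify_latents(clf, traj$Z[[nd]][live, , drop = FALSE])
        }))
        table(factor(assigned, levels = tps))
      })
      counts[tr, , 1L] <- as.integer(tallies[[1L]])
      counts[tr, , 2L] <- as.integer(tallies[[2L]])
    }
    p <- vapply(seq_along(tps), function(q) {
      a <- counts[, q, 1L]; b <- counts[, q, 2L]
      if (all(a == b)) return(1)  # identical under shared seeds (e.g. level 0)
      if (sd(a) == 0 && sd(b) == 0) return(as.numeric(a[1L] == b[1L]))
      suppressWarnings(t.test(a, b)$p.value)
    }, 0)
    out[[paste0("level_", lv)]] <- list(level = lv, counts = counts,
                                        tests = data.frame(timepoint = tps, p_value = p))
  }
  structure(list(gene = gene, levels = levels, t_start = t_start,
                 n_trials = n_trials, results = out), class = "sb_perturbation")
}

#' @method print sb_perturbation
#' @export
print.sb_perturbation <- function(x, ...) {
  cat(sprintf("<sb_perturbation> gene %s at t = %g, %d trials\n",
              x$gene, x$t_start, x$n_trials))
  for (r in x$results) {
    sig <- r$tests$timepoint[r$tests$p_value < 0.05]
    cat(sprintf("  level %+g: significant timepoints: %s\n", r$level,
                if (length(sig)) paste(sig, collapse = ", ") else "none"))
  }
  invisible(x)
}

#' Differential expression between cells predicted live and dead
#'
#' Per-gene two-group Wilcoxon rank-sum test between cells with live and dead
#' predicted status, Benjamini-Hochberg adjusted, with the mean difference
#' (live minus dead, on the input log scale) as effect size.
#'
#' @param X cells x genes expression matrix.
#' @param statuses binary vector (1 = live, 0 = dead), one per row of `X`.
#' @param min_cells minimum group size.
#' @return data frame (gene, lfc, p_value, p_adj) sorted by p-value, with
#'   attribute `group_sizes`.
#' @export
live_dead_de <- function(X, statuses, min_cells = 3L) {
  X <- as.matrix(X)
  if (length(statuses) != nrow(X)) stopf("one status per cell required")
  live <- statuses == 1
  if (sum(live) < min_cells || sum(!live) < min_cells)
    stopf("need >= %d cells per group (live: %d, dead: %d) in this interval",
          min_cells, sum(live), sum(!live))
  p <- vapply(seq_len(ncol(X)), function(j) {
    a <- X[live, j]; b <- X[!live, j]
    if (sd(a) == 0 && sd(b) == 0 && a[1L] == b[1L]) return(1)
    suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  }, 0)
  lfc <- colMeans(X[live, , drop = FALSE]) - colMeans(X[!live, , drop = FALSE])
  out <- data.frame(gene = colnames(X) %||% paste0("gene", seq_len(ncol(X))),
                    lfc = lfc, p_value = p, p_adj = p.adjust(p, "BH"))
  out <- out[order(out$p_value), ]
  attr(out, "group_sizes") <- c(live = sum(live), dead = sum(!live))
  out
}
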