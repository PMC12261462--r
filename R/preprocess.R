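# Preprocessing: depth scaling + log1p, HVG selection, anchor-gene correlation
# filter, z-scoring. The order used for the built-in pipeline is
# depth/log1p -> correlation filter -> HVG -> (optional) z-score, computed on
# training timepoints only and applied unchanged to held-out cells.

#' Depth-scale and log-transform counts
#'
#' Scales each cell's counts so its total equals `target_depth` (default: the
#' median per-cell total over all cells in the object), then applies
#' `log1p`. Refuses to run twice (guarded via `meta$log1p`).
#'
#' @param data raw-count `sc_timeseries`.
#' @param target_depth positive number, or `"median"`.
#' @return transformed `sc_timeseries`; `meta$steps`, `meta$target_depth` and
#'   `meta$log1p` record what was done.
#' @export
preprocess_counts <- function(data, target_depth = "median") {
  validate_timeseries(data)
  if (isTRUE(data$meta$log1p))
    stopf("preprocess_counts: data is already depth-scaled and log1p-transformed")
  totals <- unlist(lapply(data$matrices, rowSums), use.names = FALSE)
  zero <- totals == 0
  if (any(zero)) {
    ids <- unlist(data$cell_ids, use.names = FALSE)[zero]
    stopf("cells with zero total counts cannot be depth-scaled: %s",
          paste(head(ids, 10L), collapse = ", "))
  }
  depth <- if (identical(target_depth, "median")) median(totals) else {
    if (!is.numeric(target_depth) || target_depth <= 0)
      stopf("target_depth must be positive or \"median\"")
    target_depth
  }
  data$matrices <- lapply(data$matrices, function(M) {
    if (any(M < 0)) stopf("preprocess_counts expects non-negative counts")
    log1p(M * (depth / rowSums(M)))
  })
  data$meta$steps <- c(data$meta$steps, "depth_scale", "log1p")
  data$meta$target_depth <- depth
  data$meta$log1p <- TRUE
  data
}

#' Select highly variable genes
#'
#' Mean-binned normalised-dispersion HVG ranking (the standard single-cell
#' recipe) computed on the pooled cells of the training object: per gene, the
#' dispersion var/mean of `expm1`-scale expression is normalised by the median
#' and MAD of its mean-expression bin (robust to bins that are themselves rich
#' in variable genes), and the top `n_top` genes by normalised dispersion are
#' selected.
#'
#' @param train preprocessed (log-scale) training `sc_timeseries`, held-out
#'   timepoints already removed.
#' @param n_top number of genes to keep (default 2000); capped at the number
#'   of genes available.
#' @param n_bins number of mean-expression bins.
#' @return logical gene mask (length = number of genes) with attributes
#'   `ranking` (gene order, most variable first) and `dispersion`.
#' @export
select_hvgs <- function(train, n_top = 2000L, n_bins = 20L) {
  if (n_top <= 0) stopf("n_top must be positive")
  X <- pooled_matrix(train)
  E <- expm1(X)
  mu <- colMeans(E)
  v <- apply(E, 2L, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  # with few genes, shrink the bin count so each bin holds enough genes for a
  # stable within-bin dispersion sd (~20 per bin)
  n_bins <- max(1L, min(n_bins, length(mu) %/% 20L))
  bins <- cut(mu, breaks = unique(quantile(mu, probs = seq(0, 1, length.out = n_bins + 1L))),
              include.lowest = TRUE)
  z <- disp
  for (b in levels(bins)) {
    sel <- which(bins == b)
    # robust within-bin normalisation (median/MAD) so a handful of highly
    # variable genes cannot inflate their own bin's reference dispersion
    m <- median(disp[sel]); s <- mad(disp[sel])
    if (!is.finite(s) || s == 0) s <- sd(disp[sel])
    if (!is.finite(s) || s == 0) s <- 1
    z[sel] <- (disp[sel] - m) / s
  }
  k <- min(n_top, length(z))
  ord <- order(z, decreasing = TRUE)
  mask <- rep(FALSE, length(z))
  mask[ord[seq_len(k)]] <- TRUE
  names(mask) <- train$gene_names
  structure(mask, ranking = train$gene_names[ord], dispersion = z)
}

#' Subset an object to a gene mask
#'
#' @param data `sc_timeseries`.
#' @param mask logical vector over genes (e.g. from [select_hvgs()]).
#' @return reduced `sc_timeseries`; the mask is recorded in `meta$hvg_mask`.
#' @export
apply_gene_mask <- function(data, mask) {
  if (length(mask) != length(data$gene_names))
    stopf("mask length %d != gene count %d", length(mask), length(data$gene_names))
  data$matrices <- lapply(data$matrices, function(M) M[, mask, drop = FALSE])
  data$meta$hvg_mask <- data$gene_names[mask]
  data$gene_names <- data$gene_names[mask]
  data
}

#' Remove genes correlated with an anchor gene
#'
#' Drops every gene whose absolute Pearson correlation with `anchor_gene`
#' (computed on pooled cells of the log-normalised object) exceeds
#' `r_threshold`. The anchor itself correlates with itself at r = 1 and is
#' removed. Used to strip cell-cycle signal (anchor TOP2A, r > 0.15).
#'
#' @param data preprocessed `sc_timeseries`.
#' @param anchor_gene gene name present in the object.
#' @param r_threshold correlation threshold (default 0.15).
#' @return reduced `sc_timeseries`; removed genes recorded in meta.
#' @export
filter_gene_correlates <- function(data, anchor_gene, r_threshold = 0.15) {
  j <- match(anchor_gene, data$gene_names)
  if (is.na(j)) stopf("anchor gene '%s' not present", anchor_gene)
  X <- pooled_matrix(data)
  a <- X[, j]
  if (sd(a) == 0) stopf("anchor gene '%s' is constant; correlation undefined", anchor_gene)
  r <- suppressWarnings(as.vector(cor(X, a)))
  r[is.na(r)] <- 0  # constant genes: keep
  drop <- abs(r) > r_threshold
  drop[j] <- TRUE
  data$matrices <- lapply(data$matrices, function(M) M[, !drop, drop = FALSE])
  data$meta$anchor_filter <- list(anchor = anchor_gene, r_threshold = r_threshold,
                                  removed = data$gene_names[drop])
  data$gene_names <- data$gene_names[!drop]
  data
}

#' Z-score genes
#'
#' Per-gene standardisation to mean 0, sd 1 over the pooled cells, using the
#' population (divide-by-n) standard deviation. Constant genes map to 0.
#' The per-gene centre/scale is returned in `meta$zscore` so the identical
#' affine transform can be applied to held-out cells with [zscore_apply()].
#'
#' @param data preprocessed `sc_timeseries`.
#' @return transformed `sc_timeseries`.
#' @export
zscore_features <- function(data) {
  X <- pooled_matrix(data)
  n <- nrow(X)
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2L, mu)^2))  # population convention
  stats <- list(mean = mu, sd = sdv, convention = "population")
  out <- zscore_apply(data, stats)
  out$meta$zscore <- stats
  out$meta$steps <- c(out$meta$steps, "zscore")
  out
}

#' Apply a stored z-score transform
#'
#' @param data `sc_timeseries` on the same gene axis as the training data.
#' @param stats `meta$zscore` from [zscore_features()] on the training data.
#' @return transformed `sc_timeseries`.
#' @export
zscore_apply <- function(data, stats) {
  sdv <- ifelse(stats$sd > 0, stats$sd, 1)
  data$matrices <- lapply(data$matrices, function(M) {
    M <- sweep(M, 2L, stats$mean)
    M <- sweep(M, 2L, sdv, "/")
    M[, stats$sd == 0] <- 0
    M
  })
  data
}
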