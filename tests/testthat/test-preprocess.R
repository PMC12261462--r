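# Depth scaling + log1p, HVG selection, anchor-correlation filter, z-scoring.

test_that("depth scaling and log1p match hand arithmetic", {
  M <- rbind(c(2, 2, 0), c(8, 0, 0))
  ts <- timeseries(list(M), 0L, gene_names = c("a", "b", "c"))
  out <- preprocess_counts(ts, target_depth = 8)
  expect_equal(unname(out$matrices[[1]][1, ]), c(log(5), log(5), 0))
  expect_equal(unname(out$matrices[[1]][2, ]), c(log(9), 0, 0))
  # cell already at target depth: only log1p applied
  expect_equal(unname(out$matrices[[1]][2, 1]), log1p(8))
  # all-zero gene column stays zero
  expect_true(all(out$matrices[[1]][, 3] == 0))
})

test_that("preprocessing guards: zero-total cells, double application, bad depth", {
  M <- rbind(c(0, 0), c(1, 2))
  rownames(M) <- c("dead_cell", "ok")
  ts <- timeseries(list(M), 0L)
  expect_error(preprocess_counts(ts), "dead_cell")
  ok <- preprocess_counts(toy_counts_ts())
  expect_error(preprocess_counts(ok), "already")
  expect_error(preprocess_counts(toy_counts_ts(), target_depth = -2), "positive")
})

test_that("median target depth preserves per-cell totals at the median", {
  ts <- preprocess_counts(toy_counts_ts(seed = 5L))
  totals <- unlist(lapply(ts$matrices, function(M) rowSums(expm1(M))))
  expect_equal(unname(median(totals)), ts$meta$target_depth, tolerance = 1e-8)
})

test_that("HVG selection finds planted high-dispersion genes and caps at g", {
  set.seed(7)
  n <- 400; g <- 60
  X <- matrix(rpois(n * g, 5), n, g)
  X[, 1:10] <- rpois(n * 10, 5) * rbinom(n * 10, 1, 0.15) / 0.15  # 10x dispersion
  colnames(X) <- paste0("g", seq_len(g))
  ts <- preprocess_counts(timeseries(list(X + 1), 0L))
  mask <- select_hvgs(ts, n_top = 10L)
  expect_identical(sum(mask), 10L)
  expect_true(all(which(mask) %in% 1:10))
  # independent oracle: raw dispersion ranking picks the same gene set
  E <- expm1(ts$matrices[[1]])
  disp <- apply(E, 2, var) / colMeans(E)
  expect_setequal(which(mask), order(disp, decreasing = TRUE)[1:10])
  # n_top beyond g selects everything
  expect_identical(sum(select_hvgs(ts, n_top = 2000L)), as.integer(g))
  expect_error(select_hvgs(ts, n_top = 0L), "positive")
})

test_that("HVG mask is invariant to shuffling cell order", {
  ts <- preprocess_counts(toy_counts_ts(n_per_tp = 30L, g = 20L, seed = 9L))
  shuffled <- ts
  set.seed(1)
  shuffled$matrices <- lapply(shuffled$matrices, function(M) M[sample(nrow(M)), ])
  expect_identical(select_hvgs(ts, 8L), select_hvgs(shuffled, 8L))
})

test_that("anchor-correlation filter removes the anchor and its correlates", {
  set.seed(11)
  n <- 2000
  anchor <- rnorm(n)
  X <- cbind(TOP2A = anchor, twin = anchor + rnorm(n, 0, 1e-3),
             indep = rnorm(n), indep2 = rnorm(n))
  ts <- timeseries(list(abs(X)), 0L)
  ts$matrices[[1]] <- X  # log-scale data may be negative post-normalisation
  out <- filter_gene_correlates(ts, "TOP2A", r_threshold = 0.15)
  expect_false("TOP2A" %in% out$gene_names)
  expect_false("twin" %in% out$gene_names)
  # independent genes survive: with n = 2000 the null |r| rarely exceeds 0.15
  expect_true(all(c("indep", "indep2") %in% out$gene_names))
  expect_error(filter_gene_correlates(ts, "absent"), "not present")
  ts$matrices[[1]][, 3] <- 1
  expect_error(filter_gene_correlates(ts, "indep"), "constant")
})

test_that("z-scoring uses the population sd and zeroes constant genes", {
  M <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  ts <- timeseries(list(M), 0L)
  out <- zscore_features(ts)
  expect_equal(unname(out$matrices[[1]][, 1]),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_true(all(out$matrices[[1]][, 2] == 0))
  expect_identical(out$meta$zscore$convention, "population")
  # transformed training data is centred to machine precision
  big <- zscore_features(preprocess_counts(toy_counts_ts(seed = 13L)))
  mu <- colMeans(do.call(rbind, big$matrices))
  expect_true(all(abs(mu) < 1e-8))
  # the stored transform applies identically to held-out data
  held <- timeseries(list(M + 1), 0L)
  out2 <- zscore_apply(held, out$meta$zscore)
  expect_equal(unname(out2$matrices[[1]][, 1]),
               unname((M[, 1] + 1 - 2) / sqrt(2 / 3)), tolerance = 1e-8)
})
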