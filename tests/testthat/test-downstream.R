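# Trajectory reconstruction, drift-gene ranking, population ratios,
# perturbation, live/dead differential expression.

test_that("drift-gene scores equal the closed form W q dt for a linear decoder", {
  W <- rbind(c(1, -2, 0.5, 0), c(0, 1, 1, -1))
  q <- c(0.8, -0.4)
  fit <- linear_toy_fit(W, q)
  tab <- drift_gene_scores(fit, t = 0.5)
  expected <- drop(q %*% W) * fit$bridge$dt
  expect_equal(tab$score[match(paste0("g", 1:4), tab$gene)], expected,
               tolerance = 1e-6)
  expect_identical(sort(tab$rank), 1:4 * 1)
})

test_that("zero drift gives all-zero scores and no significant genes", {
  fit <- linear_toy_fit(matrix(0, 2, 4), c(0, 0))
  tab <- drift_gene_scores(fit, t = 0.5)
  expect_true(all(tab$score == 0))
  expect_true(all(tab$p_value == 1))
})

test_that("trajectory reconstruction: grid size, determinism, gene axis guard", {
  sf <- shared_fit()
  tr1 <- reconstruct_trajectory(sf$fit, seed = 7L)
  expect_length(tr1$X, sf$fit$bridge$n_steps + 1L)
  tr2 <- reconstruct_trajectory(sf$fit, seed = 7L)
  expect_identical(tr1$Z, tr2$Z)
  expect_identical(tr1$A, tr2$A)
  expect_error(reconstruct_trajectory(sf$fit, X0 = matrix(0, 3, 7)), "genes")
  # frozen bridge: zero drift and eps = 0 keeps the decoded output constant
  frozen <- sf$fit
  frozen$bridge <- bridge_new(8L, T = 4, eps = 0, n_steps = 8L, seed = 1L)
  trf <- reconstruct_trajectory(frozen, seed = 1L)
  expect_identical(trf$Z[[1L]], trf$Z[[9L]])
})

test_that("population ratios: hand arithmetic and status-matrix input agree", {
  r <- population_ratios(c(100, 200, 100))
  expect_equal(as.numeric(r), c(1, 0.25))
  expect_equal(attr(r, "max_ratio"), 2)
  expect_equal(as.numeric(population_ratios(c(50, 50, 50))), c(1, 1))
  A <- matrix(1, 5, 40)  # all live at all nodes
  expect_equal(as.numeric(population_ratios(A, nodes = c(1, 3, 5))), c(1, 1))
  expect_error(population_ratios(c(10)), "at least 2")
  expect_error(population_ratios(c(0, 5)), "zero denominator")
})

test_that("the latent classifier separates well-separated timepoints", {
  pf <- pop_fit()
  clf <- timepoint_classifier(pf$fit, hidden = 32L, epochs = 120L, seed = 3L)
  acc <- mean(unlist(lapply(seq_along(pf$fit$data$timepoints), function(k) {
    mu <- vae_encode(pf$fit$vae, pf$fit$data$matrices[[k]],
                     pf$fit$data$timepoints[k])$mu
    classify_latents(clf, mu) == pf$fit$data$timepoints[k]
  })))
  expect_gt(acc, 0.7)
})

test_that("a null perturbation changes nothing under shared seeds", {
  pf <- pop_fit()
  out <- perturb_and_classify(pf$fit, "gene1", levels = 0, t_start = 2,
                              n_cells = 150L, n_trials = 3L, seed = 11L)
  r <- out$results$level_0
  expect_identical(r$counts[, , "perturbed"], r$counts[, , "unperturbed"])
  expect_true(all(r$tests$p_value == 1))
  expect_error(perturb_and_classify(pf$fit, "nope", levels = 0, t_start = 2),
               "not on the training gene axis")
})

test_that("overexpressing a driver gene shifts cells toward later timepoints", {
  pf <- pop_fit()
  out <- perturb_and_classify(pf$fit, "gene1", levels = c(-4, 4), t_start = 1,
                              n_cells = 200L, n_trials = 4L, seed = 13L)
  mean_tp <- function(cnt) {
    tot <- colSums(cnt)
    sum(as.numeric(pf$fit$data$timepoints) * tot) / sum(tot)
  }
  up <- out$results$level_4$counts
  down <- out$results[["level_-4"]]$counts
  expect_gt(mean_tp(up[, , "perturbed"]), mean_tp(up[, , "unperturbed"]))
  expect_lt(mean_tp(down[, , "perturbed"]), mean_tp(down[, , "unperturbed"]))
})

test_that("live/dead DE recovers planted shifts and controls the null", {
  set.seed(21)
  n <- 200; g <- 50
  X <- matrix(rnorm(2 * n * g), 2 * n, g, dimnames = list(NULL, paste0("g", 1:g)))
  status <- rep(c(1, 0), each = n)
  X[status == 1, 1:5] <- X[status == 1, 1:5] + 2   # 2-sd shift in 5 genes
  tab <- live_dead_de(X, status)
  expect_true(all(paste0("g", 1:5) %in% head(tab$gene, 10)))
  expect_identical(attr(tab, "group_sizes"), c(live = 200L, dead = 200L))
  expect_true(all(tab$lfc[match(paste0("g", 1:5), tab$gene)] > 1))
  # identical groups: nothing beyond the false-positive rate
  Xnull <- matrix(rnorm(2 * n * g), 2 * n, g)
  tnull <- live_dead_de(Xnull, status)
  expect_lte(sum(tnull$p_adj < 0.05), 2)
  expect_error(live_dead_de(X, rep(1, 2 * n)), "per group")
})
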