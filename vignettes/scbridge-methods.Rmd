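---
title: "Methods: unbalanced diffusion Schrödinger bridges for time-series single-cell data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unbalanced diffusion Schrödinger bridges for time-series single-cell data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its model and of the design
choices made where the design was genuinely open. It states no empirical
result that the test suite and `scripts/acceptance.R` do not themselves
compute.

## The problem

A single-cell time course measures different cells at each timepoint —
sequencing destroys the cell — so no cell is observed twice, and the number
of cells collected at each timepoint is itself informative: populations
grow and shrink through birth, proliferation and death. The package
reconstructs a continuous stochastic trajectory between the measured
snapshots, predicts expression at unmeasured times, tracks relative
population size, and ranks genes by their contribution to the deterministic
trend.

## Model

**Latent space.** A variational autoencoder conditioned on time (a
sinusoidal encoding of `t` concatenated to the input) maps expression to a
`d`-dimensional diagonal-Gaussian posterior `N(μ, σ²)` and back. `σ` is
parameterised through a softplus (positivity without `exp` overflow); the
per-dimension diagonal posterior is the standard VAE choice. The loss is
`MSE + β·KL` with `β = 0.01` by default and a linear warm-up; minibatches
are stratified by timepoint so each batch carries one valid `t`.

**Bridge.** In latent space the model solves a Schrödinger bridge between
the encoded boundary timepoints: forward and backward SDEs with drifts
`f ± εQ` where `Q, Q̂` approximate `ε∇log Ψ`, `ε∇log Ψ̂` of the
Hopf–Cole factorisation. `Ψ` and `Ψ̂` are never represented directly —
only their scaled log-gradients, as drift networks. Training alternates IPF
passes: simulate the backward SDE from `ρ_T`, fit `Q` by the divergence-form
likelihood `Δt Σ A(½‖Q‖² + ε∇·Q + ⟨Q, Q̂⟩)`; then the mirror pass for `Q̂`.
The fixed point satisfies `Q + Q̂ = ε∇log p_t` (the forward/backward score
relation), which is what makes each half-bridge the time reversal of the
other. When a backward path is integrated down the grid the drift enters
with the sign of its (negative) time increment; getting this sign wrong
makes the backward boundary diagnostic diverge while the forward one still
converges — the per-round `W2(simulated, target)` diagnostics for *both*
boundaries are logged for exactly this reason.

**Unbalanced dynamics.** The state space is compactified with a cemetery
state. A data-derived prior kill rate — the fraction of latent features
deviating more than 2 sd from the next measured timepoint's mean, floored
at 20% — is modulated by a learned `K_ω(t)`; per-step transition
probabilities are `⌈k·K_ω·Δt⌋` (death) and `⌈b·K_ω·Δt⌋` (birth), clipped to
the unit interval with the excess penalised. The population loss matches
the accumulated (clipped) birth/death probabilities to the empirical mass
changes `(n_i − n_0)/max n` at every measured intermediate timepoint.

## Design choices

* **Hand-derived gradients; one-hidden-layer drift nets.** All networks are
  small dense nets trained by analytic backpropagation and Adam. The
  likelihood contains `∇·Q`, so its gradient in `θ` is a second-order
  quantity; with one hidden tanh layer both the divergence
  (`Σ_k a'(h_k)·s_k` with `s_k = Σ_j W1[j,k]W2[k,j]`) and its parameter
  gradient are closed-form. The VAE keeps two hidden SiLU layers (its loss
  is first-order). Every gradient is verified against central finite
  differences in the unit tests.
* **Divergence estimator.** Exact closed-form trace for `d ≤ 16`;
  Hutchinson above, with the probe set collapsing to the coordinate basis
  (and the estimate to the exact trace) whenever the probe count reaches
  `d`. Rademacher probes are seeded separately from the simulation noise so
  IPF passes are reproducible independently.
* **Exact W2.** Equal-size point sets are solved as a linear assignment
  problem (Jonker–Volgenant, C++, `O(n³)`); small unequal sizes by
  replication to the least common multiple; large unequal problems by
  log-domain Sinkhorn with a small entropic regulariser (method recorded on
  the result). Gradients of the joint loss use the fixed optimal matching
  (a Danskin argument) on the squared matched distances.
* **Kill-net parameterisation.** `K_ω = softplus(raw − 4)`: the
  zero-initialised net then starts at `K ≈ 0.02`, i.e. the untrained model
  is (nearly) the balanced reference process, mirroring the zero-initialised
  drift output layers. Time enters the kill net in grid-step units
  (`t/Δt`): the transformer-style sinusoidal features then span many periods
  over `[0, T]` and the net can localise killing inside a single measured
  interval, which integer-scale time cannot resolve. The prior kill rate is
  evaluated on latent features by default (`kill_features` flag mirrors the
  gene-space alternative); `K_ω` is time-only by default with a
  state-dependent variant behind `kill_state_dependent`.
* **Birth rate.** `b = 0` unless the measured counts increase somewhere, in
  which case `b = 1` and `K_ω` modulates both directions. Revived cells
  re-enter at a jittered copy (sd = 5% of the latent sd) of a uniformly
  chosen live cell: the cemetery has no geometry, and copying live cells
  preserves the current marginal.
* **Statuses on the full grid.** The status sum in the likelihood runs over
  every grid node (both endpoints included); statuses are carried piecewise
  between measured timepoints.
* **Grid.** `n_steps` defaults to 100 and is rounded up to a multiple of
  `T`, so every measured (and held-out) integer timepoint lies exactly on a
  grid node.
* **Preprocessing order.** Depth scaling (to the median per-cell total) and
  `log1p`, then the anchor-gene correlation filter (absolute Pearson
  `r > 0.15` on pooled log-normalised training cells, anchor removed), then
  HVG selection, then optional z-scoring. The anchor filter runs before HVG
  selection; the order is configurable. The z-score uses the population
  (divide-by-n) sd — the convention of the usual scaler implementations —
  and is recorded in `meta` together with the per-gene transform so held-out
  cells receive the identical affine map.
* **HVG normalisation.** Dispersion (var/mean on the `expm1` scale) is
  normalised within mean-expression bins by median and MAD; the bin count
  shrinks with the gene count so bins keep ~20 genes. The robust centre
  matters when a bin is itself rich in variable genes.
* **Drift-gene projection.** One-step decode difference
  `decode(z + QΔt) − decode(z)` rather than a decoder Jacobian-vector
  product: it is exact for linear decoders and needs no second-order
  autodiff. P-values are a two-sided one-sample Wilcoxon signed-rank test of
  the per-cell projections against zero with BH adjustment — the test is a
  documented choice, not a reproduction claim.
* **Perturbation scoring.** Perturbed and unperturbed runs share seeds, so a
  zero-level perturbation is *identical* by construction and its t-tests are
  defined as p = 1; the null calibration is therefore exact, and the
  substantive check is directional (classifier mass moving toward later
  timepoints under overexpression of a driver).

## The synthetic generator

`simulate_timeseries()` draws independent cohorts per timepoint (destructive
sampling): each cell follows `dz = b(z,t)dt + ε dW` from a common
`N(0, 0.3²)` start under a linear, bistable, or two-well branching drift;
expression is `softplus(zL + intercept + noise)` — bounded, non-negative,
on the scale of log-normalised data. The first five genes load on the
drifting coordinate (the planted drivers). A death window kills cells in
the lagging half of the cohort at a given hazard; cohort sizes are
over-provisioned by a Monte-Carlo survival estimate and survivors are
subsampled to the requested count — the measured `n_t` is the number of
cells *sequenced*, an experimental choice, so realised counts equal the
schedule unless the population crashes below it.

What it does **not** emulate: dropout and overdispersed counting noise,
library-size confounding, batch effects, doublets. Tests passing on this
generator show that the estimator recovers the latent dynamics and the
population schedule it assumes — not that those assumptions hold for any
particular real dataset.

## Problem sizes and numerical settings

The test suite and acceptance script run deliberately small instances: the
two-Gaussian bridge task (500 cells/side, 20 grid steps, 5 IPF rounds), and
two full fits on 50-gene, 5-timepoint series with ~300 cells per timepoint,
a 40-step grid, 3–4 IPF rounds of 60–70 inner steps, and latent dimension
4–8. These sizes were chosen so the whole validation cycle completes in
minutes on one CPU while still exercising every phase end to end; the
defaults (`d = 16`, 100 steps, 6 rounds, 120 inner steps) are what one
would use on real data. `ε` defaults to 0.1 and is the single most
performance-sensitive constant; the loss weights default to 1 and the
optimiser settings (Adam, `lr` `1e-3`–`1e-2`) are exposed, not asserted.

## Known limitations

* Optimisation is single-threaded R; large datasets (10⁵ cells, 2000 genes)
  will want the defaults scaled and patience.
* The population loss matches *cumulative* mass changes; between measured
  timepoints the timing of deaths within an interval is identified only
  through the prior kill rate's geometry.
* Gradients for the kill net treat simulated statuses as fixed per epoch
  (no score-function term), the standard approximation for this loss.
* The entropic W2 branch is an approximation; it is only used above the
  exact solver's size cutoff and never in the acceptance checks.
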