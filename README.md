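# scbridge

Trajectory inference for time-series single-cell RNA-seq via an unbalanced
diffusion Schrödinger bridge in a learned latent space.

Single-cell sequencing is destructive: a time-course experiment yields
snapshots of *different* cells at a few discrete timepoints, while the
underlying process — differentiation, development, drug response — is
continuous and changes the population itself through birth, proliferation and
death. `scbridge` is for analysts who have such time-series count matrices
and want (i) expression predictions at unmeasured times, (ii) the relative
cell-population change along the way, and (iii) the genes driving the
deterministic trend.

## The model

A time-conditioned variational autoencoder maps expression `x` at time `t` to
a low-dimensional latent `z` with posterior `q_φ(z | x‖t) = N(μ, σ²)` and
decoder `p_ϕ(z‖t) → x̂`, trained on `MSE(X, X̂) + β·KL(q ‖ N(0, I))`. In the
latent space, the trajectory between the boundary marginals `ρ_0` and `ρ_T`
(the encoded first and last timepoints) is modeled as a Schrödinger bridge:
the pair of forward/backward SDEs

    dZ→ = [f + εQ_θ(Z→, t)] dt + ε dW,      Z→(0) ~ ρ_0
    dZ← = [f − εQ̂_θ̂(Z←, t)] dt + ε dW̄,     Z←(0) ~ ρ_T

where `Q ≈ ε∇log Ψ` and `Q̂ ≈ ε∇log Ψ̂` are neural drift fields trained by
the forward–backward SDE likelihood

    L_div = Δt Σ_i A_i ( ½‖Q‖² + ε ∇·Q + ⟨Q, Q̂⟩ )

in alternating IPF (dynamic Sinkhorn) passes, each pass simulating the
opposite SDE by Euler–Maruyama on a 100-step grid. Population changes enter
through a one-point compactification of the state space: a prior kill rate
`k(z, t)` (fraction of features deviating > 2 sd from the next measured
timepoint, floored at 20%) is modulated by a learned network `K_ω(t)`;
per-step death/birth probabilities `⌈k·K_ω·Δt⌋`, `⌈b·K_ω·Δt⌋` drive a
live/dead status process trained to match the observed per-timepoint cell
numbers `(n_i − n_0)/max n`. The VAE is co-trained with the bridge through
`L_joint = W2(Z_φ,t, Z→_t) + W2(X_t, p_ϕ(Z_φ,t))`, the exact 2-Wasserstein
distance between empirical point sets.

All networks are small dense nets with hand-derived analytic gradients
(drift nets use one hidden layer so the divergence term and its parameter
gradient are closed-form); the exact W2 uses a Jonker–Volgenant assignment
solver in C++.

## Worked example

```r
library(scbridge)

# synthetic time course: 5 timepoints, 50 genes, cells dying mid-trajectory
sim <- simulate_timeseries(d = 2, g = 50, T = 4,
                           counts = c(300, 300, 200, 150, 150),
                           drift_spec = "linear",
                           death_window = list(from = 1, to = 3, rate = 1.2),
                           seed = 21)

cfg <- scbridge_config(d = 4, vae_hidden = c(64, 64), n_steps = 40,
                       rounds = 3, vae_epochs = 80, inner_steps = 60,
                       kill_epochs = 120, lr_kill = 1e-2, seed = 21)
fit <- scbridge(sim$data, cfg)
print(fit)
#> Unbalanced diffusion Schrodinger bridge fit
#>   timepoints: 0, 1, 2, 3, 4 (cells: 300, 300, 200, 150, 150)
#>   genes: 50, latent dim: 4, eps: 0.1, grid: 40 steps on [0, 4]
#>   IPF rounds: 3; population dynamics: on (b = 0)
#>   boundary W2 (terminal): 4.2782 -> 3.1426 over 3 rounds

traj <- reconstruct_trajectory(fit, seed = 99)
nodes <- round(fit$data$timepoints / fit$bridge$dt) + 1
population_ratios(traj$A, nodes)       # predicted n_t / n_(t-1), normalised
#> [1] 0.9830769 0.7349675 0.6974742 1.0000000
population_ratios(c(300, 300, 200, 150, 150))  # ground truth
#> [1] 1.0000000 0.6666667 0.7500000 1.0000000

head(drift_gene_scores(fit, t = 1), 3)   # planted drivers are genes 1-5
#>        gene     score rank      p_value        p_adj  top
#> gene5 gene5 0.4661860    1 6.114137e-51 1.006126e-50 TRUE
#> gene1 gene1 0.4324678    2 6.114137e-51 1.006126e-50 TRUE
#> gene3 gene3 0.4280237    3 6.114137e-51 1.006126e-50 TRUE
```

The predicted population ratios track the prescribed death schedule (a drop
to ~2/3 then ~3/4, then flat), and the top drift scores recover the genes
that load on the drifting latent coordinate. `evaluate_heldout()` reports
gene-space 2-Wasserstein distances for withheld timepoints as `mean±sd` over
sampling replicates next to a copy-previous-timepoint baseline, and
`perturb_and_classify()` runs in-silico over/underexpression experiments
scored by a latent-space timepoint classifier.

A thin command-line wrapper (`inst/cli/scbridge`) exposes `simulate`,
`preprocess`, `train`, `evaluate`, `reconstruct`, `drift-genes`,
`population`, `perturb` and `de` with a run manifest per output directory.

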