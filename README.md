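# smcotrack

Dual-color single-molecule co-localization/co-tracking analysis of membrane
receptor dimerization, with a Monte-Carlo simulator of membrane monomer–dimer
dynamics for ground-truth validation.

## What it does

Cytokine receptors such as gp130 signal by ligand-induced dimerization in the
plasma membrane. In dual-color single-molecule TIRF experiments, receptors are
stochastically labeled with two spectrally separable fluorophores and imaged
at video rate; a receptor dimer carrying one label of each color appears as a
pair of localizations that stay within a co-localization radius and move
together — a *co-locomotion trajectory*. `smcotrack` turns two per-frame
localization tables into a dimerization estimate:

1. **register** the spectral channels (least-squares affine fit to fiducial
   beads),
2. **link** localizations into trajectories (distance-gated nearest-neighbor
   assignment with gap closing; optional exact per-frame assignment),
3. **exclude** immobile particles (DBSCAN over each track's own points),
4. **filter** trajectories to a minimum of 10 steps (~320 ms at 32 ms/frame),
5. **co-localize** the channels frame-by-frame within a 100 nm radius and
   **re-link** the pair midpoints into co-trajectories,
6. **correct** the observed co-trajectory count `AB` for receptors
   stochastically double-labeled with the same fluorophore:

   ```
   AB* = AB / (2 · (A/(A+B)) · (B/(A+B)))
   rel. co-locomotion = 2 · AB* / (A + B)
   ```

   where `A` and `B` are the per-channel trajectory counts. The relative
   co-locomotion estimates the fraction of receptors residing in dimers
   (1 for a fully dimeric, fully labeled, balanced sample).

Mobility analysis accompanies the dimerization readout: ensemble MSD with a
`D = slope/4` fit over lags 2–10 (intercept absorbs the localization-error
offset `4σ²`), a two-fraction Brownian step-length mixture fitted by EM
(dimers diffuse measurably slower than monomers), and photobleaching
step counting (a dimer bleaches in two steps) via penalized change-point
segmentation.

The `sim_config()`/`simulate_membrane()`/`render_localizations()` simulator
generates the full study conditions — 150-frame movies at 32 ms/frame,
diffusing monomers and dimers, 50/50 two-color stochastic labeling with a
dark fraction, localization error, detection efficiency and bleaching — with
complete ground truth, so every stage of the pipeline is testable at desk
scale.

## Worked example

Simulate a movie with a true dimer fraction of 0.30 under default conditions
and quantify it:

```r
library(smcotrack)

cfg <- sim_config(dimer_fraction = 0.3, seed = 42)
cfg
#> sim_config: static_fraction
#>   ROI 20 x 20 um, 200 receptors, 150 frames @ 32 ms
#>   D(monomer) = 0.15, D(dimer) = 0.05 um^2/s
#>   dimer_fraction = 0.3
#>   labels: p(A) = 0.45, p(B) = 0.45, dark = 0.1; sigma_loc = 25 nm
#>   detection_eff = 1, bleach_rate = 0, boundary = reflective, seed = 42

truth <- simulate_membrane(cfg)
loc   <- render_localizations(truth, cfg)
quantify_dimerization(loc$a, loc$b)
#> dimerization_result:
#>   trajectories: A = 90, B = 92; co-trajectories AB = 12
#>   corrected AB* = 24.00; relative co-locomotion = 0.2638
#>   radius = 100 nm, min_steps = 10, immobile excluded: TRUE
```

Of the 200 receptors, ~90 are visible per channel; 12 two-color
co-trajectories survive the 10-step persistence filter, and the
double-labeling correction scales them to 24 dimers, i.e. a relative
co-locomotion of 0.26 — one movie's estimate of the true 0.30 (the slight
deficit is mostly the 10% dark-receptor fraction; the estimator is studied
over movie ensembles in `scripts/acceptance.R`). Mobility from the same
movie:

```r
tr_a <- filter_min_steps(link_localizations(loc$a), 10)
fit_diffusion_constant(compute_msd(tr_a))
#> D = 0.1206 +/- 0.00057 um^2/s (lags 2-10), intercept 4667.7 nm^2

steps <- c(step_lengths(tr_a),
           step_lengths(filter_min_steps(link_localizations(loc$b), 10)))
fit_step_length_mixture(steps, dt = 0.032, seed = 42, max_iter = 2000)
#> two-fraction Brownian mixture (n = 26810 steps):
#>   alpha = 0.759, D1 = 0.1688, D2 = 0.05603 um^2/s [converged]
```

The ensemble `D` falls between the monomer (0.15) and dimer (0.05) inputs,
and the mixture resolves the two populations (components are inflated by the
localization-error contribution `σ²/Δt ≈ 0.02 µm²/s`).

A thin command-line front end over the same functions is installed at
`system.file("cli", "smcotrack.R", package = "smcotrack")` with subcommands
`simulate`, `register`, `track`, `mobility`, `bleach`, `cotrack`, `run-all`.

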