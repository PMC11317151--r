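# smbridge

Analysis toolkit for three single-molecule assays used to characterise
DNA-bridging proteins such as the DNA-repair factor CtIP:

1. **Magnetic tweezers DNA bridging** — a bead-tethered ~4.3 kb dsDNA is
   cycled between a low force (0.1 pN, 1 min), at which a protein can bridge
   two distant segments of the tether, and a high force (4 pN, 3 min), at
   which bridges shorten the apparent extension until they rupture. The
   package converts absolute extension to relative extension Δz, extracts
   per-cycle features (Δz₀ and Δz₃‑min as the means of the first/last 12
   samples, rupture time τ as the first re-entry into the extended band
   |Δz| < 0.05 μm), classifies each cycle into the Class I–V bridging
   taxonomy, and estimates rupture kinetics with a right-censored
   Kaplan–Meier cumulative rupture probability. Forces are calibrated from
   transverse Brownian excursions via equipartition, F = k_BT·z/var(x).
2. **Kymograph single-particle tracking** — proteins diffusing on an
   optically trapped ~25 kb DNA are imaged by confocal line scans
   (22.4 ms/line, 100 nm pixels). The package localizes particles to
   sub-pixel precision, links them into trajectories (truncated to 2.5 s),
   computes time-averaged mean square displacements and fits
   MSD = 2·D·Δt + b to recover the 1D diffusion constant D, reported as the
   per-trajectory mean ± SEM alongside the ensemble fit.
3. **Equilibrium binding isotherms** — fluorescence anisotropy or quenching
   titrations are fitted by nonlinear least squares to a hyperbolic
   (f = T/(T+K_d)) or depletion-aware quadratic binding model to recover
   the dissociation constant K_d, with a seeded bootstrap confidence
   interval and a weak-binding flag when K_d exceeds the titration range.

Every pipeline has a matching synthetic-data generator with known ground
truth — a Marko–Siggia worm-like-chain tether with Ornstein–Uhlenbeck bead
noise obeying the inverted-pendulum relation, reflected Brownian particles
imaged with Poisson photon statistics, and parametric isotherms — so each
stage is testable end to end without instrument data.

## Worked example

Simulate one bead with a single bridge per force cycle (exponential
lifetimes, mean 26.3 s) and run the full Δz → features → classification
pipeline:

```r
library(smbridge)

protocol <- force_protocol()          # 10 s @ 4 pN, 5 x (0.1 pN / 4 pN) cycles
bridging <- bridging_params(bridge_formation_prob = 1,
                            mean_lifetime_s = 26.3,
                            loop_size_range_um = c(0.1, 0.5),
                            max_bridges = 1)
sim <- simulate_bead_timecourse(protocol, bridging = bridging, seed = 42)
tc  <- compute_relative_extension(sim, protocol)
records <- classify_events(extract_cycle_features(tc, protocol, smooth = TRUE))
records[, c("cycle", "dz0_um", "dz_end_um", "rupture_time_s", "event_class")]
#>   cycle     dz0_um     dz_end_um rupture_time_s event_class
#> 1     1 -0.4398705  0.0019937046       17.38333          II
#> 2     2 -0.2843662 -0.0017729602       38.50000          II
#> 3     3 -0.3502872 -0.0004078471       11.53333          II
#> 4     4 -0.1895130 -0.0005310454        2.15000          II
#> 5     5 -0.3004015  0.0031997890       39.35000          II
```

All five cycles start bridged (Δz₀ well below −0.05 μm) and rupture back to
the extended state within the 3-minute pulling step, so each is a Class II
event whose rupture time is the bridge lifetime; the recovered lifetimes
match the simulator's ground-truth event log to the sampling interval.

Fitting a noiseless anisotropy isotherm generated at K_d = 66 nM returns
the generating constant exactly:

```r
fit_isotherm(simulate_isotherm(66), n_boot = 0)
#> Binding isotherm fit (hyperbolic model, anisotropy readout)
#>   Kd = 66 nM
#>   signal: free 0.08, bound 0.2; RMSE 1.27e-17
```

A one-command synthetic regeneration of all three analyses is available via
the pipeline (`run_pipeline(run_config(system.file("extdata",
"demo_config.txt", package = "smbridge")))`) or the thin CLI in
`inst/cli/smbridge` (subcommands `simulate-mt`, `analyze-mt`,
`simulate-kymo`, `track`, `fit-binding`, `report`).

## Documentation

The methods vignette (`vignettes/smbridge-methods.Rmd`) describes the
models, the estimators, the synthetic-data generators and their
limitations, and the rationale for every tunable default.
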