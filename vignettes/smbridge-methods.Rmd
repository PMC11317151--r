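---
title: "Models and estimators in smbridge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators in smbridge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smbridge)
```

smbridge implements the analysis side of three single-molecule assays of
DNA-bridging proteins — magnetic-tweezers force cycling, confocal kymograph
tracking, and equilibrium titrations — together with generators that emulate
each instrument with known ground truth. This vignette records the models,
the estimator choices, and the reasoning behind every tunable default. All
lengths are micrometres, times seconds, forces piconewtons, concentrations
nanomolar.

## The tether: worm-like chain and bead noise

The tether is a double-stranded DNA modelled by the Marko–Siggia
interpolation of the worm-like chain,

$$F(x) = \frac{k_BT}{L_p}\left(\frac{1}{4(1-x/L)^2} - \frac14 +
\frac{x}{L}\right),$$

inverted numerically for the extension at a given force
(`wlc_extension()`). Defaults: contour length $L$ = 4292 bp × 0.34 nm/bp ≈
1.46 μm (the central duplex of the bridging substrate), persistence length
$L_p$ = 45 nm and $T$ = 298 K. The assay itself does not pin these elastic
constants down; 45 nm and 0.34 nm/bp are the standard dsDNA values at
physiological ionic strength and both are configurable in
`tether_model()`.

Bead fluctuations are an overdamped Ornstein–Uhlenbeck process. The
transverse coordinate obeys the inverted-pendulum relation
$\langle\delta x^2\rangle = k_BT\,z/F$ with corner time $\gamma/(F/z)$,
where $\gamma = 6\pi\eta r$ is the Stokes drag on the $r$ = 0.5 μm bead;
this is exactly the relation `calibrate_force()` inverts, so calibration
round-trips the simulator by construction of the physics, not of the code
paths (the two use independent formula implementations). The axial
(measured-extension) noise amplitude is not determined by equipartition
alone — in the real instrument it is dominated by camera tracking noise —
so it is a free parameter `z_noise_sd_um` with default 5 nm, a typical
camera-limited axial precision for a 1 μm bead tracked at 120 Hz at 4 pN.
Both noises are sampled at the instrument's 120 Hz.

## The bridging state machine

During each low-force relaxation step one new bridge may form with
probability `bridge_formation_prob` (subject to at most `max_bridges` = 3
concurrent bridges), sequestering a loop of contour drawn uniformly from
`loop_size_range_um`; the effective contour shortens accordingly, so the
observed extension loss at the pulling force is the fractional WLC
extension (≈ 0.92 at 4 pN) times the loop contour. During each pulling step
every active bridge ruptures after an exponential holding time with mean
`mean_lifetime_s`; bridges that outlast the step persist into later cycles
with a restarted (memoryless) clock. The mix of single and multiple
concurrent bridges is what produces single-rupture (Class II) versus
partial-rupture (Class III) cycles, and persistence across cycles produces
Class IV/V. Lifetimes are modelled as force-independent exponentials at the
4 pN pulling force; no Bell-type force dependence is exposed, because the
assay applies a single pulling force and provides no information to
constrain one.

## Magnetic-tweezers feature extraction and classification

`compute_relative_extension()` subtracts a per-tether baseline (the mean
extension over the initial high-force step) to give Δz, suppressing
anchoring-geometry variability. `extract_cycle_features()` then reduces
each pulling step to three numbers:

* Δz₀ — mean of the first 12 stored samples ("first 12 points" is read as a
  sample count, not a duration; `n_avg` is configurable);
* Δz₃‑min — mean of the last 12 samples;
* τ — elapsed time from pull start to the first sample with
  −0.05 < Δz < 0.05 μm, right-censored at the step duration when the band
  is never re-entered.

Rupture detection is a first-crossing rule on the raw samples by default.
An optional running-median pre-filter (`smooth = TRUE`, window 0.5 s)
exists for noisy data: a centred median only declares the crossing once
half its window is past the rupture, so it adds no detection delay while
making single-sample noise excursions into the band essentially impossible.
It is off by default so that noiseless traces are analysed verbatim.

Classification uses the band half-width 0.05 μm throughout: Class I
(extended at start), II (bridged, fully ruptured by the step end), III
(partial rupture: still bridged at the end but Δz₃‑min − Δz₀ ≥ 0.05 μm),
and stable bridges grouped into consecutive runs — length 1 is Class IV,
length ≥ 2 Class V. Three closures were genuinely open and are resolved as
follows, each towards the "less bridged" reading: |Δz₀| exactly at the
threshold is Class I; a difference exactly at the threshold is Class III;
elongation cycles (Δz₀ above the band) are labelled `excluded` rather than
Class I, since the extended-molecule acceptance band is two-sided and says
nothing about elongations. Stable runs spanning every cycle of a record are
excluded by default (configurable): a bridge that never ruptures within the
observation window has unidentifiable kinetics.

Rupture kinetics are summarised as the cumulative rupture probability
1 − S(t) with S the Kaplan–Meier estimator (via the `survival` package),
censoring non-rupturing cycles at the pull duration. Without censoring this
reduces exactly to the empirical CDF, which the tests verify. The pooled Δz
histogram integrates to 1 by construction (heights are densities); the
default bin width is 0.02 μm, and pooling is over every sample of every
pulling step of every bead — pooling one summary value per step is the
plausible alternative, available by subsetting, but per-sample pooling is
the default since it uses all the data. Class frequencies are reported per
cycle (a Class V run of three cycles counts three times); the counts are
also returned so the per-run alternative can be recomputed.

## Kymograph simulation, localization and linking

`simulate_kymograph()` places particles on a tether of length ~8.6 μm
(25 427 bp), moves them by reflected 1D Brownian motion with the configured
D, and renders each 22.4 ms line as Poisson counts whose expectation is the
Gaussian point-spread profile (σ = 0.15 μm) integrated over 100 nm pixels,
over a uniform background (2 photons/pixel), with optional single-step
photobleaching. Positions use the 0-based pixel-centre convention: the
centre of pixel 0 is coordinate 0.

`localize_lines()` thresholds each line at median + 5 robust σ (MAD with a
Poisson floor), keeps local maxima, and refines each candidate with an
iterative Gaussian-weighted centroid over ±3 PSF σ — a fixed point of this
iteration coincides with the true centre for a Gaussian spot, giving
sub-pixel accuracy without a nonlinear fit per line. The reported
uncertainty is the photon-limited σ/√N. `link_trajectories()` performs
greedy nearest-neighbour linking with a hard gate (default
5·√(2·D_prior·Δt) with D_prior = 5 μm²/s), gap closing up to 3 lines,
truncation of tracks to 2.5 s (to homogenise the per-trajectory variance),
and discards kymographs with more than two concurrent particles, mirroring
the acquisition rule for crowded molecules.

## Diffusion estimation on a finite tether

`compute_msd()` uses all overlapping pairs at each lag;
`estimate_diffusion()` fits MSD = 2DΔt + b over the first 5 lags by
weighted least squares (weights = pair counts), the intercept absorbing
static localization noise. Both a per-trajectory mean ± SEM and a fit to
the ensemble (pair-weighted) MSD are reported; the per-trajectory mean is
the headline because the corresponding experiments report a mean ± SEM over
trajectories.

Confinement needs care at these operating conditions: with D ≈ 4 μm²/s,
2.5 s tracks and an 8.6 μm tether, reflections at the tether ends depress a
naive MSD fit by roughly 15%. The standard remedy is exclusion: at lag k,
pairs whose *starting* position lies within
`margin_factor`·√(2·D·k·Δt) of either end are dropped, so retained pairs
are effectively free-diffusion pairs. Two subtleties shaped the
implementation:

* the margins are sized from a pooled first-pass estimate (the
  pair-weighted lag-1 MSD over all trajectories), never from the
  trajectory's own MSD — self-sizing couples each trajectory's pair
  selection to its own noise and visibly biases the per-trajectory mean;
* exclusion introduces a second, opposing bias on the *equal-weight*
  per-trajectory mean: trajectories that happen to take small steps stay
  inside the interior and contribute many small-displacement pairs, while
  wide-ranging trajectories contribute few, so aggressive exclusion biases
  the equal-weight mean upward even though the pair-weighted ensemble
  stays unbiased.

The default `margin_factor = 1.5` balances the residual reflection bias
against this selection bias; calibrated on synthetic ground truth across
D ∈ {0.5, 3.9, 10} μm²/s at the instrument geometry, the per-trajectory
mean is then unbiased to within ~3% (inside 2 SEM at the sample sizes
used), and the ensemble fit — unbiased for any margin ≥ 2 — is reported
alongside as a check. With `boundaries = NULL` no exclusion is applied and
closed-form cases (static particles, uniform drift) are reproduced exactly.

## Binding isotherms

Two non-cooperative single-site models are implemented: the hyperbolic
fraction bound $f = T/(T+K_d)$ ("simple binding model", the default) and
the depletion-aware quadratic
$f = \big(T+P+K_d - \sqrt{(T+P+K_d)^2 - 4TP}\big)/2P$ for probe
concentration P. The quadratic is offered because the 5 nM labelled probe
is not negligible against the smaller dissociation constants encountered;
the two agree to <0.1% as P → 0 (tested at P = 0.001 nM). Both readouts
share the linear two-state signal model
signal = s_free + (s_bound − s_free)·f; a quench readout simply has
s_bound < s_free, and anisotropy is fitted without intensity-weighting of
the bound and free species since the anisotropy probes show no evidence of
intensity change. Titrant concentrations are monomer units.

`fit_isotherm()` runs Levenberg–Marquardt least squares (`minpack.lm`) over
(K_d, s_free, s_bound) with data-driven starts (the plateaus from the
extreme titration points, K_d from inverse interpolation at the half
signal), requires ≥ 6 points spanning ≥ 1 decade, and reports a
residual-resampling bootstrap percentile interval (default 1000 seeded
resamples). A weak-binding flag is raised when the fitted K_d exceeds the
largest titrant concentration, the regime in which a reliable K_d cannot be
claimed. Noiseless generated isotherms are refitted to the generating K_d
to ~1e-6 relative accuracy; non-convergence raises an error rather than
falling back silently.

## What the generators emulate — and what they do not

The simulators reproduce the statistical structure the analyses depend on:
WLC elasticity, pendulum-law transverse noise, exponential rupture times,
reflected free diffusion, Poisson shot noise, bleaching. They deliberately
omit instrument drift, reference-bead correction, multiple-tether
artefacts, rotational bead dynamics, camera blur and aliasing, branched
substrates, and any force dependence of bridge lifetimes. Passing tests
therefore demonstrate that the estimators recover known parameters under
the stated noise models, not that every systematic of a real instrument is
handled; in particular, real traces with slow drift should be
baseline-corrected before `compute_relative_extension()` and analysed with
the median pre-filter enabled.

## Problem sizes and numerical choices

The test suite simulates at the instrument's native rates but modest
population sizes, chosen to keep the whole suite comfortably within a few
minutes while leaving every statistical assertion at ≥ 3σ separation:
30-bead populations (≈150 cycles) for end-to-end lifetime recovery, 200
five-cycle time courses per variant (≈1000 Class II events) in the
acceptance checks, 115 trajectories for diffusion recovery (matching the
reported trajectory count), and 120 noisy replicates per K_d for the
median-recovery property. The rupture-time distributional check simulates
at a reduced 4 Hz sampling rate because it reads the ground-truth event
log, not the trace. Degenerate inputs are rejected with instructive errors
(zero-duration protocols, pulling steps shorter than 2·n_avg samples,
titrations spanning less than a decade, zero-variance calibration input);
boundary cases in classification are resolved by the documented tie-breaks,
and negative fitted diffusion constants are flagged, never clipped.

## Known limitations

* The Class II lifetime is the time to re-enter the ±0.05 μm band, so
  bridges whose extension loss is comparable to the band (loops ≲ 60 nm
  of contour at 4 pN) are partly unresolvable: some are classified Class I
  outright and, with noise, the smallest remaining ones can cross early.
  At the short-loop settings used for the truncation-variant emulation
  this depresses the recovered mean lifetime by ~2–4%.
* Kaplan–Meier censoring assumes bridge survival is independent of the
  censoring time, which holds for the memoryless simulator but is an
  approximation for real bridges with ageing.
* The boundary-exclusion margin trades two small biases; at diffusion
  constants or track lengths far outside the calibrated regime the default
  factor should be re-examined (`margin_factor`, `boundaries` are exposed).
* The binding models are non-cooperative single-site forms; Hill
  coefficients and multi-site schemes are out of scope.
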