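# smtrack

Quantification tools for single-molecule imaging of DNA-repair proteins on
stretched DNA ("tightropes" and optically trapped lambda DNA), plus the
companion gel-based equilibrium analyses. The package targets experiments in
which a fluorescently labeled protein — for example a DNA glycosylase such
as AAG/MPG, or the damage sensor UV-DDB — binds a damaged DNA substrate and
is followed in a kymograph: who binds where, for how long, how it moves, and
whether two differently labeled proteins meet.

Because raw movies from such experiments are rarely deposited, the package
ships a first-class synthetic-data generator with full ground truth, so every
analysis stage can be validated closed-loop: simulate with known parameters,
analyze, and compare the recovered values against the truth.

## What it computes

**Motion.** Time-averaged mean squared displacement of a tracked particle,

    MSD(n Δt) = 1/(N−n) Σ_{i=1}^{N−n} (x_{i+n} − x_i)²,

fit by weighted nonlinear least squares to the anomalous-diffusion model

    MSD(n Δt) = 2 D (n Δt)^α + y,

with D ≥ 0, α ∈ (0, 2] and intercept y ≥ 0 (y reflects localization noise).
Fits with R² < 0.8 or using < 10% of the MSD curve are rejected. Particles
are classified motile/stationary × persistent/dissociated.

**Kinetics.** Binding dwell times from blink-merged tracks, exponential
lifetimes via survival decay (Kaplan–Meier, censoring-aware) or the
cumulative residence time distribution (CRTD) of completed events, a
photobleaching lifetime from per-second photon traces, and the
rate-subtraction bleach correction

    k_off = 1/τ_obs − 1/τ_bleach,  τ_corrected = 1/k_off.

**Colocalization.** Dual-channel pairing of tracks that stay within a
distance threshold for a minimum overlap time, plus on-/off-target
classification of events against a fiducial map of damage-site positions.

**Equilibria.** Gel lane fractions, the quadratic (ligand-depletion)
binding isotherm

    %bound = 100 · [(D + P + K_d) − √((D + P + K_d)² − 4 D P)] / (2 D),

used because the DNA concentration is in the same molar range as K_d,
excision fractions product/(product+substrate), and fold stimulation of
excision time courses.

## Worked example

```r
library(smtrack)

## photobleaching correction of an observed 2.8 s lifetime
obs  <- exponentialLifetime(2.8, se = 0.06)
gfp  <- exponentialLifetime(40.4, se = 6.3)   # fluorophore lifetime
correctPhotobleaching(obs, gfp)
#> LifetimeFit (external, bleach-corrected): tau = 3.009 s (SE 0.078),
#>   t1/2 = 2.085 s, n = 0 (+0 censored)

## closed loop: simulate motile particles, analyze their diffusion
cfg <- simConfig(nFrames = 300, diffusionCoefficient = 0.0211,
                 bindLifetime = 30, motileFraction = 1, rngSeed = 7)
sim <- simulateTrajectories(cfg, 40)
tr  <- mergeBlinkGaps(sim$tracks, maxGap = 2)
ph  <- analyzeMotion(tr, frameInterval = 0.1, localizationSigma = 0.02)
acc <- ph[ph$accepted, ]
c(meanD = mean(acc$D_um2_s), meanAlpha = mean(acc$alpha))
#>     meanD meanAlpha
#>    0.0224      1.01        # truth: D = 0.0211 um^2/s, alpha = 1

## binding lifetime with censoring at the 30 s observation window
fitSurvival(extractDwells(tr, 30), "survival_decay")
#> LifetimeFit (survival_decay): tau = 30.67 s (SE 1.08), t1/2 = 21.26 s,
#>   n = 26 (+14 censored)                     # truth: 30 s

## Kd from a simulated titration at 8 nM DNA with 2% noise
pts <- simulateIsotherm(6, 8, c(0,1,2,4,6,8,12,16,24,48), 2, seed = 2)
fitKd(pts)
#> KdFit: Kd = 5.742 nM (SE 0.246), R^2 = 0.996, 10 points at D = 8 nM
```

The recovered D (0.0224 vs 0.0211), lifetime (30.7 vs 30 s) and Kd (5.74 vs
6 nM) sit within the sampling error expected at these sample sizes.

A command-line wrapper over the same functions lives at
`inst/scripts/smtrack.R` with subcommands
`simulate | track | motion | kinetics | coloc | kd | excision | pipeline`.

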