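---
title: "Models and methods behind smtrack"
author: "smtrack authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smtrack)
```

# Scope

smtrack quantifies single-molecule experiments in which fluorescently
labeled DNA-repair proteins bind and move on stretched, damage-containing
DNA, imaged as kymographs (space × time), together with the companion
equilibrium and excision gel assays. This vignette documents the models,
the tunable parameters, the numerical choices, and what the synthetic-data
generator does and does not emulate.

# The synthetic-data generator

`simConfig()` + `simulateTrajectories()` draw particles under a two-state
model: a particle is either *stationary* (bound at a damage site) or
*motile*, performing a 1D displacement process with stationary power-law
increments,

$$\mathrm{Var}[x(t+k\,\Delta t) - x(t)] = 2D\,(k\,\Delta t)^{\alpha}.$$

For $\alpha = 1$ increments are iid Gaussian; for $\alpha \ne 1$ they are
fractional Gaussian noise with Hurst exponent $H = \alpha/2$, generated by
exact Davies–Harte circulant embedding (`fgnIncrements()`), so the fitted
model $\mathrm{MSD} = 2D(n\Delta t)^\alpha$ is exactly the generator's
truth at every lag, not only asymptotically. Tracks end at the first of
exponential dissociation (`bindLifetime`), exponential photobleaching
(`bleachLifetime`), or the end of the movie; fluorophore blinking is an
independent on/off telegraph process that hides frames without ending the
track. Gaussian localization noise of sd `localizationSigma` is added to
every reported position. Reflecting boundaries keep motile particles on
the substrate; increment statistics are therefore only exact away from the
substrate ends (tests use long substrates).

Default conditions mirror the imaging regimes the package targets: 10
frames/s for 5-minute movies (quantum-dot tightrope imaging runs at
~11–12.5 fps, trap-based kymographs at 10–30 fps), $D = 2.11\times10^{-2}$
µm²/s, $\alpha = 1$, one damage site every 2 kb, 0.34 µm/kb (B-form rise)
for kb↔µm conversion, and a 300 s observation window. Quantum-dot labels
do not bleach (`bleachLifetime = Inf`); a GFP-like label is emulated with
`bleachLifetime ≈ 40 s`. The generator exposes `motileFraction`
(default 0.3, representative of the motile fractions such experiments
report) to set the stationary/motile mix.

What the generator does *not* emulate: motion blur within a frame
(positions are sampled instantaneously), camera read noise and
pixel-response nonuniformity (shot noise plus a constant offset only),
crossing-trajectory identity swaps, chromatic offsets between channels,
and substrate fluctuations. Passing closed-loop tests therefore
demonstrates correctness of the estimators under this idealized imaging
model, not robustness to every real-data artifact.

`renderKymograph()` draws each frame column as a sum of Gaussian line
profiles (sd `psfSigma` pixels) normalized to `photonRate × frameInterval`
expected photons, applies Poisson shot noise, and adds a constant offset.
Photon counts are integers ≥ 0 before the offset.

`makeDamageLayout()` covers both substrate types: regular arrays (one site
every `spacing` kb) and explicit fiducial layouts, where sites closer than
the optical resolution limit merge into one observable site (at their mean
position) and sites within the bead margin of *either* end are dropped —
the canonical lambda-DNA layout reduces 10 designed nick sites to 8
observable ones.

# Tracking

`trackLines()` detects per-frame candidate peaks above the column median
plus `detectionThreshold` column-MADs, refines each by a bounded
Levenberg–Marquardt 1D Gaussian fit (subpixel center; intensity-weighted
centroid as fallback), and links centers frame-to-frame by nearest
neighbor within 3 pixels (ties to the smaller displacement). The linker
tolerates no dark frames; blink gaps are re-joined afterwards by
`mergeBlinkGaps()`, which connects segments separated by a dark gap
strictly shorter than 2 s (the boundary is exclusive) *and* by at most
`maxPositionJump` (default 0.5 µm ≈ 1.5 kb; the "same position" criterion
is nowhere quantified in the experimental literature, so it is explicit
and configurable here). Merging is transitive and idempotent. Tracks
shorter than 10 frames are discarded — at 10 fps shorter detections are
not distinguishable from noise. Overlapping same-id samples are a
consistency error; crossing particles may swap identities (documented
limitation; no multi-emitter deconvolution is attempted).

# Motion analysis

`computeMsd()` is the exact time-averaged estimator
$\mathrm{MSD}(n\Delta t) = \frac{1}{N-n}\sum_i (x_{i+n}-x_i)^2$ for lags
$n = 1 \ldots \lfloor 0.25\,N \rfloor$ by default — the first quarter of
the curve, which always satisfies the ≥ 10% coverage rule. Phases with
merged blink gaps are not interpolated; gaps break phases, because the
estimator requires uniform sampling.

`fitDiffusion()` fits $2D(n\Delta t)^\alpha + y$ by weighted least
squares. Two numerical choices matter:

* **Weights** are $(N-n)/n^2$, the inverse of the sampling variance of
  the time-averaged MSD (which grows like $n^2/(N-n)$ for Brownian
  motion). Weighting only by pair counts $(N-n)$ leaves the fit dominated
  by the long-lag tail, where single-trajectory MSDs fluctuate wildly,
  and admits a degenerate $\alpha \to 0$, $D \to \infty$ solution; with
  inverse-variance weights the estimator recovers the truth to within a
  few percent in the closed-loop tests.
* **The intercept is bounded at zero** by default. In the blur-free
  imaging model the true intercept is $2\sigma_\mathrm{loc}^2 \ge 0$;
  with a fully free intercept, trajectory-to-trajectory MSD fluctuations
  can be absorbed as (low $\alpha$, negative $y$), biasing the mean
  fitted $\alpha$ well below 1. Instruments with appreciable motion blur
  can have genuinely negative intercepts; pass `yMin = -Inf` there.

$\alpha$ is bounded to $(0, 2]$; boundary fits (e.g. exactly ballistic
$\alpha = 2$) are reported as such. $R^2$ is computed in the same
weighted metric the fit minimizes. A fit is *accepted* only when
$R^2 \ge 0.8$ and at least 10% of the available MSD lags were used;
non-convergence yields a rejected fit with a diagnostic, never an
exception.

Phase segmentation (`segmentPhases()`) is not specified by the
experimental literature, so the package uses a transparent sliding-window
displacement test: a frame is motile when the windowed empirical MSD over
lags 1–3 exceeds the localization-noise floor $4\sigma_\mathrm{loc}^2$ by
a configurable factor (default 3). Runs shorter than `minPhaseFrames` are
absorbed into their predecessor. Summaries treat phases independently
(per-phase n), matching how such experiments count phases; per-particle
aggregation is available by grouping on `track_id`.

# Binding kinetics

`extractDwells()` takes one dwell per blink-merged track (last minus
first detected time) and right-censors events still present at the end of
the observation window. `fitSurvival()` offers two estimators:

* **survival_decay** — a Kaplan–Meier product-limit estimate of the
  surviving fraction (censored events contribute while under
  observation) fit to $A e^{-t/\tau}$ with weights $n_\mathrm{risk}$. The
  amplitude is free because a minimum-duration cut makes the estimated
  curve the *conditional* survival given passing the cut — exponential
  with the same $\tau$ but amplitude ≠ 1.
* **crtd** — the cumulative residence time distribution: the cumulative
  count of completed events by duration (one point per unique duration,
  so frame-discretized ties do not overweight the staircase), fit to
  $A(1 - e^{-t/\tau})$.

Both report $\tau$, its standard error from the fit covariance, and
$t_{1/2} = \tau \ln 2$. Dwells shorter than a configurable minimum
(single-frame detections) can be excluded via `minDuration`.

`estimateBleachLifetime()` fits $A e^{-t/\tau} + c$ to per-second photon
counts; a fitted $\tau$ beyond 10× the trace span (or negligible
amplitude) is flagged "no appreciable bleaching" ($\tau = \infty$).
`correctPhotobleaching()` treats dissociation and bleaching as
independent competing exponentials, so the observed rate is their sum and
$k_\mathrm{off} = 1/\tau_\mathrm{obs} - 1/\tau_\mathrm{bleach}$; standard
errors propagate to first order. The correction is undefined (an error)
when $\tau_\mathrm{obs} \ge \tau_\mathrm{bleach}$, and an infinite bleach
lifetime returns the observed lifetime unchanged. For a 2.8 s observed
lifetime against a 40.4 s bleach lifetime the correction adds ≈ 0.2 s.

Observation windows much shorter than the lifetime leave $\tau$ poorly
identified; the fit reports whatever the window supports (amplitude,
$\tau$, SE) rather than guessing an extrapolation procedure, and the
censored count makes the extrapolation burden visible.

# Colocalization

`callColocalization()` declares a pair colocalized when the two tracks
stay within `distanceThreshold` (default 0.5 µm) for at least
`minOverlap` (default 1 s) of co-existing time; experimental reports of
"overlapping signals" state no numeric thresholds, so both are explicit.
Pairing is greedy one-to-one by descending overlap (ties to smaller mean
distance) — simpler than optimal assignment, and equal to the exhaustive
optimum on the small instances the test suite enumerates. Whether a
colocalized fraction is quoted per distinct entity or per molecule is
ambiguous in the literature, so both denominators are reported
(`fraction_of_entities`, `fraction_of_molecules`). `classifyOnTarget()`
marks an event on-target when its distance to the nearest *observable*
fiducial site is at most the window (default ±1 kb, half the 2 kb array
spacing); under a uniform null the expected on-target fraction is the
covered length fraction, which the tests verify against binomial bounds.

# Equilibria

`fractionBoundModel()` implements the quadratic (ligand-depletion)
isotherm — the physical root of the mass-action quadratic — required
because the DNA concentration (8 nM) is in the same molar range as the
$K_d$ values (≈ 2–32 nM); a hyperbolic fit would be biased. `fitKd()`
estimates $K_d$ by least squares with the start value taken at
half-maximal binding; all points are weighted equally, and replicate
titrations are fit individually in the closed-loop tests with the median
reported. `laneFractions()` subtracts background per band, clipping
negatives to zero with a warning (whether the original analyses
subtracted per band or per lane is not stated). Fold stimulation is
reported per timepoint with a summary at the earliest timepoint where the
unstimulated fraction reaches 0.05, avoiding 0/0 instability; note the
early-time fold approaches the *rate* ratio, which exceeds the
plateau-region fold.

# Numerical choices and degenerate inputs

All nonlinear fits go through a bounded Levenberg–Marquardt wrapper that
returns the optimum even when the Jacobian is singular there (common at
parameter bounds, e.g. $D = 0$), with standard errors from
$\sigma^2 (J^\top J)^{-1}$ and NA where that matrix is singular.
Degenerate inputs follow a consistent policy: empty inputs yield empty
results (blank kymograph, empty fiducial map with a warning, empty
behavior tables without division by zero); impossible requests are
errors naming the violated precondition (all-censored dwell sets,
all-zero lanes, titrations without a transition, zero DNA concentration);
poor fits are flagged, not raised.

# Problem sizes

The test suite and the acceptance script run at desk scale, chosen so
that sampling error — not runtime — dominates the tolerances: 50 motile
phases of 300 frames for diffusion recovery, 500–2000 dwells per lifetime
fit, 50 replicate titrations per $K_d$, 500 particles per channel for
colocalization recall, and 10⁴ events for the on-target null. Each
reported quantity carries the problem size used.

# Known limitations

No hidden-Markov phase inference, no 2D/3D imaging, no multi-exponential
dwell models beyond a goodness-of-fit flag, no spectral unmixing or
chromatic registration, no gel densitometry (band intensities are
inputs), and no modeling of bead/trap mechanics or DNA force-extension.
Kymograph containers are TIFF + JSON sidecar; tables are CSV.
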