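#' @import methods
NULL

#' Simulation configuration for synthetic single-molecule data
#'
#' Holds every ground-truth parameter of the synthetic-data generator:
#' imaging cadence, motion model, photophysics, and substrate geometry.
#' Time constants may be \code{Inf} to disable the corresponding process
#' (e.g. \code{bleachLifetime = Inf} for non-bleaching labels such as
#' quantum dots).
#'
#' @slot frameInterval seconds per frame (0.1 s at 10 fps).
#' @slot nFrames number of frames in the movie.
#' @slot diffusionCoefficient 1D diffusion coefficient, um^2/s.
#' @slot alpha anomalous diffusion exponent, in (0, 2].
#' @slot localizationSigma per-frame Gaussian localization error sd, um.
#' @slot bindLifetime exponential mean of the bound-state dwell, s.
#' @slot bleachLifetime exponential mean of fluorophore survival, s.
#' @slot blinkOnLifetime,blinkOffLifetime exponential means of the
#'   fluorescent on/off telegraph process, s.
#' @slot photonRate expected photons per second from one emitter.
#' @slot psfSigma Gaussian line-profile sd, pixels.
#' @slot pixelSize um per pixel.
#' @slot dnaLength substrate length, kb.
#' @slot siteSpacing damage-site spacing, kb.
#' @slot kbToUm um per kb (0.34 for B-form DNA).
#' @slot motileFraction probability that a particle diffuses rather than
#'   remaining stationary at a site.
#' @slot rngSeed integer seed, or NA to leave the RNG state untouched.
#' @export
setClass("SimulationConfig",
  representation(
    frameInterval = "numeric", nFrames = "numeric",
    diffusionCoefficient = "numeric", alpha = "numeric",
    localizationSigma = "numeric",
    bindLifetime = "numeric", bleachLifetime = "numeric",
    blinkOnLifetime = "numeric", blinkOffLifetime = "numeric",
    photonRate = "numeric", psfSigma = "numeric", pixelSize = "numeric",
    dnaLength = "numeric", siteSpacing = "numeric", kbToUm = "numeric",
    motileFraction = "numeric", rngSeed = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  pos <- function(x) length(x) == 1L && is.finite(x) && x > 0
  if (!pos(object@frameInterval)) msg <- c(msg, "frameInterval must be finite and > 0")
  if (!(object@nFrames >= 1)) msg <- c(msg, "nFrames must be >= 1")
  if (!(object@diffusionCoefficient >= 0)) msg <- c(msg, "diffusionCoefficient must be >= 0")
  if (!(object@alpha > 0 && object@alpha <= 2)) msg <- c(msg, "alpha must lie in (0, 2]")
  if (!(object@localizationSigma >= 0)) msg <- c(msg, "localizationSigma must be >= 0")
  for (s in c("bindLifetime", "bleachLifetime", "blinkOnLifetime", "blinkOffLifetime")) {
    v <- slot(object, s)
    if (!(length(v) == 1L && !is.na(v) && v > 0))
      msg <- c(msg, sprintf("%s must be > 0 (Inf disables the process)", s))
  }
  if (!pos(object@photonRate)) msg <- c(msg, "photonRate must be > 0")
  if (!pos(object@psfSigma)) msg <- c(msg, "psfSigma must be > 0")
  if (!pos(object@pixelSize)) msg <- c(msg, "pixelSize must be > 0")
  if (!pos(object@kbToUm)) msg <- c(msg, "kbToUm must be > 0")
  if (!(object@dnaLength > 0)) msg <- c(msg, "dnaLength must be > 0")
  if (!(object@siteSpacing > 0)) msg <- c(msg, "siteSpacing must be > 0")
  if (object@dnaLength < object@siteSpacing)
    msg <- c(msg, "dnaLength must be >= siteSpacing")
  if (!(object@motileFraction >= 0 && object@motileFraction <= 1))
    msg <- c(msg, "motileFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults mirror a quantum-dot tightrope experiment: 10 fps for 5 min,
#' D = 2.11e-2 um^2/s, Brownian motion (alpha = 1), a 20 kb substrate with
#' one damage site every 2 kb, and non-bleaching labels. Pass
#' \code{bleachLifetime = 40.4} and \code{blinkOnLifetime}/
#' \code{blinkOffLifetime} for a GFP-like fluorophore.
#'
#' @param frameInterval,nFrames imaging cadence (s per frame) and movie length.
#' @param diffusionCoefficient,alpha motion model (um^2/s; exponent in (0,2]).
#' @param localizationSigma localization noise sd, um.
#' @param bindLifetime,bleachLifetime,blinkOnLifetime,blinkOffLifetime time
#'   constants in s; Inf disables.
#' @param photonRate,psfSigma,pixelSize rendering parameters.
#' @param dnaLength,siteSpacing,kbToUm substrate geometry (kb; um/kb).
#' @param motileFraction probability a particle is motile.
#' @param rngSeed integer seed or NA.
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simConfig(nFrames = 100, diffusionCoefficient = 0.02)
#' @export
simConfig <- function(frameInterval = 0.1, nFrames = 3000,
                      diffusionCoefficient = 0.0211, alpha = 1,
                      localizationSigma = 0.02,
                      bindLifetime = Inf, bleachLifetime = Inf,
                      blinkOnLifetime = Inf, blinkOffLifetime = 0.5,
                      photonRate = 500, psfSigma = 1.5, pixelSize = 0.1,
                      dnaLength = 20, siteSpacing = 2, kbToUm = 0.34,
                      motileFraction = 0.3, rngSeed = NA_real_) {
  new("SimulationConfig",
      frameInterval = frameInterval, nFrames = nFrames,
      diffusionCoefficient = diffusionCoefficient, alpha = alpha,
      localizationSigma = localizationSigma,
      bindLifetime = bindLifetime, bleachLifetime = bleachLifetime,
      blinkOnLifetime = blinkOnLifetime, blinkOffLifetime = blinkOffLifetime,
      photonRate = photonRate, psfSigma = psfSigma, pixelSize = pixelSize,
      dnaLength = dnaLength, siteSpacing = siteSpacing, kbToUm = kbToUm,
      motileFraction = motileFraction, rngSeed = as.numeric(rngSeed))
}

#' Kymograph: space-versus-time fluorescence image
#'
#' A matrix of intensities with rows as spatial pixels along the DNA and
#' columns as frames, plus the physical metadata needed to convert pixel
#' and frame indices to um and seconds.
#'
#' @slot image numeric matrix, space pixels x time frames; finite, >= 0.
#' @slot pixelSize um per pixel.
#' @slot frameInterval s per frame.
#' @slot channel channel label.
#' @export
setClass("Kymograph",
  representation(image = "matrix", pixelSize = "numeric",
                 frameInterval = "numeric", channel = "character"))

setValidity("Kymograph", function(object) {
  msg <- character()
  if (!is.numeric(object@image) || nrow(object@image) < 1L || ncol(object@image) < 1L)
    msg <- c(msg, "image must be a non-empty numeric matrix")
  else if (!all(is.finite(object@image)) || any(object@image < 0))
    msg <- c(msg, "image intensities must be finite and >= 0")
  if (!(length(object@pixelSize) == 1L && object@pixelSize > 0))
    msg <- c(msg, "pixelSize must be > 0")
  if (!(length(object@frameInterval) == 1L && object@frameInterval > 0))
    msg <- c(msg, "frameInterval must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param image,pixelSize,frameInterval,channel see slots of
#'   \linkS4class{Kymograph}.
#' @rdname Kymograph-class
#' @export
Kymograph <- function(image, pixelSize, frameInterval, channel = "A") {
  new("Kymograph", image = image, pixelSize = pixelSize,
      frameInterval = frameInterval, channel = channel)
}

#' Fiducial map of damage-site positions along a substrate
#'
#' Stores both the designed ("input") sites and the observable sites after
#' applying the optical resolution limit (unresolved neighbours merge into
#' one site) and the bead-exclusion margin (sites too close to either
#' anchoring bead are dropped).
#'
#' @slot substrateLength substrate length.
#' @slot sites observable site positions, strictly increasing.
#' @slot inputSites designed site positions.
#' @slot resolutionLimit two sites closer than this merge into one.
#' @slot beadMargin sites within this distance of either end are dropped.
#' @slot units "kb" or "um".
#' @export
setClass("FiducialMap",
  representation(substrateLength = "numeric", sites = "numeric",
                 inputSites = "numeric", resolutionLimit = "numeric",
                 beadMargin = "numeric", units = "character"))

setValidity("FiducialMap", function(object) {
  msg <- character()
  s <- object@sites
  if (length(s) && (any(s < 0) || any(s > object@substrateLength)))
    msg <- c(msg, "sites must lie within [0, substrateLength]")
  if (length(s) > 1L && any(diff(s) <= 0))
    msg <- c(msg, "sites must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Time-averaged mean squared displacement curve
#'
#' @slot lag lag times n*dt, s (lag 0 excluded).
#' @slot msd MSD values, um^2.
#' @slot nFrames total frames N in the phase.
#' @slot nPairs number of averaged displacement pairs (N - n) per lag.
#' @export
setClass("MsdCurve",
  representation(lag = "numeric", msd = "numeric",
                 nFrames = "integer", nPairs = "integer"))

setValidity("MsdCurve", function(object) {
  msg <- character()
  if (length(object@lag) != length(object@msd) ||
      length(object@lag) != length(object@nPairs))
    msg <- c(msg, "lag, msd and nPairs must have equal length")
  if (any(object@msd < 0)) msg <- c(msg, "MSD values must be >= 0")
  if (any(object@lag <= 0)) msg <- c(msg, "lag 0 is excluded")
  if (length(object@lag) > object@nFrames - 1L)
    msg <- c(msg, "at most N - 1 lags")
  if (length(msg)) msg else TRUE
})

#' Anomalous-diffusion fit of an MSD curve
#'
#' Parameters of MSD(n*dt) = 2 D (n*dt)^alpha + y fitted by nonlinear least
#' squares, with the acceptance filter (R^2 >= 0.8 and >= 10% of the MSD
#' curve used) recorded in \code{accepted}.
#'
#' @slot D diffusion coefficient, um^2/s (um^2/s^alpha for alpha != 1).
#' @slot alpha anomalous exponent, in (0, 2].
#' @slot intercept y-intercept, um^2 (reflects localization noise).
#' @slot r2 coefficient of determination.
#' @slot fractionUsed fraction of the available MSD lags fitted.
#' @slot accepted filter outcome.
#' @slot message fit diagnostic ("" when clean).
#' @export
setClass("DiffusionFit",
  representation(D = "numeric", alpha = "numeric", intercept = "numeric",
                 r2 = "numeric", fractionUsed = "numeric",
                 accepted = "logical", message = "character"))

setValidity("DiffusionFit", function(object) {
  msg <- character()
  if (!is.na(object@D) && object@D < 0) msg <- c(msg, "D must be >= 0")
  if (isTRUE(object@accepted) &&
      (is.na(object@r2) || object@r2 < 0.8 || object@fractionUsed < 0.10))
    msg <- c(msg, "accepted fits require R^2 >= 0.8 and >= 10% coverage")
  if (length(msg)) msg else TRUE
})

#' Exponential binding-lifetime fit
#'
#' @slot tau lifetime, s.
#' @slot halfLife tau * ln 2, s.
#' @slot amplitude fitted amplitude (survival starts at 1; CRTD ends at the
#'   number of completed events).
#' @slot se standard error of tau, s.
#' @slot nEvents,nCensored event counts.
#' @slot r2 coefficient of determination of the fit.
#' @slot method "survival_decay", "crtd" or "bleach_trace".
#' @slot bleachCorrected whether the photobleaching correction was applied.
#' @slot noBleaching flag set by \code{estimateBleachLifetime} when the
#'   trace does not decay appreciably.
#' @export
setClass("LifetimeFit",
  representation(tau = "numeric", halfLife = "numeric", amplitude = "numeric",
                 se = "numeric", nEvents = "integer", nCensored = "integer",
                 r2 = "numeric", method = "character",
                 bleachCorrected = "logical", noBleaching = "logical"))

setValidity("LifetimeFit", function(object) {
  msg <- character()
  if (is.finite(object@tau) && object@tau <= 0) msg <- c(msg, "tau must be > 0")
  if (is.finite(object@tau) &&
      abs(object@halfLife - object@tau * log(2)) > 1e-9 * object@tau)
    msg <- c(msg, "halfLife must equal tau * ln 2")
  if (length(msg)) msg else TRUE
})

.lifetimeFit <- function(tau, amplitude = 1, se = NA_real_, nEvents = 0L,
                         nCensored = 0L, r2 = NA_real_, method = "survival_decay",
                         bleachCorrected = FALSE, noBleaching = FALSE) {
  new("LifetimeFit", tau = tau, halfLife = tau * log(2), amplitude = amplitude,
      se = se, nEvents = as.integer(nEvents), nCensored = as.integer(nCensored),
      r2 = r2, method = method, bleachCorrected = bleachCorrected,
      noBleaching = noBleaching)
}

#' Quadratic (ligand-depletion) binding-isotherm fit
#'
#' @slot kd equilibrium dissociation constant, nM.
#' @slot se standard error of Kd, nM.
#' @slot r2 coefficient of determination.
#' @slot nPoints number of titration points fitted.
#' @slot dnaConc fixed total DNA concentration, nM.
#' @export
setClass("KdFit",
  representation(kd = "numeric", se = "numeric", r2 = "numeric",
                 nPoints = "integer", dnaConc = "numeric"))

setValidity("KdFit", function(object) {
  if (!is.na(object@kd) && object@kd <= 0) "Kd must be > 0" else TRUE
})

#' Dual-color colocalization result
#'
#' @slot counts named integer vector: a_only, b_only, colocalized.
#' @slot pairs data.frame of matched pairs (a_id, b_id, overlap_s, mean_dist_um).
#' @slot fractions named numeric vector: fraction_of_entities (a colocalized
#'   pair counted once among all distinct entities) and fraction_of_molecules
#'   (colocalized molecules over all molecules in both channels).
#' @export
setClass("ColocalizationResult",
  representation(counts = "integer", pairs = "data.frame",
                 fractions = "numeric"))

setValidity("ColocalizationResult", function(object) {
  msg <- character()
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (length(msg)) msg else TRUE
})
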