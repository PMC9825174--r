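#' @include AllClasses.R
NULL

#' Accessors for smtrack S4 objects
#'
#' Small accessor generics so user code never touches slots directly:
#' \code{tau} and \code{halfLife} for \linkS4class{LifetimeFit},
#' \code{diffusionCoefficient} / \code{alphaExponent} / \code{isAccepted}
#' for \linkS4class{DiffusionFit}, \code{kd} for \linkS4class{KdFit},
#' \code{sites} for \linkS4class{FiducialMap}, \code{kymoImage},
#' \code{pixelSize} and \code{frameInterval} for \linkS4class{Kymograph},
#' \code{msdLags} / \code{msdValues} for \linkS4class{MsdCurve}, and
#' \code{colocCounts} / \code{colocFractions} for
#' \linkS4class{ColocalizationResult}.
#'
#' @param object an smtrack S4 object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tau", function(object) standardGeneric("tau"))
#' @rdname accessors
#' @export
setMethod("tau", "LifetimeFit", function(object) object@tau)

#' @rdname accessors
#' @export
setGeneric("halfLife", function(object) standardGeneric("halfLife"))
#' @rdname accessors
#' @export
setMethod("halfLife", "LifetimeFit", function(object) object@halfLife)

#' @rdname accessors
#' @export
setGeneric("tauSE", function(object) standardGeneric("tauSE"))
#' @rdname accessors
#' @export
setMethod("tauSE", "LifetimeFit", function(object) object@se)

#' @rdname accessors
#' @export
setGeneric("diffusionCoefficient", function(object) standardGeneric("diffusionCoefficient"))
#' @rdname accessors
#' @export
setMethod("diffusionCoefficient", "DiffusionFit", function(object) object@D)

#' @rdname accessors
#' @export
setGeneric("alphaExponent", function(object) standardGeneric("alphaExponent"))
#' @rdname accessors
#' @export
setMethod("alphaExponent", "DiffusionFit", function(object) object@alpha)

#' @rdname accessors
#' @export
setGeneric("isAccepted", function(object) standardGeneric("isAccepted"))
#' @rdname accessors
#' @export
setMethod("isAccepted", "DiffusionFit", function(object) object@accepted)

#' @rdname accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))
#' @rdname accessors
#' @export
setMethod("rSquared", "DiffusionFit", function(object) object@r2)
#' @rdname accessors
#' @export
setMethod("rSquared", "LifetimeFit", function(object) object@r2)
#' @rdname accessors
#' @export
setMethod("rSquared", "KdFit", function(object) object@r2)

#' @rdname accessors
#' @export
setGeneric("kd", function(object) standardGeneric("kd"))
#' @rdname accessors
#' @export
setMethod("kd", "KdFit", function(object) object@kd)

#' @rdname accessors
#' @export
setGeneric("kdSE", function(object) standardGeneric("kdSE"))
#' @rdname accessors
#' @export
setMethod("kdSE", "KdFit", function(object) object@se)

#' @rdname accessors
#' @export
setGeneric("sites", function(object) standardGeneric("sites"))
#' @rdname accessors
#' @export
setMethod("sites", "FiducialMap", function(object) object@sites)

#' @rdname accessors
#' @export
setGeneric("kymoImage", function(object) standardGeneric("kymoImage"))
#' @rdname accessors
#' @export
setMethod("kymoImage", "Kymograph", function(object) object@image)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "Kymograph", function(object) object@pixelSize)

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setMethod("frameInterval", "Kymograph", function(object) object@frameInterval)

#' @rdname accessors
#' @export
setGeneric("msdLags", function(object) standardGeneric("msdLags"))
#' @rdname accessors
#' @export
setMethod("msdLags", "MsdCurve", function(object) object@lag)

#' @rdname accessors
#' @export
setGeneric("msdValues", function(object) standardGeneric("msdValues"))
#' @rdname accessors
#' @export
setMethod("msdValues", "MsdCurve", function(object) object@msd)

#' @rdname accessors
#' @export
setGeneric("colocCounts", function(object) standardGeneric("colocCounts"))
#' @rdname accessors
#' @export
setMethod("colocCounts", "ColocalizationResult", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("colocFractions", function(object) standardGeneric("colocFractions"))
#' @rdname accessors
#' @export
setMethod("colocFractions", "ColocalizationResult", function(object) object@fractions)

#' @rdname accessors
#' @export
setGeneric("colocPairs", function(object) standardGeneric("colocPairs"))
#' @rdname accessors
#' @export
setMethod("colocPairs", "ColocalizationResult", function(object) object@pairs)

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nFrames, "frames @",
      sprintf("%.3g s/frame", object@frameInterval), "\n")
  cat(sprintf("  motion: D = %.4g um^2/s, alpha = %.3g, loc sd = %.3g um, motile fraction %.2g\n",
              object@diffusionCoefficient, object@alpha,
              object@localizationSigma, object@motileFraction))
  cat(sprintf("  lifetimes (s): bind %.4g, bleach %.4g, blink on/off %.4g/%.4g\n",
              object@bindLifetime, object@bleachLifetime,
              object@blinkOnLifetime, object@blinkOffLifetime))
  cat(sprintf("  substrate: %.3g kb, site every %.3g kb, %.3g um/kb\n",
              object@dnaLength, object@siteSpacing, object@kbToUm))
})

setMethod("show", "Kymograph", function(object) {
  cat(sprintf("Kymograph [%s]: %d px x %d frames (%.3g um/px, %.3g s/frame)\n",
              object@channel, nrow(object@image), ncol(object@image),
              object@pixelSize, object@frameInterval))
})

setMethod("show", "FiducialMap", function(object) {
  cat(sprintf("FiducialMap: %d observable / %d input sites on %.3g %s\n",
              length(object@sites), length(object@inputSites),
              object@substrateLength, object@units))
})

setMethod("show", "DiffusionFit", function(object) {
  cat(sprintf("DiffusionFit: D = %.4g um^2/s, alpha = %.3g, y = %.3g um^2, R^2 = %.3f [%s]\n",
              object@D, object@alpha, object@intercept, object@r2,
              if (isTRUE(object@accepted)) "accepted" else "rejected"))
})

setMethod("show", "LifetimeFit", function(object) {
  cat(sprintf("LifetimeFit (%s%s): tau = %.4g s (SE %.3g), t1/2 = %.4g s, n = %d (+%d censored)\n",
              object@method,
              if (object@bleachCorrected) ", bleach-corrected" else "",
              object@tau, object@se, object@halfLife,
              object@nEvents, object@nCensored))
})

setMethod("show", "KdFit", function(object) {
  cat(sprintf("KdFit: Kd = %.4g nM (SE %.3g), R^2 = %.3f, %d points at D = %.3g nM\n",
              object@kd, object@se, object@r2, object@nPoints, object@dnaConc))
})

setMethod("show", "ColocalizationResult", function(object) {
  cat(sprintf("ColocalizationResult: %d colocalized, %d A-only, %d B-only (%.1f%% of molecules)\n",
              object@counts[["colocalized"]], object@counts[["a_only"]],
              object@counts[["b_only"]],
              100 * object@fractions[["fraction_of_molecules"]]))
})
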