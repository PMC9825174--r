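#' @include AllClasses.R
NULL

#' Extract binding dwell times from tracks
#'
#' One dwell per (blink-merged) track: duration is the last minus the first
#' detected time; an event still present at the end of the observation
#' window is right-censored, so its duration is a lower bound.
#'
#' @param tracks blink-merged track table.
#' @param observationWindow movie length, s.
#' @return data.frame: particle_id, channel, start_s, end_s, duration_s,
#'   censored, on_target (NA).
#' @export
extractDwells <- function(tracks, observationWindow) {
  ids <- unique(tracks$particle_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    tr <- tracks[tracks$particle_id == id, ]
    s <- min(tr$time_s); e <- max(tr$time_s)
    cens <- if (!is.null(tr$censored_end)) any(tr$censored_end) else FALSE
    cens <- cens || e >= observationWindow - 1e-9
    data.frame(particle_id = id, channel = tr$channel[1],
               start_s = s, end_s = e, duration_s = e - s,
               censored = cens, on_target = NA, stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(particle_id = character(), channel = character(),
                      start_s = numeric(), end_s = numeric(),
                      duration_s = numeric(), censored = logical(),
                      on_target = logical(), stringsAsFactors = FALSE)
  if (any(out$duration_s < 0)) stop("negative dwell duration")
  out
}

#' Fit an exponential binding lifetime
#'
#' \code{method = "survival_decay"}: a product-limit (Kaplan-Meier)
#' estimate of the surviving fraction S(t) -- so right-censored events
#' contribute while under observation -- is fit to S(t) = exp(-t/tau).
#' \code{method = "crtd"}: the cumulative residence time distribution of
#' completed events (cumulative count of events with duration <= t) is fit
#' to A (1 - exp(-t/tau)). Both return the lifetime tau, its standard
#' error, and the half-life t1/2 = tau ln 2.
#'
#' @param dwells dwell table (duration_s, censored).
#' @param method "survival_decay" or "crtd".
#' @param minEvents minimum number of uncensored events (default 10).
#' @param minDuration drop dwells shorter than this, s (single-frame
#'   detections are indistinguishable from noise); default 0.
#' @return A \linkS4class{LifetimeFit}.
#' @export
fitSurvival <- function(dwells, method = c("survival_decay", "crtd"),
                        minEvents = 10, minDuration = 0) {
  method <- match.arg(method)
  dwells <- dwells[dwells$duration_s >= minDuration, , drop = FALSE]
  nUnc <- sum(!dwells$censored)
  nCens <- sum(dwells$censored)
  if (nUnc == 0L) stop("all events censored: lifetime unidentifiable")
  if (nUnc < minEvents)
    stop(sprintf("need >= %d uncensored events, got %d", minEvents, nUnc))
  if (method == "survival_decay") {
    sf <- survival::survfit(
      survival::Surv(dwells$duration_s, !dwells$censored) ~ 1)
    keep <- sf$surv > 0
    t <- sf$time[keep]; s <- sf$surv[keep]; w <- sf$n.risk[keep]
    # free amplitude: with a minimum-duration cut the product-limit curve
    # estimates survival conditional on passing the cut, A * exp(-t/tau)
    fit <- .lmCurveFit(function(p) p[["A"]] * exp(-t / p[["tau"]]),
      s, start = list(A = 1, tau = mean(dwells$duration_s)),
      lower = c(.Machine$double.eps, .Machine$double.eps), weights = w)
    .lifetimeFit(unname(fit$par["tau"]), amplitude = unname(fit$par["A"]),
                 se = unname(fit$se["tau"]), nEvents = nUnc,
                 nCensored = nCens, r2 = fit$r2, method = "survival_decay")
  } else {
    dAll <- sort(dwells$duration_s[!dwells$censored])
    d <- unique(dAll)                       # CDF value at each unique time
    cnt <- cumsum(tabulate(match(dAll, d)))
    fit <- .lmCurveFit(function(p) p[["A"]] * (1 - exp(-d / p[["tau"]])),
      cnt, start = list(A = length(dAll), tau = mean(dAll)),
      lower = c(1, .Machine$double.eps))
    .lifetimeFit(unname(fit$par["tau"]), amplitude = unname(fit$par["A"]),
                 se = unname(fit$se["tau"]), nEvents = nUnc,
                 nCensored = nCens, r2 = fit$r2, method = "crtd")
  }
}

#' Estimate the photobleaching lifetime from a photon trace
#'
#' Photon counts binned per second of continuous exposure are fit to a
#' single-exponential decay A exp(-t/tau) + c. A trace whose fitted tau
#' exceeds \code{maxTauFactor} times the trace span (or whose decay
#' amplitude is negligible) is flagged as showing no appreciable bleaching
#' (tau = Inf, \code{noBleaching} slot set).
#'
#' @param trace data.frame with columns bin_s and counts, or a numeric
#'   vector of per-second counts.
#' @param maxTauFactor no-bleaching threshold as a multiple of the trace
#'   span (default 10).
#' @return A \linkS4class{LifetimeFit} with method "bleach_trace".
#' @export
estimateBleachLifetime <- function(trace, maxTauFactor = 10) {
  if (is.numeric(trace))
    trace <- data.frame(bin_s = seq_along(trace) - 1, counts = trace)
  if (nrow(trace) < 5L) stop("need at least 5 bins")
  if (any(trace$counts < 0)) stop("counts must be >= 0")
  t <- trace$bin_s; y <- trace$counts
  span <- max(t) - min(t)
  if (stats::sd(y) == 0)
    return(.lifetimeFit(Inf, amplitude = 0, nEvents = nrow(trace),
                        r2 = NA_real_, method = "bleach_trace",
                        noBleaching = TRUE))
  fit <- .lmCurveFit(function(p) p[["A"]] * exp(-t / p[["tau"]]) + p[["c0"]],
    y, start = list(A = max(y) - min(y), tau = span / 2, c0 = min(y)),
    lower = c(0, .Machine$double.eps, 0))
  cf <- fit$par
  if (cf[["tau"]] > maxTauFactor * span || cf[["A"]] < 1e-6 * max(y))
    return(.lifetimeFit(Inf, amplitude = unname(cf["A"]),
                        nEvents = nrow(trace), r2 = fit$r2,
                        method = "bleach_trace", noBleaching = TRUE))
  .lifetimeFit(unname(cf["tau"]), amplitude = unname(cf["A"]),
               se = unname(fit$se["tau"]), nEvents = nrow(trace),
               r2 = fit$r2, method = "bleach_trace")
}

#' Correct an observed binding lifetime for photobleaching
#'
#' Dissociation and photobleaching are independent competing exponentials,
#' so the observed decay rate is their sum; the true off-rate is recovered
#' by rate subtraction, k_off = 1/tau_obs - 1/tau_bleach, and the corrected
#' lifetime is 1/k_off (always >= the observed lifetime). Standard errors
#' are propagated to first order. With an infinite bleach lifetime (no
#' appreciable bleaching) the observed lifetime is returned unchanged but
#' flagged corrected.
#'
#' @param observed \linkS4class{LifetimeFit} of the observed dwells.
#' @param bleach \linkS4class{LifetimeFit} from
#'   \code{\link{estimateBleachLifetime}} (or any LifetimeFit).
#' @return A bleach-corrected \linkS4class{LifetimeFit}.
#' @examples
#' obs <- exponentialLifetime(2.8, se = 0.06)
#' bl <- exponentialLifetime(40.4, se = 6.3)
#' tau(correctPhotobleaching(obs, bl)) - tau(obs)   # ~0.2 s
#' @export
correctPhotobleaching <- function(observed, bleach) {
  tauO <- observed@tau; tauB <- bleach@tau
  if (!is.finite(tauB) || isTRUE(bleach@noBleaching)) {
    out <- observed
    out@bleachCorrected <- TRUE
    return(out)
  }
  if (tauO >= tauB)
    stop("observed lifetime >= bleach lifetime: bleach-dominated, correction undefined")
  k <- 1 / tauO - 1 / tauB
  tauC <- 1 / k
  varK <- 0
  if (is.finite(observed@se)) varK <- varK + (observed@se / tauO^2)^2
  if (is.finite(bleach@se)) varK <- varK + (bleach@se / tauB^2)^2
  seC <- if (varK > 0) sqrt(varK) * tauC^2 else NA_real_
  .lifetimeFit(tauC, amplitude = observed@amplitude, se = seC,
               nEvents = observed@nEvents, nCensored = observed@nCensored,
               r2 = observed@r2, method = observed@method,
               bleachCorrected = TRUE)
}

#' Construct a LifetimeFit from a known lifetime
#'
#' Convenience constructor for literature values or externally fitted
#' lifetimes, e.g. to feed \code{\link{correctPhotobleaching}}.
#'
#' @param tau lifetime, s.
#' @param se standard error, s.
#' @param method label.
#' @return A \linkS4class{LifetimeFit}.
#' @export
exponentialLifetime <- function(tau, se = NA_real_, method = "external") {
  .lifetimeFit(tau, se = se, method = method)
}
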