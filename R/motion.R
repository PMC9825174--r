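#' @include AllClasses.R
NULL

#' Time-averaged mean squared displacement
#'
#' Computes the time-averaged MSD of a uniformly sampled 1D position
#' series: MSD(n dt) = 1/(N - n) * sum_{i=1}^{N-n} (x_{i+n} - x_i)^2,
#' for n = 1 .. floor(maxLagFraction * N).
#'
#' @param positions ordered positions, um; frames must be contiguous.
#' @param frameInterval s per frame.
#' @param maxLagFraction largest lag as a fraction of N (default 0.25).
#' @param frames optional frame indices used to verify uniform sampling.
#' @return An \linkS4class{MsdCurve}.
#' @examples
#' computeMsd(c(0, 1, 2, 3), 0.1)   # MSD = 1, 4, 9 um^2 at 1 lag each
#' @export
computeMsd <- function(positions, frameInterval, maxLagFraction = 0.25,
                       frames = NULL) {
  N <- length(positions)
  if (N < 2L) stop("need at least 2 positions")
  if (!is.null(frames) && any(diff(frames) != 1L))
    stop("positions must be uniformly sampled (no internal gaps)")
  maxLag <- max(1L, min(N - 1L, floor(maxLagFraction * N)))
  lags <- seq_len(maxLag)
  msd <- vapply(lags, function(n) mean(diff(positions, lag = n)^2), numeric(1))
  new("MsdCurve", lag = lags * frameInterval, msd = msd,
      nFrames = as.integer(N), nPairs = as.integer(N - lags))
}

#' Fit the anomalous-diffusion model to an MSD curve
#'
#' Weighted nonlinear least squares of MSD(n dt) = 2 D (n dt)^alpha + y
#' with D >= 0, alpha in (0, 2] and intercept y >= \code{yMin}. The
#' default \code{yMin = 0} reflects the blur-free imaging model, where the
#' intercept equals twice the localization variance and is nonnegative;
#' set \code{yMin = -Inf} for instruments with appreciable motion blur,
#' which can drive the true intercept negative. Weights are inverse
#' to the sampling variance of the time-averaged MSD, which for a
#' single trajectory grows as n^2/(N - n) with lag n, i.e. weights
#' proportional to (N - n)/n^2; this keeps the alpha-D fit identifiable
#' where equal or pairs-count weighting lets the noisy large-lag tail
#' drive alpha to degenerate values. The fit is
#' accepted only when R^2 >= \code{r2Min} and at least \code{minCoverage}
#' of the available MSD lags were used; non-convergence yields a rejected
#' fit with a diagnostic message rather than an error.
#'
#' @param msd an \linkS4class{MsdCurve}.
#' @param r2Min acceptance threshold on R^2 (default 0.8).
#' @param minCoverage minimum fraction of the MSD curve used (default 0.10).
#' @param yMin lower bound on the intercept (default 0).
#' @return A \linkS4class{DiffusionFit}.
#' @export
fitDiffusion <- function(msd, r2Min = 0.8, minCoverage = 0.10, yMin = 0) {
  validObject(msd)
  t <- msd@lag
  y <- msd@msd
  if (length(t) < 4L)
    return(new("DiffusionFit", D = NA_real_, alpha = NA_real_,
               intercept = NA_real_, r2 = NA_real_,
               fractionUsed = length(t) / (msd@nFrames - 1L),
               accepted = FALSE, message = "fewer than 4 MSD points"))
  n <- seq_along(t)
  w <- as.numeric(msd@nPairs) / n^2
  lin <- stats::lm(y ~ t, weights = w)
  d0 <- max(stats::coef(lin)[2] / 2, 1e-8)
  frac <- length(t) / (msd@nFrames - 1L)
  fit <- .lmCurveFit(function(p) 2 * p[["D"]] * t^p[["alpha"]] + p[["y0"]],
    y, start = list(D = d0, alpha = 1, y0 = max(min(y), yMin, 0)),
    lower = c(0, 1e-6, yMin), upper = c(Inf, 2, Inf), weights = w)
  new("DiffusionFit", D = unname(fit$par["D"]),
      alpha = unname(fit$par["alpha"]), intercept = unname(fit$par["y0"]),
      r2 = fit$r2, fractionUsed = frac,
      accepted = fit$converged && fit$r2 >= r2Min && frac >= minCoverage,
      message = if (fit$converged) "" else "no convergence")
}

# Windowed motility statistic: mean empirical MSD over lags 1..3 within a
# centered window, compared to the localization-noise floor 4*sigma^2.
.motileFrames <- function(x, windowFrames, localizationSigma,
                          motilityFactor) {
  N <- length(x)
  half <- windowFrames %/% 2L
  floorMsd <- motilityFactor * 4 * localizationSigma^2
  stat <- vapply(seq_len(N), function(i) {
    lo <- max(1L, i - half); hi <- min(N, i + half)
    xi <- x[lo:hi]
    lags <- seq_len(min(3L, length(xi) - 1L))
    mean(vapply(lags, function(n) mean(diff(xi, lag = n)^2), numeric(1)))
  }, numeric(1))
  stat > floorMsd
}

#' Segment a trajectory into motile and stationary phases
#'
#' A sliding-window displacement test: a frame is motile when the empirical
#' MSD over lags 1-3 inside its window exceeds the localization-noise floor
#' 4 sigma_loc^2 by \code{motilityFactor}. Contiguous same-label frames form
#' one phase; runs shorter than \code{minPhaseFrames} are absorbed into the
#' preceding phase. Tracks shorter than \code{minPhaseFrames} are excluded
#' (zero-row result); tracks shorter than the window get a single phase
#' labeled by the whole-track criterion.
#'
#' @param track samples of one particle (columns frame, position_um).
#' @param windowFrames sliding-window width, frames.
#' @param localizationSigma localization noise sd, um.
#' @param motilityFactor multiple of the noise floor required (default 3).
#' @param minPhaseFrames minimum analyzable length, frames (default 10).
#' @return data.frame: start_frame, end_frame, label ("motile"/"stationary").
#' @export
segmentPhases <- function(track, windowFrames = 15, localizationSigma = 0.02,
                          motilityFactor = 3, minPhaseFrames = 10) {
  track <- track[order(track$frame), ]
  x <- track$position_um
  N <- length(x)
  if (N < minPhaseFrames)
    return(data.frame(start_frame = integer(), end_frame = integer(),
                      label = character(), stringsAsFactors = FALSE))
  motile <- .motileFrames(x, min(windowFrames, N), localizationSigma,
                          motilityFactor)
  r <- rle(motile)
  # absorb short runs into the previous phase
  while (length(r$lengths) > 1L && any(r$lengths < minPhaseFrames)) {
    k <- which.min(r$lengths)
    r$values[k] <- if (k > 1L) r$values[k - 1L] else r$values[k + 1L]
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  data.frame(start_frame = track$frame[starts],
             end_frame = track$frame[ends],
             label = ifelse(r$values, "motile", "stationary"),
             stringsAsFactors = FALSE)
}

#' Segment, compute MSD and fit diffusion for every track
#'
#' Runs \code{\link{segmentPhases}} on each particle, computes the
#' time-averaged MSD of every phase and fits the anomalous-diffusion model
#' to motile phases, applying the R^2/coverage acceptance filter.
#'
#' @param tracks track table (tracking dialect).
#' @param frameInterval s per frame.
#' @param ... passed to \code{\link{segmentPhases}}.
#' @param maxLagFraction passed to \code{\link{computeMsd}}.
#' @return data.frame: phase_id, track_id, start_frame, end_frame, label,
#'   n_frames, D_um2_s, alpha, y_um2, r2, accepted.
#' @export
analyzeMotion <- function(tracks, frameInterval, maxLagFraction = 0.25, ...) {
  out <- list()
  for (id in unique(tracks$particle_id)) {
    tr <- tracks[tracks$particle_id == id, ]
    tr <- tr[order(tr$frame), ]
    phases <- segmentPhases(tr, ...)
    if (!nrow(phases)) next
    for (k in seq_len(nrow(phases))) {
      sel <- tr$frame >= phases$start_frame[k] & tr$frame <= phases$end_frame[k]
      x <- tr$position_um[sel]
      row <- data.frame(
        phase_id = sprintf("%s.%d", id, k), track_id = id,
        start_frame = phases$start_frame[k], end_frame = phases$end_frame[k],
        label = phases$label[k], n_frames = sum(sel),
        D_um2_s = NA_real_, alpha = NA_real_, y_um2 = NA_real_,
        r2 = NA_real_, accepted = FALSE, stringsAsFactors = FALSE)
      if (phases$label[k] == "motile" && sum(sel) >= 8L) {
        fit <- fitDiffusion(computeMsd(x, frameInterval,
                                       maxLagFraction = maxLagFraction))
        row$D_um2_s <- fit@D; row$alpha <- fit@alpha
        row$y_um2 <- fit@intercept; row$r2 <- fit@r2
        row$accepted <- fit@accepted
      }
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out))
    return(data.frame(phase_id = character(), track_id = character(),
                      start_frame = integer(), end_frame = integer(),
                      label = character(), n_frames = integer(),
                      D_um2_s = numeric(), alpha = numeric(),
                      y_um2 = numeric(), r2 = numeric(), accepted = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Classify particle behavior into motile/stationary x persistent/dissociated
#'
#' A particle is motile when it has at least one accepted motile phase, and
#' dissociated when its track ends before the observation window (i.e. it
#' is not end-censored). Counts over all particles sum to the number of
#' particles.
#'
#' @param tracks track table.
#' @param phases output of \code{\link{analyzeMotion}} on the same tracks.
#' @param observationWindow movie length, s.
#' @return data.frame with columns motility, fate, count (4 rows), plus a
#'   per-particle table in attribute \code{"particles"}.
#' @export
classifyBehavior <- function(tracks, phases, observationWindow) {
  ids <- unique(tracks$particle_id)
  grid <- expand.grid(motility = c("motile", "stationary"),
                      fate = c("persistent", "dissociated"),
                      stringsAsFactors = FALSE)
  if (!length(ids)) {
    grid$count <- 0L
    attr(grid, "particles") <- data.frame()
    return(grid)
  }
  per <- do.call(rbind, lapply(ids, function(id) {
    tr <- tracks[tracks$particle_id == id, ]
    ph <- phases[phases$track_id == id, , drop = FALSE]
    motile <- any(ph$label == "motile" & ph$accepted)
    endT <- max(tr$time_s)
    censored <- if (!is.null(tr$censored_end)) any(tr$censored_end)
      else endT >= observationWindow - 1e-9
    data.frame(particle_id = id,
               motility = if (motile) "motile" else "stationary",
               fate = if (censored) "persistent" else "dissociated",
               stringsAsFactors = FALSE)
  }))
  grid$count <- vapply(seq_len(nrow(grid)), function(i)
    sum(per$motility == grid$motility[i] & per$fate == grid$fate[i]),
    integer(1))
  attr(grid, "particles") <- per
  grid
}
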