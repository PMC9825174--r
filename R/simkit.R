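#' @include AllClasses.R
NULL

# Sample alternating on/off telegraph intervals covering [0, horizon].
# Returns a logical on/off state per frame midpoint time.
.blinkStates <- function(times, onLifetime, offLifetime) {
  if (!is.finite(onLifetime) || length(times) == 0L)
    return(rep(TRUE, length(times)))
  horizon <- max(times)
  t <- 0
  on <- TRUE
  edges <- numeric(0)
  states <- logical(0)
  while (t <= horizon) {
    dur <- stats::rexp(1, 1 / (if (on) onLifetime else offLifetime))
    edges <- c(edges, t)
    states <- c(states, on)
    t <- t + dur
    on <- !on
  }
  idx <- findInterval(times, edges)
  states[pmax(idx, 1L)]
}

#' Simulate single-molecule trajectories on stretched DNA
#'
#' Generates \code{nParticles} particle tracks under the generator's state
#' model: a particle is either stationary (bound at a damage site) or
#' undergoes a 1D displacement process with stationary power-law increments,
#' Var[x(t + k dt) - x(t)] = 2 D (k dt)^alpha. Tracks end by the first of
#' exponential dissociation, exponential photobleaching, or the end of the
#' observation window; blinking (on/off telegraph) removes frames without
#' ending the track. Independent Gaussian localization noise of sd
#' \code{localizationSigma} is added to every reported position.
#'
#' @param config a \linkS4class{SimulationConfig}; its \code{rngSeed} (when
#'   not NA) fixes the RNG so identical seeds give identical output.
#' @param nParticles number of particles, >= 1.
#' @param layout optional \linkS4class{FiducialMap}; stationary particles
#'   snap to their nearest observable site.
#' @param channel channel label stored in the track table.
#' @return list with elements \code{tracks} (data.frame: particle_id,
#'   channel, frame, time_s, position_um, amplitude, sigma_px, censored_end,
#'   merged_gaps) and \code{truth} (list: \code{particles} data.frame of
#'   per-particle ground truth, \code{positions} data.frame of true
#'   noise-free positions for every rendered frame).
#' @examples
#' cfg <- simConfig(nFrames = 200, rngSeed = 1)
#' sim <- simulateTrajectories(cfg, nParticles = 5)
#' head(sim$tracks)
#' @export
simulateTrajectories <- function(config, nParticles, layout = NULL,
                                 channel = "A") {
  validObject(config)
  if (!is.numeric(nParticles) || nParticles < 1)
    stop("nParticles must be >= 1")
  if (!is.na(config@rngSeed)) set.seed(as.integer(config@rngSeed))
  dt <- config@frameInterval
  nF <- as.integer(config@nFrames)
  window <- nF * dt
  lenUm <- config@dnaLength * config@kbToUm
  siteUm <- if (!is.null(layout)) {
    s <- sites(layout)
    if (layout@units == "kb") s * config@kbToUm else s
  } else NULL

  tracks <- vector("list", nParticles)
  truthPos <- vector("list", nParticles)
  pid <- sprintf("P%04d", seq_len(nParticles))
  motile <- stats::runif(nParticles) < config@motileFraction
  bindT <- if (is.finite(config@bindLifetime))
    stats::rexp(nParticles, 1 / config@bindLifetime) else rep(Inf, nParticles)
  bleachT <- if (is.finite(config@bleachLifetime))
    stats::rexp(nParticles, 1 / config@bleachLifetime) else rep(Inf, nParticles)
  start <- stats::runif(nParticles, 0, lenUm)
  siteIdx <- rep(NA_integer_, nParticles)

  for (i in seq_len(nParticles)) {
    endT <- min(bindT[i], bleachT[i], window)
    nObs <- max(1L, min(nF, ceiling(endT / dt)))
    frames <- 0:(nObs - 1L)
    times <- frames * dt
    if (motile[i]) {
      sig2 <- 2 * config@diffusionCoefficient * dt^config@alpha
      inc <- if (nObs > 1L)
        fgnIncrements(nObs - 1L, H = config@alpha / 2, sigma2 = sig2)
      else numeric(0)
      x <- start[i] + c(0, cumsum(inc))
      x <- .reflect(x, 0, lenUm)
    } else {
      x0 <- start[i]
      if (!is.null(siteUm) && length(siteUm)) {
        siteIdx[i] <- which.min(abs(siteUm - x0))
        x0 <- siteUm[siteIdx[i]]
      }
      x <- rep(x0, nObs)
    }
    on <- .blinkStates(times, config@blinkOnLifetime, config@blinkOffLifetime)
    obs <- which(on)
    if (!length(obs)) obs <- 1L          # keep at least the first frame
    xObs <- x[obs] + stats::rnorm(length(obs), 0, config@localizationSigma)
    tracks[[i]] <- data.frame(
      particle_id = pid[i], channel = channel, frame = frames[obs],
      time_s = times[obs], position_um = xObs,
      amplitude = NA_real_, sigma_px = NA_real_,
      censored_end = endT >= window, merged_gaps = 0L,
      stringsAsFactors = FALSE)
    truthPos[[i]] <- data.frame(
      particle_id = pid[i], frame = frames, time_s = times,
      position_um = x, visible = on, stringsAsFactors = FALSE)
  }
  particles <- data.frame(
    particle_id = pid, motile = motile,
    bind_time_s = bindT, bleach_time_s = bleachT,
    end_time_s = pmin(bindT, bleachT, window),
    true_dwell_s = pmin(bindT, bleachT, window),
    censored = pmin(bindT, bleachT) >= window,
    site_index = siteIdx, start_um = start, stringsAsFactors = FALSE)
  list(tracks = do.call(rbind, tracks),
       truth = list(particles = particles,
                    positions = do.call(rbind, truthPos)))
}

# reflecting boundaries keep diffusing particles on the substrate
.reflect <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  y <- ifelse(y > span, 2 * span - y, y)
  y + lo
}

#' Render a kymograph from trajectories
#'
#' Each frame column is the sum of Gaussian line profiles (sd
#' \code{psfSigma} pixels) centred at the true particle positions, each
#' normalized to \code{photonRate * frameInterval} expected photons, with
#' optional Poisson shot noise and a constant camera offset.
#'
#' @param sim output of \code{\link{simulateTrajectories}} (uses the true,
#'   noise-free positions and visibility), or a data.frame with columns
#'   frame, position_um and optionally visible.
#' @param config the \linkS4class{SimulationConfig} used for the simulation.
#' @param nPixels spatial extent; default covers the substrate.
#' @param shotNoise add Poisson noise (default TRUE).
#' @param offset constant background, photons per pixel.
#' @param channel channel label.
#' @return A \linkS4class{Kymograph}.
#' @export
renderKymograph <- function(sim, config, nPixels = NULL, shotNoise = TRUE,
                            offset = 5, channel = "A") {
  validObject(config)
  pos <- if (is.data.frame(sim)) sim else sim$truth$positions
  if (is.null(pos$visible)) pos$visible <- TRUE
  if (is.null(nPixels))
    nPixels <- ceiling(config@dnaLength * config@kbToUm / config@pixelSize)
  nPixels <- as.integer(nPixels)
  if (nPixels < 1L || config@pixelSize <= 0)
    stop("empty spatial window or non-positive pixel size")
  nF <- as.integer(config@nFrames)
  amp <- config@photonRate * config@frameInterval
  px <- (seq_len(nPixels) - 0.5) * config@pixelSize   # pixel centre, um
  img <- matrix(0, nPixels, nF)
  vis <- pos[pos$visible & pos$frame < nF, , drop = FALSE]
  if (nrow(vis)) {
    if (any(vis$position_um < 0 | vis$position_um > nPixels * config@pixelSize))
      stop("trajectory positions fall outside the rendered spatial window")
    sigUm <- config@psfSigma * config@pixelSize
    for (r in seq_len(nrow(vis))) {
      w <- exp(-(px - vis$position_um[r])^2 / (2 * sigUm^2))
      img[, vis$frame[r] + 1L] <- img[, vis$frame[r] + 1L] + amp * w / sum(w)
    }
  }
  if (shotNoise) {
    img[] <- stats::rpois(length(img), img)
    stopifnot(all(img >= 0), all(img == floor(img)))
  }
  Kymograph(img + offset, pixelSize = config@pixelSize,
            frameInterval = config@frameInterval, channel = channel)
}

#' Simulate binding dwell times under competing dissociation and bleaching
#'
#' Each observed dwell is the minimum of an exponential dissociation time
#' (mean \code{bindLifetime}), an exponential photobleaching time (mean
#' \code{bleachLifetime}; Inf disables), and right-censoring at the
#' observation window.
#'
#' @param bindLifetime,bleachLifetime exponential means, s (> 0; Inf
#'   disables the process).
#' @param observationWindow movie length, s.
#' @param n number of dwells.
#' @param seed optional integer seed.
#' @return data.frame: particle_id, channel, start_s, end_s, duration_s,
#'   censored, on_target (NA).
#' @export
simulateDwellTimes <- function(bindLifetime, bleachLifetime = Inf,
                               observationWindow = 300, n = 1, seed = NULL) {
  if (!is.numeric(observationWindow) || observationWindow <= 0)
    stop("observationWindow must be > 0")
  if (n < 1) stop("n must be >= 1")
  for (v in c(bindLifetime, bleachLifetime))
    if (is.na(v) || v <= 0) stop("lifetimes must be > 0 (Inf disables)")
  if (!is.null(seed)) set.seed(as.integer(seed))
  tBind <- if (is.finite(bindLifetime))
    stats::rexp(n, 1 / bindLifetime) else rep(Inf, n)
  tBleach <- if (is.finite(bleachLifetime))
    stats::rexp(n, 1 / bleachLifetime) else rep(Inf, n)
  dur <- pmin(tBind, tBleach, observationWindow)
  data.frame(particle_id = sprintf("D%05d", seq_len(n)), channel = "A",
             start_s = 0, end_s = dur, duration_s = dur,
             censored = pmin(tBind, tBleach) >= observationWindow,
             on_target = NA, stringsAsFactors = FALSE)
}

#' Build a damage-site layout
#'
#' \code{mode = "array"} places sites at regular spacing along a defined
#' substrate (tandem-ligated damage arrays: one site every
#' \code{spacing} kb). \code{mode = "fiducial"} starts from explicit site
#' positions (nickase recognition sites on lambda DNA), drops sites within
#' \code{beadMargin} of either anchoring bead, and merges runs of sites
#' closer than \code{resolutionLimit} into a single observable site at
#' their mean position.
#'
#' @param mode "array" or "fiducial".
#' @param spacing,length array geometry (same units as \code{units}).
#' @param sitePositions explicit site positions for fiducial mode.
#' @param resolutionLimit merge distance for fiducial mode.
#' @param beadMargin exclusion margin at both substrate ends.
#' @param units "kb" (default) or "um".
#' @return A \linkS4class{FiducialMap}.
#' @examples
#' makeDamageLayout("array", spacing = 2, length = 20)   # 10 sites
#' @export
makeDamageLayout <- function(mode = c("array", "fiducial"), spacing = NULL,
                             length = NULL, sitePositions = NULL,
                             resolutionLimit = 0, beadMargin = 0,
                             units = "kb") {
  mode <- match.arg(mode)
  if (mode == "array") {
    if (is.null(spacing) || is.null(length) || spacing <= 0)
      stop("array mode needs spacing > 0 and length")
    input <- seq(spacing, length, by = spacing)
    obs <- input
  } else {
    if (is.null(sitePositions) || is.null(length))
      stop("fiducial mode needs sitePositions and length")
    input <- sort(sitePositions)
    keep <- input[input >= beadMargin & input <= length - beadMargin]
    obs <- numeric(0)
    if (base::length(keep)) {
      grp <- cumsum(c(1, diff(keep) >= resolutionLimit))
      obs <- as.numeric(tapply(keep, grp, mean))
    }
  }
  new("FiducialMap", substrateLength = as.numeric(length), sites = obs,
      inputSites = as.numeric(input), resolutionLimit = resolutionLimit,
      beadMargin = beadMargin, units = units)
}

#' Simulate an equilibrium binding titration
#'
#' Percent bound is drawn from the quadratic (ligand-depletion) binding
#' model \code{\link{fractionBoundModel}} plus Gaussian noise, clipped to
#' [0, 100].
#'
#' @param kd true dissociation constant, nM.
#' @param dnaConc total DNA concentration, nM.
#' @param proteinConcs titration grid, nM.
#' @param noiseSd Gaussian noise sd, percentage points.
#' @param seed optional integer seed.
#' @return data.frame: protein_nM, dna_nM, percent_bound.
#' @export
simulateIsotherm <- function(kd, dnaConc, proteinConcs, noiseSd = 0,
                             seed = NULL) {
  if (kd <= 0) stop("kd must be > 0")
  if (any(proteinConcs < 0) || dnaConc <= 0)
    stop("concentrations must be >= 0 with dnaConc > 0")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  y <- fractionBoundModel(dnaConc, proteinConcs, kd)
  if (noiseSd > 0) y <- y + stats::rnorm(length(y), 0, noiseSd)
  data.frame(protein_nM = proteinConcs, dna_nM = dnaConc,
             percent_bound = pmin(pmax(y, 0), 100))
}
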