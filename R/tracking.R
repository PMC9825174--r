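#' @include AllClasses.R
NULL

# Fit a 1D Gaussian a*exp(-(x-mu)^2/(2 s^2)) + b around a candidate peak.
# Falls back to an intensity-weighted centroid when the fit fails.
.fitLine <- function(profile, peak, psfGuess = 1.5, halfWidth = NULL) {
  n <- length(profile)
  if (is.null(halfWidth)) halfWidth <- max(4L, ceiling(4 * psfGuess))
  lo <- max(1L, peak - halfWidth)
  hi <- min(n, peak + halfWidth)
  x <- lo:hi
  y <- profile[x]
  b0 <- min(y)
  a0 <- max(profile[peak] - b0, .Machine$double.eps)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(x - mu)^2 / (2 * s^2)) + b,
      start = list(a = a0, mu = peak, s = psfGuess, b = b0),
      lower = c(a = 0, mu = lo, s = 0.3, b = -Inf),
      upper = c(a = Inf, mu = hi, s = 4 * psfGuess, b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    return(c(center = unname(cf["mu"]), amplitude = unname(cf["a"]),
             sigma = unname(cf["s"])))
  }
  w <- pmax(y - b0, 0)
  c(center = sum(w * x) / sum(w), amplitude = a0, sigma = psfGuess)
}

#' Track fluorescent lines through a kymograph
#'
#' Per frame, candidate peaks are local maxima exceeding the frame
#' background (column median) by \code{detectionThreshold} background-noise
#' standard deviations (column MAD); each candidate is refined by a 1D
#' Gaussian fit giving a subpixel centre. Centres are linked frame-to-frame
#' by nearest-neighbour assignment within \code{linkGatePx} pixels (ties to
#' the smaller displacement); a track ends at the first frame with no
#' detection inside its gate (blink gaps are re-joined afterwards by
#' \code{\link{mergeBlinkGaps}}). Tracks shorter than
#' \code{minTrackFrames} are discarded.
#'
#' @param kymograph a \linkS4class{Kymograph}.
#' @param detectionThreshold peak threshold in background-noise sd units.
#' @param minTrackFrames minimum track length, frames.
#' @param psfSigma expected line-profile sd, pixels (fit start value).
#' @param linkGatePx frame-to-frame linking gate, pixels.
#' @return data.frame of track samples (particle_id, channel, frame,
#'   time_s, position_um, amplitude, sigma_px, censored_end, merged_gaps);
#'   zero rows when nothing is detected.
#' @export
trackLines <- function(kymograph, detectionThreshold = 5,
                       minTrackFrames = 10, psfSigma = 1.5,
                       linkGatePx = 3) {
  validObject(kymograph)
  img <- kymograph@image
  nPx <- nrow(img); nF <- ncol(img)
  active <- list()     # each: list(rows = list of sample rows, last, lastFrame)
  done <- list()
  nextId <- 1L
  for (f in seq_len(nF)) {
    col <- img[, f]
    bg <- stats::median(col)
    noise <- stats::mad(col)
    if (noise == 0) noise <- sqrt(max(bg, 1))   # Poisson floor for flat bg
    thr <- bg + detectionThreshold * noise
    isPeak <- col > thr &
      col >= c(-Inf, col[-nPx]) & col >= c(col[-1], -Inf)
    peaks <- which(isPeak)
    # suppress shoulders: keep strongest within one PSF
    if (length(peaks) > 1L) {
      ord <- peaks[order(col[peaks], decreasing = TRUE)]
      kept <- integer(0)
      for (p in ord)
        if (!length(kept) || min(abs(kept - p)) > 2 * psfSigma)
          kept <- c(kept, p)
      peaks <- sort(kept)
    }
    det <- lapply(peaks, function(p) .fitLine(col, p, psfGuess = psfSigma))
    centers <- vapply(det, `[[`, numeric(1), "center")
    usedDet <- rep(FALSE, length(det))
    stillActive <- list()
    for (tr in active) {
      j <- NA_integer_
      if (length(centers)) {
        d <- abs(centers - tr$last)
        d[usedDet] <- Inf
        if (min(d) <= linkGatePx) j <- which.min(d)
      }
      if (!is.na(j)) {
        usedDet[j] <- TRUE
        tr$rows[[length(tr$rows) + 1L]] <-
          c(f - 1L, centers[j], det[[j]]["amplitude"], det[[j]]["sigma"])
        tr$last <- centers[j]
        tr$lastFrame <- f
        stillActive[[length(stillActive) + 1L]] <- tr
      } else {
        done[[length(done) + 1L]] <- tr
      }
    }
    for (j in seq_along(det)) {
      if (usedDet[j]) next
      stillActive[[length(stillActive) + 1L]] <- list(
        id = nextId,
        rows = list(c(f - 1L, centers[j], det[[j]]["amplitude"],
                      det[[j]]["sigma"])),
        last = centers[j], lastFrame = f)
      nextId <- nextId + 1L
    }
    active <- stillActive
  }
  done <- c(done, active)
  if (!length(done)) return(.emptyTracks())
  out <- lapply(done, function(tr) {
    m <- do.call(rbind, tr$rows)
    if (nrow(m) < minTrackFrames) return(NULL)
    data.frame(
      particle_id = sprintf("T%04d", tr$id), channel = kymograph@channel,
      frame = as.integer(m[, 1]), time_s = m[, 1] * kymograph@frameInterval,
      position_um = (m[, 2] - 0.5) * kymograph@pixelSize,
      amplitude = m[, 3], sigma_px = m[, 4],
      censored_end = tr$lastFrame == nF, merged_gaps = 0L,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) .emptyTracks() else out[order(out$particle_id, out$frame), ]
}

.emptyTracks <- function() {
  data.frame(particle_id = character(), channel = character(),
             frame = integer(), time_s = numeric(), position_um = numeric(),
             amplitude = numeric(), sigma_px = numeric(),
             censored_end = logical(), merged_gaps = integer(),
             stringsAsFactors = FALSE)
}

#' Merge blink-interrupted track segments
#'
#' Reconnects fluorophore blinking: two segments A (ending) and B (starting)
#' from the same channel are merged when the dark gap satisfies
#' 0 < gap < \code{maxGap} (strict: a 2 s gap at the default is NOT merged)
#' and the positions across the gap differ by at most
#' \code{maxPositionJump}. Merging is transitive and the operation is
#' idempotent; each merge increments the track's merged-gap count.
#'
#' @param tracks track table (one channel).
#' @param maxGap maximum dark gap, s (default 2).
#' @param maxPositionJump maximum position change across the gap, um.
#' @return merged track table.
#' @export
mergeBlinkGaps <- function(tracks, maxGap = 2.0, maxPositionJump = 0.5) {
  if (!nrow(tracks)) return(tracks)
  if (length(unique(tracks$channel)) > 1L)
    stop("mergeBlinkGaps expects tracks from a single channel")
  if (anyDuplicated(tracks[, c("particle_id", "frame")]))
    stop("overlapping-in-time segments with the same id are inconsistent")
  repeat {
    ids <- unique(tracks$particle_id)
    seg <- do.call(rbind, lapply(ids, function(id) {
      s <- tracks[tracks$particle_id == id, ]
      data.frame(id = id, start = min(s$time_s), end = max(s$time_s),
                 posStart = s$position_um[which.min(s$time_s)],
                 posEnd = s$position_um[which.max(s$time_s)],
                 stringsAsFactors = FALSE)
    }))
    seg <- seg[order(seg$start), ]
    merged <- FALSE
    for (i in seq_len(nrow(seg) - 1L)) {
      gaps <- seg$start - seg$end[i]
      jump <- abs(seg$posStart - seg$posEnd[i])
      ok <- which(gaps > 0 & gaps < maxGap & jump <= maxPositionJump)
      if (length(ok)) {
        j <- ok[which.min(gaps[ok])]
        a <- seg$id[i]; b <- seg$id[j]
        sel <- tracks$particle_id == b
        gapsTotal <- max(tracks$merged_gaps[tracks$particle_id == a]) +
          max(tracks$merged_gaps[sel]) + 1L
        cens <- any(tracks$censored_end[sel])
        tracks$particle_id[sel] <- a
        sub <- tracks$particle_id == a
        tracks$merged_gaps[sub] <- gapsTotal
        tracks$censored_end[sub] <- cens
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  tracks[order(tracks$particle_id, tracks$frame), ]
}
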