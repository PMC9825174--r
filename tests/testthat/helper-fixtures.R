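# Fixtures and independent oracles built in code.

# Simple constant-interval track table for one particle.
makeTrack <- function(id, frames, positions, channel = "A", dt = 0.1,
                      censored = FALSE) {
  n <- length(frames)
  data.frame(particle_id = rep_len(id, n), channel = rep_len(channel, n),
             frame = frames, time_s = frames * dt, position_um = positions,
             amplitude = rep_len(NA_real_, n), sigma_px = rep_len(NA_real_, n),
             censored_end = rep_len(censored, n),
             merged_gaps = rep_len(0L, n), stringsAsFactors = FALSE)
}

# Brute-force time-averaged MSD: the literal double loop.
msdBruteForce <- function(x, dt, maxLag) {
  N <- length(x)
  vapply(seq_len(maxLag), function(n) {
    s <- 0
    for (i in seq_len(N - n)) s <- s + (x[i + n] - x[i])^2
    s / (N - n)
  }, numeric(1))
}

# Exhaustive one-to-one colocalization pairing maximizing total overlap:
# enumerates all assignments on small instances.
colocBruteForce <- function(overlapMatrix) {
  nA <- nrow(overlapMatrix); nB <- ncol(overlapMatrix)
  best <- list(total = -Inf, pairs = NULL)
  recurse <- function(a, usedB, pairs, total) {
    if (a > nA) {
      if (total > best$total) best <<- list(total = total, pairs = pairs)
      return(invisible())
    }
    recurse(a + 1L, usedB, pairs, total)   # leave a unmatched
    for (b in seq_len(nB)) {
      if (usedB[b] || !is.finite(overlapMatrix[a, b])) next
      recurse(a + 1L, replace(usedB, b, TRUE),
              rbind(pairs, c(a, b)), total + overlapMatrix[a, b])
    }
  }
  recurse(1L, rep(FALSE, nB), NULL, 0)
  best
}

# Brownian phase with optional localization noise, as a track table.
brownianTrack <- function(id, nFrames, D, dt = 0.1, sigmaLoc = 0,
                          x0 = 0, channel = "A") {
  x <- x0 + cumsum(c(0, stats::rnorm(nFrames - 1, 0, sqrt(2 * D * dt))))
  makeTrack(id, 0:(nFrames - 1), x + stats::rnorm(nFrames, 0, sigmaLoc),
            channel = channel, dt = dt)
}
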