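#' @include AllClasses.R
NULL

#' Call dual-color colocalization between two track tables
#'
#' A pair of particles (one per channel) is colocalized when their
#' positions stay within \code{distanceThreshold} for at least
#' \code{minOverlap} seconds of co-existing time. Each particle joins at
#' most one pair; candidate pairs are accepted greedily by descending
#' overlap duration, ties broken by smaller mean distance. The result is
#' symmetric under swapping the channels.
#'
#' @param tracksA,tracksB track tables sharing the coordinate frame and
#'   time base (identical frame interval).
#' @param distanceThreshold colocalization distance, um (default 0.5).
#' @param minOverlap minimum co-localized time, s (default 1).
#' @return A \linkS4class{ColocalizationResult}.
#' @export
callColocalization <- function(tracksA, tracksB, distanceThreshold = 0.5,
                               minOverlap = 1.0) {
  dtA <- .inferFrameInterval(tracksA)
  dtB <- .inferFrameInterval(tracksB)
  if (!is.na(dtA) && !is.na(dtB) && abs(dtA - dtB) > 1e-9)
    stop("channels have mismatched time bases")
  dt <- if (!is.na(dtA)) dtA else dtB
  idsA <- unique(tracksA$particle_id)
  idsB <- unique(tracksB$particle_id)
  # pre-split per particle; bounding boxes prune impossible pairs exactly
  prep <- function(tracks, ids) {
    sp <- split(tracks[, c("frame", "position_um")], tracks$particle_id)
    lapply(sp[ids], function(s)
      list(frame = s$frame, x = s$position_um,
           f0 = min(s$frame), f1 = max(s$frame),
           x0 = min(s$position_um), x1 = max(s$position_um)))
  }
  pa <- prep(tracksA, idsA)
  pb <- prep(tracksB, idsB)
  cand <- list()
  for (a in idsA) {
    ta <- pa[[a]]
    for (b in idsB) {
      tb <- pb[[b]]
      if (tb$f0 > ta$f1 || ta$f0 > tb$f1) next
      if (tb$x0 - ta$x1 > distanceThreshold ||
          ta$x0 - tb$x1 > distanceThreshold) next
      common <- intersect(ta$frame, tb$frame)
      if (!length(common)) next
      xa <- ta$x[match(common, ta$frame)]
      xb <- tb$x[match(common, tb$frame)]
      close <- abs(xa - xb) <= distanceThreshold
      overlap <- sum(close) * dt
      if (overlap >= minOverlap)
        cand[[length(cand) + 1L]] <- data.frame(
          a_id = a, b_id = b, overlap_s = overlap,
          mean_dist_um = mean(abs(xa - xb)[close]),
          stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(cand)) do.call(rbind, cand) else
    data.frame(a_id = character(), b_id = character(),
               overlap_s = numeric(), mean_dist_um = numeric(),
               stringsAsFactors = FALSE)
  pairs <- pairs[order(-pairs$overlap_s, pairs$mean_dist_um), ]
  usedA <- character(0); usedB <- character(0)
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (pairs$a_id[i] %in% usedA || pairs$b_id[i] %in% usedB) next
    keep[i] <- TRUE
    usedA <- c(usedA, pairs$a_id[i]); usedB <- c(usedB, pairs$b_id[i])
  }
  pairs <- pairs[keep, , drop = FALSE]
  nC <- nrow(pairs)
  counts <- c(a_only = length(idsA) - nC, b_only = length(idsB) - nC,
              colocalized = nC)
  tot <- sum(counts)
  nMol <- length(idsA) + length(idsB)
  fractions <- c(
    fraction_of_entities = if (tot > 0) nC / tot else NA_real_,
    fraction_of_molecules = if (nMol > 0) 2 * nC / nMol else NA_real_)
  new("ColocalizationResult", counts = as.integer(counts) |>
        stats::setNames(names(counts)),
      pairs = pairs, fractions = fractions)
}

.inferFrameInterval <- function(tracks) {
  if (!nrow(tracks)) return(NA_real_)
  f <- tracks$time_s / pmax(tracks$frame, 1L)
  stats::median(f[tracks$frame > 0], na.rm = TRUE)
}

#' Classify binding events as on- or off-target against a fiducial map
#'
#' An event is on-target when its distance to the nearest observable
#' damage site is at most \code{window}. Positions and fiducials must be
#' in the same units.
#'
#' @param events data.frame with a \code{position} column (or
#'   \code{position_um}/\code{position_kb}).
#' @param fiducials a \linkS4class{FiducialMap}.
#' @param window on-target half-window (same units as the map).
#' @return \code{events} with logical column \code{on_target} added and the
#'   on-target fraction in attribute \code{"fraction_on_target"}; an empty
#'   map yields all off-target with a warning.
#' @export
classifyOnTarget <- function(events, fiducials, window = 1) {
  pos <- events$position
  if (is.null(pos)) pos <- events$position_kb
  if (is.null(pos)) pos <- events$position_um
  if (is.null(pos)) stop("events must carry a position column")
  s <- sites(fiducials)
  if (!length(s)) {
    warning("empty fiducial map: all events off-target")
    events$on_target <- rep(FALSE, nrow(events))
  } else {
    events$on_target <- vapply(pos, function(p) min(abs(s - p)) <= window,
                               logical(1))
  }
  attr(events, "fraction_on_target") <-
    if (nrow(events)) mean(events$on_target) else NA_real_
  events
}

#' Tabulate behavior categories for single- and dual-color particles
#'
#' Crosses the colocalization call with the motile/stationary x
#' persistent/dissociated behavior classification, giving one 2x2 table
#' for A-only, B-only and colocalized particles. Fractions sum to 1 within
#' each non-empty group.
#'
#' @param result a \linkS4class{ColocalizationResult}.
#' @param behaviorA,behaviorB outputs of \code{\link{classifyBehavior}}
#'   (their \code{"particles"} attribute is used) for the two channels.
#' @return named list of data.frames (a_only, b_only, colocalized), each
#'   with columns motility, fate, count, fraction.
#' @export
summarizeDualColor <- function(result, behaviorA, behaviorB) {
  perA <- attr(behaviorA, "particles")
  perB <- attr(behaviorB, "particles")
  pairedA <- result@pairs$a_id
  pairedB <- result@pairs$b_id
  groups <- list(
    a_only = perA[!(perA$particle_id %in% pairedA), , drop = FALSE],
    b_only = perB[!(perB$particle_id %in% pairedB), , drop = FALSE],
    colocalized = perA[perA$particle_id %in% pairedA, , drop = FALSE])
  lapply(groups, function(g) {
    grid <- expand.grid(motility = c("motile", "stationary"),
                        fate = c("persistent", "dissociated"),
                        stringsAsFactors = FALSE)
    grid$count <- vapply(seq_len(nrow(grid)), function(i) {
      if (!NROW(g)) 0L else
        sum(g$motility == grid$motility[i] & g$fate == grid$fate[i])
    }, integer(1))
    tot <- sum(grid$count)
    grid$fraction <- if (tot > 0) grid$count / tot else rep(NA_real_, 4)
    grid
  })
}
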