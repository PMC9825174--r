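#' @include AllClasses.R
NULL

#' Per-species lane fractions from gel band intensities
#'
#' Subtracts the background from each band (clipping negatives to zero
#' with a warning) and divides by the lane total, so fractions always sum
#' to 1.
#'
#' @param intensities named numeric vector of band intensities (e.g.
#'   free, bound_1, bound_2, ternary or substrate, product).
#' @param background background intensity, a scalar or one value per band.
#' @return named numeric vector of fractions summing to 1.
#' @examples
#' laneFractions(c(free = 80, bound = 20))   # bound fraction 0.20
#' @export
laneFractions <- function(intensities, background = 0) {
  if (any(intensities < 0)) stop("raw intensities must be >= 0")
  sub <- intensities - background
  if (any(sub < 0)) {
    warning("negative background-subtracted intensities clipped to 0")
    sub <- pmax(sub, 0)
  }
  total <- sum(sub)
  if (total <= 0) stop("all-zero lane after background subtraction")
  sub / total
}

#' Quadratic (ligand-depletion) binding model
#'
#' Percent DNA bound at total DNA concentration D, total protein
#' concentration P and dissociation constant Kd, from the physical root of
#' the mass-action quadratic:
#' \deqn{\%bound = 100 \frac{(D+P+K_d) - \sqrt{(D+P+K_d)^2 - 4DP}}{2D}}
#' Used instead of a hyperbola because the DNA concentration is in the
#' same molar range as Kd (ligand depletion).
#'
#' @param D total DNA concentration, nM (> 0).
#' @param P total protein concentration, nM (vectorized).
#' @param Kd dissociation constant, nM (> 0).
#' @return percent bound in [0, 100].
#' @examples
#' fractionBoundModel(8, 8, 6)   # 43.1
#' @export
fractionBoundModel <- function(D, P, Kd) {
  if (!is.numeric(D) || D <= 0) stop("D must be > 0")
  if (Kd <= 0) stop("Kd must be > 0")
  if (any(P < 0)) stop("P must be >= 0")
  s <- D + P + Kd
  100 * (s - sqrt(s^2 - 4 * D * P)) / (2 * D)
}

#' Fit the quadratic binding isotherm for Kd
#'
#' Nonlinear least squares of \code{\link{fractionBoundModel}} to
#' (protein concentration, percent bound) titration points at a single
#' shared DNA concentration. The Kd start value is taken from the protein
#' concentration at half-maximal binding.
#'
#' @param points data.frame with columns protein_nM and percent_bound
#'   (and optionally dna_nM).
#' @param dnaConc total DNA concentration, nM; taken from the points when
#'   omitted.
#' @return A \linkS4class{KdFit}.
#' @export
fitKd <- function(points, dnaConc = NULL) {
  if (nrow(points) < 3L) stop("need at least 3 titration points")
  if (is.null(dnaConc)) {
    d <- unique(points$dna_nM)
    if (length(d) != 1L) stop("points must share a single DNA concentration")
    dnaConc <- d
  }
  y <- points$percent_bound
  P <- points$protein_nM
  if (max(y) < 5 || min(y) > 95)
    stop("no binding transition in the data: Kd unidentifiable")
  half <- max(y) / 2
  kd0 <- tryCatch(stats::approx(y, P, xout = half, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- max(stats::median(P), 1e-3)
  fit <- .lmCurveFit(function(p) fractionBoundModel(dnaConc, P, p[["Kd"]]),
    y, start = list(Kd = kd0), lower = 1e-9)
  new("KdFit", kd = unname(fit$par["Kd"]), se = unname(fit$se["Kd"]),
      r2 = fit$r2, nPoints = nrow(points), dnaConc = dnaConc)
}

#' Fraction of substrate excised
#'
#' Fraction product = product / (product + substrate), from quantified
#' substrate and product band intensities of a denaturing gel.
#'
#' @param substrateIntensity,productIntensity band intensities (>= 0, not
#'   both zero); vectorized.
#' @return fraction in [0, 1].
#' @export
excisionFraction <- function(substrateIntensity, productIntensity) {
  tot <- substrateIntensity + productIntensity
  if (any(tot <= 0)) stop("substrate + product must be > 0")
  productIntensity / tot
}

#' Fold stimulation of an excision time course
#'
#' Per-timepoint ratio of the stimulated to the unstimulated excision
#' fraction over matched time grids, plus a summary fold taken at the
#' earliest timepoint where the unstimulated fraction reaches
#' \code{minBaseline} (avoids 0/0 instability at early times).
#'
#' @param seriesPlus,seriesMinus data.frames with columns time_min and
#'   fraction, on identical time grids.
#' @param minBaseline minimum unstimulated fraction for the summary
#'   timepoint (default 0.05).
#' @return list: \code{table} (time_min, fraction_plus, fraction_minus,
#'   fold; fold is NA where the unstimulated fraction is zero),
#'   \code{summary_fold}, \code{summary_time_min}.
#' @export
foldStimulation <- function(seriesPlus, seriesMinus, minBaseline = 0.05) {
  if (!isTRUE(all.equal(seriesPlus$time_min, seriesMinus$time_min)))
    stop("time grids must match")
  fp <- seriesPlus$fraction; fm <- seriesMinus$fraction
  fold <- ifelse(fm > 0, fp / fm, NA_real_)
  tab <- data.frame(time_min = seriesPlus$time_min, fraction_plus = fp,
                    fraction_minus = fm, fold = fold)
  k <- which(fm >= minBaseline)[1]
  list(table = tab,
       summary_fold = if (!is.na(k)) fold[k] else NA_real_,
       summary_time_min = if (!is.na(k)) tab$time_min[k] else NA_real_)
}
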