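#' Fractional Gaussian increments by circulant embedding
#'
#' Draws n stationary increments of a fractional Brownian path with Hurst
#' exponent H and one-step variance \code{sigma2}, using the Davies-Harte
#' circulant embedding of the fGn autocovariance so that
#' Var[x(t+k) - x(t)] = sigma2 * k^(2H) holds exactly in expectation for
#' every lag k. For H = 1/2 the increments are plain iid Gaussian.
#'
#' Uses the current RNG stream; seed upstream for reproducibility.
#'
#' @param n number of increments.
#' @param H Hurst exponent in (0, 1]; the anomalous MSD exponent is 2H.
#' @param sigma2 variance of a single increment.
#' @return numeric vector of n increments.
#' @export
fgnIncrements <- function(n, H, sigma2 = 1) {
  stopifnot(n >= 1, H > 0, H <= 1, sigma2 >= 0)
  if (sigma2 == 0) return(numeric(n))
  if (abs(H - 0.5) < 1e-12) return(stats::rnorm(n, 0, sqrt(sigma2)))
  if (abs(H - 1) < 1e-12) {           # degenerate ballistic limit: x_k = k*Z
    return(rep(stats::rnorm(1, 0, sqrt(sigma2)), n))
  }
  k <- 0:n
  gam <- sigma2 / 2 *
    (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  circ <- c(gam, rev(gam[2:n]))        # length 2n
  m <- length(circ)
  lambda <- Re(stats::fft(circ))
  lambda[lambda < 0 & lambda > -1e-8 * max(lambda)] <- 0
  if (any(lambda < 0))
    stop("circulant embedding produced negative eigenvalues; H out of range")
  # Hermitian-symmetric complex Gaussian spectrum
  z <- complex(length.out = m)
  z[1] <- stats::rnorm(1)
  z[n + 1] <- stats::rnorm(1)
  if (n > 1) {
    u <- stats::rnorm(n - 1)
    v <- stats::rnorm(n - 1)
    z[2:n] <- complex(real = u, imaginary = v) / sqrt(2)
    z[m:(n + 2)] <- Conj(z[2:n])
  }
  x <- Re(stats::fft(sqrt(lambda) * z)) / sqrt(m)
  x[seq_len(n)]
}
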