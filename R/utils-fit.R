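# Robust bounded Levenberg-Marquardt curve fit.
#
# Thin wrapper over minpack.lm::nls.lm that always returns the optimum
# (nls-style wrappers error on singular Jacobians at degenerate optima,
# e.g. a power-law amplitude pinned at zero). Standard errors come from
# sigma^2 (J'J)^-1 with a finite-difference Jacobian; NA when singular.
.lmCurveFit <- function(pred, y, start, lower = NULL, upper = NULL,
                        weights = NULL) {
  sw <- if (is.null(weights)) rep(1, length(y)) else sqrt(weights)
  resid <- function(p) sw * (y - pred(p))
  out <- minpack.lm::nls.lm(
    par = start, fn = resid,
    lower = if (is.null(lower)) rep(-Inf, length(start)) else lower,
    upper = if (is.null(upper)) rep(Inf, length(start)) else upper,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- out$par
  fitted <- pred(p)
  # R^2 in the same (weighted) metric the fit minimizes
  wts <- sw^2
  ybar <- sum(wts * y) / sum(wts)
  ssTot <- sum(wts * (y - ybar)^2)
  r2 <- if (ssTot > 0) 1 - sum(wts * (y - fitted)^2) / ssTot else 1
  k <- length(p); n <- length(y)
  se <- rep(NA_real_, k)
  names(se) <- names(p)
  if (n > k) {
    J <- matrix(0, n, k)
    h <- pmax(abs(unlist(p)) * 1e-6, 1e-10)
    for (j in seq_len(k)) {
      pj <- p; pj[[j]] <- pj[[j]] + h[j]
      J[, j] <- (resid(pj) - resid(p)) / h[j]
    }
    jtj <- crossprod(J)
    sigma2 <- sum(resid(p)^2) / (n - k)
    cv <- tryCatch(solve(jtj) * sigma2, error = function(e) NULL)
    if (!is.null(cv)) se <- stats::setNames(sqrt(pmax(diag(cv), 0)), names(p))
  }
  list(par = unlist(p), fitted = fitted, r2 = r2, se = se,
       converged = out$info %in% 1:4)
}
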