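#' Storey q-values with Benjamini-Hochberg fallback
#'
#' Estimates the proportion of true nulls pi0 with Storey's smoother: the
#' fraction of p-values above lambda, divided by (1 - lambda), is
#' computed over a lambda grid and a cubic smoothing spline is evaluated
#' at the largest lambda. q-values are the BH-style step-up quantities
#' scaled by pi0, made monotone in p. With fewer than `min_p` p-values,
#' or when the pi0 estimate is unstable (non-finite or <= 0), the method
#' falls back to pi0 = 1, i.e. plain Benjamini-Hochberg.
#'
#' @param p numeric vector of p-values in (0, 1]; `NA`s propagate.
#' @param lambda grid for the pi0 smoother.
#' @param min_p minimum number of p-values for the Storey estimate.
#' @return numeric vector of q-values, same length and order as `p`.
#' @export
estimate_qvalues <- function(p, lambda = seq(0.05, 0.95, 0.05), min_p = 100L) {
  if (length(p) == 0L) return(numeric(0))
  ok <- !is.na(p)
  pv <- p[ok]
  if (any(pv <= 0 | pv > 1)) stop("p-values must lie in (0, 1]")
  m <- length(pv)
  pi0 <- 1
  if (m >= min_p) {
    pi0_lambda <- vapply(lambda, function(l) mean(pv > l) / (1 - l), 0)
    sp <- try(stats::smooth.spline(lambda, pi0_lambda, df = 3), silent = TRUE)
    if (!inherits(sp, "try-error")) {
      est <- stats::predict(sp, x = max(lambda))$y
      if (is.finite(est) && est > 0) pi0 <- min(est, 1)
    }
  }
  q <- pi0 * stats::p.adjust(pv, method = "BH")
  q <- pmin(q, 1)
  out <- rep(NA_real_, length(p))
  out[ok] <- q
  out
}
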