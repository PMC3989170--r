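#' Local false discovery rate from a p-value sample
#'
#' Storey-style nonparametric lfdr: the null proportion `pi0` is estimated
#' from the flat tail (`mean(p >= lambda) / (1 - lambda)`), the marginal
#' density of probit-transformed p-values is estimated by a kernel density
#' smoothed with a spline, and `lfdr(p) = pi0 * f0(p) / f(p)`, truncated to
#' [0, 1] and made monotone nondecreasing in p by a cumulative-maximum pass
#' over the sorted values. Used as the posterior weight in the original
#' Leek-Storey surrogate variable iteration.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param lambda tail cut for the pi0 estimate (default 0.8).
#' @param adjust kernel bandwidth adjustment (default 1.5).
#' @return numeric vector of lfdr values in [0, 1], aligned with `p`.
#'   Degenerate inputs (too few distinct p-values for density estimation)
#'   raise an error; callers fall back to uniform weights.
#' @export
estimate_lfdr <- function(p, lambda = 0.8, adjust = 1.5) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  if (length(unique(round(p, 10))) < 10L) {
    stop("degenerate p-value histogram: too few distinct values")
  }
  pi0 <- min(1, mean(p >= lambda) / (1 - lambda))
  eps <- 1e-8
  x <- stats::qnorm(pmin(pmax(p, eps), 1 - eps))
  dens <- stats::density(x, adjust = adjust)
  sp <- stats::smooth.spline(dens$x, dens$y)
  f <- pmax(stats::predict(sp, x)$y, 1e-12)
  lfdr <- pmin(pi0 * stats::dnorm(x) / f, 1)
  ord <- order(p)
  lfdr[ord] <- cummax(lfdr[ord])
  pmin(lfdr, 1)
}
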