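#' One-sided exact binomial test
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(n, alpha0)`. Used to
#' ask whether the number of channels (or units) crossing a per-site
#' significance criterion exceeds what the criterion's false-positive rate
#' alone would produce.
#'
#' @param k Number of successes (sites crossing the criterion).
#' @param n Number of trials (sites tested).
#' @param alpha0 Null success probability, usually the per-site alpha level.
#' @return One-tailed p-value in `(0, 1]`.
#' @examples
#' binomial_test_onesided(21, 85, 0.05)   # ~9e-10
#' @export
binomial_test_onesided <- function(k, n, alpha0) {
  stopifnot(length(k) == 1, length(n) == 1, k == round(k), n == round(n))
  if (k > n) stop("k must not exceed n")
  if (k < 0 || n < 1) stop("k must be >= 0 and n >= 1")
  if (alpha0 <= 0 || alpha0 >= 1) stop("alpha0 must lie in (0, 1)")
  stats::pbinom(k - 1, n, alpha0, lower.tail = FALSE)
}

#' One-sided binomial Bayes factor with a truncated-uniform prior
#'
#' `BF_+0` comparing a directional alternative `theta > alpha0` against the
#' point null `theta = alpha0` for `k` successes in `n` trials. The
#' alternative places a uniform (Beta(1, 1)) prior on `theta`, truncated to
#' `(alpha0, 1]`:
#' \deqn{BF_{+0} = \frac{\int_{\alpha_0}^{1} \theta^k (1-\theta)^{n-k}
#'   d\theta / (1 - \alpha_0)}{\alpha_0^k (1-\alpha_0)^{n-k}}}
#' The marginal integral is evaluated in log space through the regularized
#' incomplete beta function, so extreme `k`/`n` do not underflow.
#'
#' @inheritParams binomial_test_onesided
#' @param log If `TRUE` return the log Bayes factor.
#' @return `BF_+0` (> 0); values below 1/3 are conventionally read as
#'   evidence for the null rate.
#' @examples
#' binomial_bf_plus(5, 21, 0.05)   # 17.09
#' @export
binomial_bf_plus <- function(k, n, alpha0, log = FALSE) {
  stopifnot(length(k) == 1, length(n) == 1, k == round(k), n == round(n))
  if (k > n) stop("k must not exceed n")
  if (alpha0 <= 0 || alpha0 >= 1) stop("alpha0 must lie in (0, 1)")
  # log integral_a^1 th^k (1-th)^(n-k) dth = lbeta + log upper tail of Beta(k+1, n-k+1)
  log_marg <- lbeta(k + 1, n - k + 1) +
    stats::pbeta(alpha0, k + 1, n - k + 1, lower.tail = FALSE, log.p = TRUE) -
    log1p(-alpha0)
  log_null <- k * log(alpha0) + (n - k) * log1p(-alpha0)
  lbf <- log_marg - log_null
  if (log) lbf else exp(lbf)
}

#' Default (JZS) Bayes factor for a one-sample or paired t statistic
#'
#' Bayes factor for the alternative that the standardized effect `delta`
#' follows a Cauchy(0, `rscale`) prior against the point null `delta = 0`,
#' given an observed one-sample (or paired-difference) t statistic. The
#' marginal likelihood is the Cauchy-weighted noncentral-t density,
#' integrated by adaptive quadrature:
#' \deqn{BF_{10} = \frac{\int f_{t;\,n-1,\,\delta\sqrt{n}}(t)\,
#'   \mathrm{Cauchy}(\delta; 0, r)\, d\delta}{f_{t;\,n-1,\,0}(t)}}
#' With `sided = "plus"` (or `"minus"`) the prior mass is folded onto the
#' positive (negative) half line, giving the directional `BF_+0` (`BF_-0`).
#'
#' @param t Observed t statistic.
#' @param n Sample size (number of pairs for a paired design).
#' @param rscale Cauchy prior scale on the standardized effect; 0.707
#'   (`sqrt(2)/2`) is the common default.
#' @param sided `"two"`, `"plus"` or `"minus"`.
#' @return `BF_10` (or directional variant).
#' @export
jzs_ttest_bf <- function(t, n, rscale = sqrt(2) / 2, sided = c("two", "plus", "minus")) {
  sided <- match.arg(sided)
  if (!is.finite(t)) stop("t must be finite")
  if (n < 2) stop("n must be at least 2")
  df <- n - 1
  # dt(ncp) warns about its own precision limit (~1e-8); harmless here
  lik <- function(delta) suppressWarnings(
    stats::dt(t, df = df, ncp = delta * sqrt(n)))
  prior <- function(delta) stats::dcauchy(delta, 0, rscale)
  num <- switch(sided,
    two = stats::integrate(function(d) lik(d) * prior(d),
                           -Inf, Inf, rel.tol = 1e-9)$value,
    plus = 2 * stats::integrate(function(d) lik(d) * prior(d),
                                0, Inf, rel.tol = 1e-9)$value,
    minus = 2 * stats::integrate(function(d) lik(d) * prior(d),
                                 -Inf, 0, rel.tol = 1e-9)$value)
  num / stats::dt(t, df = df)
}

#' One-sided Bayes factor for a positive correlation
#'
#' Bayesian test of a positive population correlation `rho > 0` against
#' `rho = 0`, from an observed sample correlation. The prior on `rho` is a
#' stretched beta with width `kappa` (kappa = 1 is uniform on (-1, 1)),
#' folded onto the positive half. The sampling distribution of `r` given
#' `rho` uses the classical asymptotic likelihood kernel
#' `(1 - rho^2)^((n-1)/2) * (1 - rho * r)^(3/2 - n)`, which is accurate for
#' the moderate-n, |r| < 0.5 regime this pipeline works in.
#'
#' This parametric kernel is an approximation when applied to rank-based
#' coefficients (Spearman rho, Kendall tau); results on those inputs are
#' labelled approximate by the callers.
#'
#' @param r_obs Observed correlation, `|r_obs| < 1`.
#' @param n Number of observations, `n >= 4`.
#' @param kappa Stretched-beta prior width (1 = uniform).
#' @return `BF_+0` for a positive association.
#' @export
correlation_bf_plus <- function(r_obs, n, kappa = 1) {
  if (abs(r_obs) >= 1) stop("|r_obs| must be < 1")
  if (n < 4) stop("n must be at least 4")
  loglik <- function(rho) {
    (n - 1) / 2 * log1p(-rho^2) + (1.5 - n) * log1p(-rho * r_obs)
  }
  a <- 1 / kappa
  # prior on (-1, 1): rho = 2 * b - 1, b ~ Beta(1/kappa, 1/kappa); folded to (0, 1)
  log_prior <- function(rho) {
    stats::dbeta((rho + 1) / 2, a, a, log = TRUE) - log(2)
  }
  f <- function(rho) 2 * exp(loglik(rho) + log_prior(rho))
  num <- stats::integrate(f, 0, 1, rel.tol = 1e-9)$value
  num / exp(loglik(0))   # loglik(0) = 0, kept for clarity
}

#' Correlation bound giving a target directional Bayes factor
#'
#' Smallest observed correlation at which [correlation_bf_plus()] reaches
#' `bf`; with `bf = 1/3` this is the "evidence of absence" bound below which
#' a positive association is considered absent. The bound is approximate in
#' the same sense as [correlation_bf_plus()]; the pipeline defaults use the
#' fixed reference constant 0.085 for n = 60 instead (see
#' [classify_channels()]).
#'
#' @param n Number of observations.
#' @param bf Target Bayes factor.
#' @param kappa Prior width passed on.
#' @return Correlation bound in (0, 1).
#' @export
correlation_bf_bound <- function(n, bf = 1 / 3, kappa = 1) {
  stats::uniroot(function(r) correlation_bf_plus(r, n, kappa) - bf,
                 interval = c(1e-6, 0.9), tol = 1e-6)$root
}
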