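#' Normal-theory log posterior marginal likelihood
#'
#' With likelihood \eqn{\phi(x;\mu,\sigma^2)} and an improper flat prior,
#' the posterior is \eqn{N(x, \sigma^2)} and the posterior marginal
#' likelihood on a region \eqn{\Theta} is
#' \deqn{M_H(x) = (4\pi\sigma^2)^{-1/2}
#'   \frac{\int_\Theta \phi(\mu; x, \sigma^2/2)\,d\mu}
#'        {\int_\Theta \phi(\mu; x, \sigma^2)\,d\mu},}
#' every integral an exact normal cdf difference.  A point hypothesis uses
#' the plain likelihood \eqn{\phi(x;\mu_0,\sigma^2)}.
#'
#' @param x Estimate (original scale).
#' @param sigma Standard error, positive.
#' @param h An `ebf_hypothesis` (scalar kinds).
#' @return Log marginal likelihood in nats.
#' @export
normal_lml <- function(x, sigma, h) {
  stopifnot(sigma > 0)
  if (h$kind == "point")
    return(stats::dnorm(x, h$value, sigma, log = TRUE))
  if (h$kind %in% c("full", "vector")) {
    d <- if (h$kind == "full") h$d else h$d1 + h$d2
    return(-d / 2 * log(4 * pi * sigma^2))
  }
  b <- h_bounds(h)
  num <- lnorm_mass(b[1], b[2], x, sigma / sqrt(2))
  den <- lnorm_mass(b[1], b[2], x, sigma)
  if (!is.finite(den) || den == -Inf) stop("empty posterior mass on region")
  -0.5 * log(4 * pi * sigma^2) + num - den
}

## log Pr(a < N(m, s^2) < b), stable in either tail
lnorm_mass <- function(a, b, m, s) {
  if (is.infinite(a) && is.infinite(b)) return(0)
  if (is.infinite(a)) return(stats::pnorm(b, m, s, log.p = TRUE))
  if (is.infinite(b)) return(stats::pnorm(a, m, s, lower.tail = FALSE,
                                          log.p = TRUE))
  log_region_mass(stats::pnorm(a, m, s, log.p = TRUE),
                  stats::pnorm(b, m, s, log.p = TRUE),
                  stats::pnorm(a, m, s, lower.tail = FALSE, log.p = TRUE),
                  stats::pnorm(b, m, s, lower.tail = FALSE, log.p = TRUE))
}

#' EBFs for normal summary statistics
#'
#' `ebf_z()` is the general engine: it takes either a z-score (`z`, with
#' `se = 1` implied) or an `estimate` and `se`, and two hypotheses about
#' the mean, and assembles the EBF from exact normal-theory marginal
#' likelihoods and the normal bias rule.  The closed forms for the common
#' cases are available as wrappers:
#' \itemize{
#' \item `ebf_z_twosided(z, d)`: point null vs unrestricted d-dimensional
#'   alternative, \eqn{EBF_{01} = 2^{d/2} e^{-(z^2-d)/2}} (a chi-squared
#'   test when d > 1; pass `z = sqrt(chisq)`).
#' \item `ebf_z_onesided(z, sign_restricted)`: point null vs
#'   \eqn{\mu > 0}, \eqn{\sqrt2\,\Phi(z)/\Phi(z\sqrt2)\,e^{-(z^2-1/2)/2}},
#'   with exponent \eqn{(z^2-1)/2} when the opposite sign is impossible.
#' \item `ebf_z_directional(z)`: \eqn{\mu<0} vs \eqn{\mu>0},
#'   \eqn{\Phi(-z\sqrt2)\Phi(z) / [\Phi(z\sqrt2)\Phi(-z)]}; the two
#'   directional biases cancel.
#' }
#'
#' @param z Standardised statistic `estimate/se`.
#' @param estimate,se Estimate and its standard error (alternative input).
#' @param d Dimension (for the unrestricted alternative).
#' @param h0,h1 Hypotheses (`ebf_hypothesis`).
#' @param sign_restricted `TRUE` if the sign opposite to the alternative is
#'   impossible by definition.
#' @return An `ebf` object (all fields computed in log scale first, so very
#'   large |z| degrade gracefully to `ebf01` of 0 or `Inf`).
#' @examples
#' ebf_z_twosided(1.28)                     # stent trial: 1.03
#' ebf_z_directional(estimate = 16.6, se = 12.96, cut = 30)  # 2.29
#' @export
ebf_z <- function(z = NULL, estimate = NULL, se = NULL,
                  h0 = h_point(0), h1 = h_full(), d = 1L) {
  if (is.null(estimate)) {
    stopifnot(!is.null(z))
    estimate <- z; se <- 1
  } else stopifnot(!is.null(se), se > 0)
  if ((h0$kind == "full" && h0$d > 1L) || (h1$kind == "full" && h1$d > 1L) ||
      d > 1L) {
    if (h0$kind != "point" || h1$kind != "full")
      stop("d > 1 supported only for point null vs unrestricted alternative")
    return(ebf_z_twosided(estimate / se, d = max(d, h1$d)))
  }
  assemble_ebf(normal_lml(estimate, se, h0), normal_lml(estimate, se, h1),
               normal_bias(h0), normal_bias(h1),
               details = list(family = "normal", z = estimate / se))
}

#' @rdname ebf_z
#' @export
ebf_z_twosided <- function(z, d = 1L) {
  log_ebf01 <- (d / 2) * log(2) - (z^2 - d) / 2
  new_ebf(log_ebf01, bias0 = 0, bias1 = d / 2,
          details = list(family = "normal", form = "point vs two-sided",
                         z = z, d = d))
}

#' @rdname ebf_z
#' @export
ebf_z_onesided <- function(z, sign_restricted = FALSE) {
  bias1 <- if (sign_restricted) 0.5 else 0.25
  log_ebf01 <- 0.5 * log(2) + stats::pnorm(z, log.p = TRUE) -
    stats::pnorm(z * sqrt(2), log.p = TRUE) - z^2 / 2 + bias1
  new_ebf(log_ebf01, bias0 = 0, bias1 = bias1,
          details = list(family = "normal", form = "point vs one-sided",
                         z = z, sign_restricted = sign_restricted))
}

#' @rdname ebf_z
#' @param cut Threshold separating the two directional hypotheses
#'   (H0 below, H1 above) when `estimate`/`se` are given.
#' @export
ebf_z_directional <- function(z = NULL, estimate = NULL, se = NULL, cut = 0) {
  if (is.null(z)) z <- (estimate - cut) / se
  log_ebf01 <- stats::pnorm(-z * sqrt(2), log.p = TRUE) +
    stats::pnorm(z, log.p = TRUE) -
    stats::pnorm(z * sqrt(2), log.p = TRUE) -
    stats::pnorm(-z, log.p = TRUE)
  new_ebf(log_ebf01, bias0 = 0.25, bias1 = 0.25,
          details = list(family = "normal", form = "directional", z = z))
}

#' WAIC-like deviance criterion
#'
#' Minus twice the bias-corrected log posterior marginal likelihood of the
#' unrestricted normal hypothesis: the maximised deviance penalised by
#' `d * (1 + log 2)` (about 1.69 per parameter) — an AIC-like criterion
#' whose differences are interpretable on the Bayes-factor scale.
#'
#' @param max_loglik Maximised log likelihood (nats).
#' @param d Number of parameters.
#' @return The criterion value.
#' @examples
#' deviance_criterion(0, 1)  # 1.6931
#' @export
deviance_criterion <- function(max_loglik, d) {
  stopifnot(d >= 0)
  -2 * max_loglik + d * (1 + log(2))
}

#' Comparator Bayes-factor bounds and criteria
#'
#' The standard comparators for the two-sided normal test: the Sellke
#' P-value bound \eqn{-e\,p\log p} (valid for \eqn{p \le e^{-1}}), the
#' Held–Ott Beta(1, b) bound \eqn{-e(1-p)\log(1-p)}, the Bayesian
#' reference criterion \eqn{e^{-(z^2+1)/2}}, the minimum Bayes factor over
#' all priors \eqn{e^{-z^2/2}}, and the unit-information Bayes factor
#' \eqn{\sqrt{n+1}\,e^{-z^2 n/(2(n+1))}}.  All are in favour of H0.
#'
#' @param z z-statistic (for BRC, minimum and unit-information BFs).
#' @param p Two-sided P-value in (0, 1) (for the Sellke and Held–Ott bounds).
#' @param n Sample size (for the unit-information BF).
#' @return Named list with `sellke`, `held_ott`, `brc`, `min_bf`,
#'   `unit_information` (entries `NULL` when their input is missing).
#' @export
comparator_bfs <- function(z = NULL, p = NULL, n = NULL) {
  out <- list()
  if (!is.null(p)) {
    stopifnot(p > 0, p < 1)
    if (p > exp(-1))
      stop("Sellke bound is only valid for p <= exp(-1)")
    out$sellke <- -exp(1) * p * log(p)
    out$held_ott <- -exp(1) * (1 - p) * log1p(-p)
  }
  if (!is.null(z)) {
    out$brc <- exp(-(z^2 + 1) / 2)
    out$min_bf <- exp(-z^2 / 2)
    if (!is.null(n))
      out$unit_information <- sqrt(n + 1) * exp(-0.5 * z^2 * n / (n + 1))
  }
  out
}
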