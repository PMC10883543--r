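#' F-statistic log posterior marginal likelihood
#'
#' For an observed statistic `x` such that \eqn{rX \sim F_{\nu_1,\nu_2}}
#' for a scale parameter `r > 0` with the improper prior
#' \eqn{\pi(r) \propto 1/r}, the posterior is \eqn{x f_{\nu_1,\nu_2}(rx)}
#' and the squared density collapses to an F with doubled degrees of
#' freedom:
#' \deqn{M_H(x) = \frac{B(\nu_1,\nu_2)}{B(\nu_1/2,\nu_2/2)^2}
#'   \frac{x^{-1}\left[F_{2\nu_1,2\nu_2}\right]_\Theta}
#'        {\left[F_{\nu_1,\nu_2}\right]_\Theta}}
#' where \eqn{[F]_\Theta} denotes the cdf mass of `r*x` over the region —
#' so every case, including the one-sided ANOVA region `(0, 1]`, is a
#' closed cumulative form.  A point hypothesis `r = r0` uses the
#' likelihood \eqn{r_0 f_{\nu_1,\nu_2}(r_0 x)}.
#'
#' @param x Observed F statistic, positive.
#' @param nu1,nu2 Numerator and denominator degrees of freedom.
#' @param h An `ebf_hypothesis` on `r`, region within `(0, Inf)`.
#' @return Log marginal likelihood in nats.
#' @export
f_lml <- function(x, nu1, nu2, h) {
  stopifnot(x > 0, nu1 > 0, nu2 > 0)
  if (h$kind == "point") {
    stopifnot(h$value > 0)
    return(log(h$value) + stats::df(h$value * x, nu1, nu2, log = TRUE))
  }
  b <- h_bounds(h)
  lo <- max(b[1], 0); hi <- b[2]
  if (hi <= lo) stop("empty region on the positive half-line")
  num <- lf_mass(lo * x, hi * x, 2 * nu1, 2 * nu2)
  den <- lf_mass(lo * x, hi * x, nu1, nu2)
  if (!is.finite(den)) stop("empty posterior mass on region")
  lbeta(nu1, nu2) - 2 * lbeta(nu1 / 2, nu2 / 2) - log(x) + num - den
}

## log Pr(a < F_{v1,v2} < b)
lf_mass <- function(a, b, v1, v2) {
  if (a <= 0 && is.infinite(b)) return(0)
  if (a <= 0) return(stats::pf(b, v1, v2, log.p = TRUE))
  if (is.infinite(b)) return(stats::pf(a, v1, v2, lower.tail = FALSE,
                                       log.p = TRUE))
  log_region_mass(stats::pf(a, v1, v2, log.p = TRUE),
                  stats::pf(b, v1, v2, log.p = TRUE),
                  stats::pf(a, v1, v2, lower.tail = FALSE, log.p = TRUE),
                  stats::pf(b, v1, v2, lower.tail = FALSE, log.p = TRUE))
}

#' Scale-ratio density of two F distributions
#'
#' \eqn{G(w) = \int_0^\infty t\,f_{\nu_1,\nu_2}(t)\,f_{\nu_1,\nu_2}(tw)\,dt}:
#' simultaneously the inner integral of the expected-bias double integral
#' (after reducing by scale invariance) and the density of the ratio
#' \eqn{Y/X} of two independent F variates.  Evaluated on the log scale to
#' tame the heavy right tail at small `nu2`.
#'
#' @param w Ratio value(s), positive.
#' @param nu1,nu2 Degrees of freedom.
#' @return Density values.
#' @keywords internal
f_ratio_density <- function(w, nu1, nu2) {
  lo1 <- log(stats::qf(1e-13, nu1, nu2))
  hi1 <- log(stats::qf(1e-13, nu1, nu2, lower.tail = FALSE))
  vapply(w, function(ww) {
    lw <- log(ww)
    lo <- max(lo1, lo1 - lw); hi <- min(hi1, hi1 - lw)
    if (lo >= hi) return(0)
    f <- function(s) {
      t <- exp(s)
      r <- t^2 * stats::df(t, nu1, nu2) * stats::df(t * ww, nu1, nu2)
      r[!is.finite(r)] <- 0
      r
    }
    stats::integrate(f, lo, hi, rel.tol = 1e-10, abs.tol = 0,
                     subdivisions = 400L)$value
  }, numeric(1))
}

#' Expected bias for the F family
#'
#' By scale invariance the double integral over observed and replicate
#' statistics reduces to \eqn{\log[B(\nu_1,\nu_2)/B(\nu_1/2,\nu_2/2)^2]}
#' plus the differential entropy of the ratio \eqn{Y/X} of two independent
#' F variates, evaluated by nested quadrature on the log scale.  The same
#' value applies to the unrestricted scale hypothesis and to the one-sided
#' ANOVA alternative `r < 1` (values `r > 1` being implausible by
#' construction); point hypotheses are unbiased.  Values are cached.
#'
#' @param nu1,nu2 Degrees of freedom.
#' @param h An `ebf_hypothesis` (default unrestricted).
#' @return An `ebf_bias` for the F family.
#' @examples
#' f_bias(1, 1)  # 0.609
#' f_bias(5, 5)  # 0.527
#' @export
f_bias <- function(nu1, nu2, h = h_full()) {
  validate_hypothesis(h)
  if (h$kind == "point") return(bias_spec(0, "f", h))
  key <- sprintf("fbias_%.6g_%.6g", nu1, nu2)
  if (is.null(.ebf_cache[[key]])) {
    K <- lbeta(nu1, nu2) - 2 * lbeta(nu1 / 2, nu2 / 2)
    f <- function(v) {
      G <- f_ratio_density(exp(v), nu1, nu2)
      ifelse(G > 0, exp(v) * G * (K - log(G)), 0)
    }
    .ebf_cache[[key]] <- stats::integrate(f, -60, 60, rel.tol = 1e-8,
                                          abs.tol = 1e-7,
                                          subdivisions = 400L)$value
  }
  bias_spec(.ebf_cache[[key]], "f", h)
}

#' EBFs for F statistics and one-sided ANOVA
#'
#' `ebf_f()` assembles the EBF for any pair of hypotheses about the scale
#' ratio `r`.  `ebf_anova()` is the analysis-of-variance default:
#' `H0: r = 1` (point, plain F likelihood) against the one-sided
#' `H1: r < 1`, with the alternative's marginal likelihood in the closed
#' cumulative form and its bias equal to the unrestricted value.
#'
#' @inheritParams f_lml
#' @param h0,h1 Hypotheses on `r`.
#' @return An `ebf` object.
#' @examples
#' ebf_anova(3.2, 4, 20)
#' @export
ebf_f <- function(x, nu1, nu2, h0, h1) {
  assemble_ebf(f_lml(x, nu1, nu2, h0), f_lml(x, nu1, nu2, h1),
               f_bias(nu1, nu2, h0), f_bias(nu1, nu2, h1),
               details = list(family = "f", nu1 = nu1, nu2 = nu2))
}

#' @rdname ebf_f
#' @export
ebf_anova <- function(x, nu1, nu2) {
  ebf_f(x, nu1, nu2, h_point(1), h_interval(0, 1))
}
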