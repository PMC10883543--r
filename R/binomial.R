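#' Binomial log posterior marginal likelihood
#'
#' For `x` successes in `n` Bernoulli trials with a symmetric
#' `Beta(alpha, alpha)` prior (default uniform, `alpha = 1`), the posterior
#' is `Beta(x + alpha, n - x + alpha)` and
#' \deqn{M_H(x) = \binom{n}{x}
#'  \frac{B(2x+\alpha,\,2(n-x)+\alpha)}{B(x+\alpha,\,n-x+\alpha)}
#'  \frac{\int_\Theta f_B(p;\,2x+\alpha,\,2(n-x)+\alpha)\,dp}
#'       {\int_\Theta f_B(p;\,x+\alpha,\,n-x+\alpha)\,dp},}
#' all region masses exact incomplete-Beta differences, computed in log
#' space so counts in the thousands are safe.  A point hypothesis uses the
#' binomial pmf at `p0`.
#'
#' @param x Number of successes (0..n).
#' @param n Number of trials.
#' @param h An `ebf_hypothesis` on the probability, region within `[0, 1]`.
#' @param alpha Symmetric Beta prior parameter, default 1 (uniform).
#' @return Log marginal likelihood in nats.
#' @export
binom_lml <- function(x, n, h, alpha = 1) {
  stopifnot(n >= 1, x >= 0, x <= n, alpha > 0)
  if (h$kind == "point")
    return(stats::dbinom(x, n, h$value, log = TRUE))
  b <- clamp01(h_bounds(h))
  num <- lbeta_mass(b[1], b[2], 2 * x + alpha, 2 * (n - x) + alpha)
  den <- lbeta_mass(b[1], b[2], x + alpha, n - x + alpha)
  if (!is.finite(den)) stop("empty posterior mass on region")
  lchoose(n, x) + lbeta(2 * x + alpha, 2 * (n - x) + alpha) -
    lbeta(x + alpha, n - x + alpha) + num - den
}

clamp01 <- function(b) c(max(b[1], 0), min(b[2], 1))

## log Pr(a < Beta(s1, s2) < b); vectorised over the shape arguments
lbeta_mass <- function(a, b, s1, s2) {
  if (a <= 0 && b >= 1) return(rep(0, length(s1)))
  log_region_mass(stats::pbeta(a, s1, s2, log.p = TRUE),
                  stats::pbeta(b, s1, s2, log.p = TRUE),
                  stats::pbeta(a, s1, s2, lower.tail = FALSE, log.p = TRUE),
                  stats::pbeta(b, s1, s2, lower.tail = FALSE, log.p = TRUE))
}

#' Expected bias for the binomial family
#'
#' The exact `(n+1)^2`-term double sum over observed and replicate counts,
#' with joint prior predictive
#' \eqn{\Pr(x,y) = \binom{n}{x}\binom{n}{y}
#' B(x+y+\alpha,\,2n-x-y+\alpha)/B(\alpha,\alpha)} (uniform over x when
#' `alpha = 1`).  Each term is the log-ratio of the posterior marginal
#' likelihood of `x` to the marginal likelihood of `x` with prior taken
#' from the replicate `y`, including the region masses.
#'
#' @param n Number of trials.
#' @param h Hypothesis region within `[0, 1]` (default full).
#' @param alpha Symmetric Beta prior parameter.
#' @return An `ebf_bias` for the binomial family.
#' @examples
#' binom_bias(1)                      # (1/3) log 2 = 0.231
#' binom_bias(10, h_interval(0, 0.5)) # 0.210
#' @export
binom_bias <- function(n, h = h_full(), alpha = 1) {
  validate_hypothesis(h)
  if (h$kind == "point") return(bias_spec(0, "binomial", h))
  b <- clamp01(if (h$kind == "full") c(0, 1) else h_bounds(h))
  xs <- 0:n
  lpost_mass <- lbeta_mass(b[1], b[2], xs + alpha, n - xs + alpha)
  logM <- vapply(xs, function(x) binom_lml(x, n, interval_h(b), alpha),
                 numeric(1))
  xy <- expand.grid(x = xs, y = xs)
  lPr <- lchoose(n, xy$x) + lchoose(n, xy$y) +
    lbeta(xy$x + xy$y + alpha, 2 * n - xy$x - xy$y + alpha) -
    lbeta(alpha, alpha)
  lrep <- lchoose(n, xy$x) +
    lbeta(xy$x + xy$y + alpha, 2 * n - xy$x - xy$y + alpha) -
    lbeta(xy$y + alpha, n - xy$y + alpha) +
    lbeta_mass(b[1], b[2], xy$x + xy$y + alpha, 2 * n - xy$x - xy$y + alpha) -
    lpost_mass[xy$y + 1]
  bias <- sum(exp(lPr) * (logM[xy$x + 1] - lrep))
  bias_spec(bias, "binomial", h)
}

interval_h <- function(b) {
  if (b[1] <= 0 && b[2] >= 1) h_full()
  else if (b[1] <= 0) h_below(b[2])
  else if (b[2] >= 1) h_above(b[1])
  else h_interval(b[1], b[2])
}

#' EBF for a binomial count
#'
#' Assembles the EBF for any pair of hypotheses about a binomial
#' probability, with biases from the exact double sum.  For the symmetric
#' comparison of `[0, 0.5]` against `[0.5, 1]` the two biases are equal and
#' cancel.
#'
#' @inheritParams binom_lml
#' @param h0,h1 Hypotheses on the probability.
#' @return An `ebf` object.
#' @examples
#' ebf_binom(8, 10, h_below(0.5), h_above(0.5))
#' ebf_binom(5, 10, h_point(0.5), h_full())
#' @export
ebf_binom <- function(x, n, h0 = h_point(0.5), h1 = h_full(), alpha = 1) {
  assemble_ebf(binom_lml(x, n, h0, alpha), binom_lml(x, n, h1, alpha),
               binom_bias(n, h0, alpha), binom_bias(n, h1, alpha),
               details = list(family = "binomial", n = n, alpha = alpha))
}

#' Negative-binomial marginal likelihood, bias and EBF
#'
#' When the number of successes `x` is fixed by design and the number of
#' trials `N` is random, the likelihood for `p` is negative binomial,
#' \eqn{\binom{n-1}{x-1} p^x (1-p)^{n-x}}, and the same Beta posterior
#' algebra applies with \eqn{\binom{n-1}{x-1}} in place of
#' \eqn{\binom{n}{x}}.  The expected bias is taken over the exact prior
#' predictive of two replicate trial counts under the `Beta(alpha, alpha)`
#' prior; because that predictive is very heavy-tailed in `n`, the double
#' sum is evaluated by vectorised Monte Carlo (`p ~ Beta(alpha, alpha)`,
#' `n ~ x + NegBin(x, p)`) with a fixed internal seed, rather than by
#' truncation.  This construction of "replicate data of the same size"
#' (fixed `x`) is one interpretation; see the package vignette.
#'
#' @inheritParams binom_lml
#' @param reps,seed Monte Carlo settings for the bias evaluation.
#' @return `negbinom_lml`: log marginal likelihood; `negbinom_bias`: an
#'   `ebf_bias`; `ebf_negbinom`: an `ebf` object.
#' @export
negbinom_lml <- function(x, n, h, alpha = 1) {
  stopifnot(x >= 1, n >= x)
  if (h$kind == "point")
    return(stats::dnbinom(n - x, x, h$value, log = TRUE))
  binom_lml(x, n, h, alpha) - lchoose(n, x) + lchoose(n - 1, x - 1)
}

#' @rdname negbinom_lml
#' @export
negbinom_bias <- function(x, h = h_full(), alpha = 1,
                          reps = 2e5, seed = 20240222) {
  stopifnot(x >= 1)
  validate_hypothesis(h)
  if (h$kind == "point") return(bias_spec(0, "negbinomial", h))
  b <- clamp01(if (h$kind == "full") c(0, 1) else h_bounds(h))
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  p <- stats::rbeta(reps, alpha, alpha)
  n1 <- x + stats::rnbinom(reps, x, p)
  n2 <- x + stats::rnbinom(reps, x, p)
  bias <- mean(nb_bias_term(x, n1, n2, b, alpha))
  bias_spec(bias, "negbinomial", h)
}

## b(n1, n2): log posterior marginal likelihood of n1 minus log marginal
## likelihood of n1 with prior = posterior from replicate n2 (both NB in x)
nb_bias_term <- function(x, n1, n2, b, alpha) {
  lmass <- function(s1, s2) lbeta_mass(b[1], b[2], s1, s2)
  logM <- lbeta(2 * x + alpha, 2 * (n1 - x) + alpha) -
    lbeta(x + alpha, n1 - x + alpha) +
    lmass(2 * x + alpha, 2 * (n1 - x) + alpha) -
    lmass(x + alpha, n1 - x + alpha)
  lrep <- lbeta(2 * x + alpha, n1 + n2 - 2 * x + alpha) -
    lbeta(x + alpha, n2 - x + alpha) +
    lmass(2 * x + alpha, n1 + n2 - 2 * x + alpha) -
    lmass(x + alpha, n2 - x + alpha)
  logM - lrep
}

#' @rdname negbinom_lml
#' @param h0,h1 Hypotheses on the probability.
#' @export
ebf_negbinom <- function(x, n, h0 = h_point(0.5), h1 = h_full(), alpha = 1,
                         reps = 2e5, seed = 20240222) {
  assemble_ebf(negbinom_lml(x, n, h0, alpha), negbinom_lml(x, n, h1, alpha),
               negbinom_bias(x, h0, alpha, reps, seed),
               negbinom_bias(x, h1, alpha, reps, seed),
               details = list(family = "negbinomial", x = x, n = n))
}

#' Sampling-model-averaged EBF
#'
#' When it is unclear whether `x` or `n` was fixed by design, the
#' bias-corrected posterior marginal likelihoods are computed under both
#' the binomial and negative-binomial models and averaged arithmetically
#' (equal weights by default) before taking the ratio.
#'
#' @inheritParams ebf_negbinom
#' @param weights Model weights `(binomial, negative binomial)`, summing
#'   to 1.
#' @return An `ebf` object.
#' @export
ebf_binom_averaged <- function(x, n, h0 = h_point(0.5), h1 = h_full(),
                               alpha = 1, weights = c(0.5, 0.5),
                               reps = 2e5, seed = 20240222) {
  stopifnot(length(weights) == 2, all(weights >= 0),
            abs(sum(weights) - 1) < 1e-12)
  corrected <- function(h) {
    lb <- binom_lml(x, n, h, alpha) - bias_value(binom_bias(n, h, alpha))
    ln <- negbinom_lml(x, n, h, alpha) -
      bias_value(negbinom_bias(x, h, alpha, reps, seed))
    log_sum_exp(log(weights[1]) + lb, log(weights[2]) + ln)
  }
  m0 <- corrected(h0); m1 <- corrected(h1)
  assemble_ebf(m0, m1, 0, 0,
               details = list(family = "model-averaged", weights = weights))
}
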