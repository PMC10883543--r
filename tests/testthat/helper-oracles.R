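## Independent brute-force oracles used across the suite.  These integrate
## the defining expressions directly and deliberately share no code with
## the package's closed forms.

bv <- ebfactor:::bias_value
h_bounds <- ebfactor:::h_bounds

## Eq-5-style normal posterior marginal likelihood by quadrature
oracle_normal_lml <- function(x, sigma, lo, hi) {
  num <- integrate(function(mu) dnorm(x, mu, sigma) * dnorm(mu, x, sigma),
                   lo, hi, rel.tol = 1e-12)$value
  den <- integrate(function(mu) dnorm(mu, x, sigma), lo, hi,
                   rel.tol = 1e-12)$value
  log(num / den)
}

## product-of-t posterior marginal likelihood by quadrature (s = 1)
oracle_t_lml_full <- function(x, nu) {
  log(integrate(function(mu) dt(x - mu, nu) * dt(mu - x, nu),
                -Inf, Inf, rel.tol = 1e-12)$value)
}

## direct Beta-function evaluation of the binomial posterior marginal
oracle_binom_lml <- function(x, n, lo, hi, alpha = 1) {
  num <- integrate(function(p) dbinom(x, n, p) * dbeta(p, x + alpha, n - x + alpha),
                   lo, hi, rel.tol = 1e-12)$value
  den <- pbeta(hi, x + alpha, n - x + alpha) - pbeta(lo, x + alpha, n - x + alpha)
  log(num / den)
}

## quadrature of the F posterior marginal likelihood over a region in r
oracle_f_lml <- function(x, nu1, nu2, lo, hi) {
  num <- integrate(function(r) r * x^2 * df(r * x, nu1, nu2)^2, lo, hi,
                   rel.tol = 1e-12)$value
  den <- integrate(function(r) x * df(r * x, nu1, nu2), lo, hi,
                   rel.tol = 1e-12)$value
  log(num / den) - log(x)
}

## brute-force evaluation of the two P-value Beta integrals; substituted
## to unit scale so the quadrature is well conditioned for tiny p
oracle_pvalue_M <- function(p) {
  L <- log1p(-p)                      # < 0; decay scale of (1-p)^b
  num <- integrate(function(t) {
    b <- 1 + t / (-2 * L)
    b^2 * exp((2 * b - 1) * L) / (-2 * L)
  }, 0, Inf, rel.tol = 1e-10)$value
  den <- integrate(function(t) {
    b <- 1 + t / (-L)
    b * exp(b * L) / (-L)
  }, 0, Inf, rel.tol = 1e-10)$value
  num / den
}
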