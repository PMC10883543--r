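#' Expected-bias reference tables
#'
#' Regenerates the expected-bias tables for the t, binomial and F
#' families over the requested grids (quadrature for t and F, exact
#' double sums for the binomial).
#'
#' @param family `"t"`, `"binomial"` or `"f"`.
#' @param nu Degrees-of-freedom grid (t).
#' @param n Trial-count grid (binomial).
#' @param regions List of hypothesis regions (binomial); default the full
#'   interval and the lower half.
#' @param nu1,nu2 Degrees-of-freedom grids (F).
#' @param alpha Beta prior parameter (binomial).
#' @return A data frame in long format with the grid columns and `bias`.
#' @examples
#' bias_table("t", nu = 1:3)
#' @export
bias_table <- function(family = c("t", "binomial", "f"),
                       nu = 1:10, n = 1:10,
                       regions = list(h_full(), h_interval(0, 0.5)),
                       nu1 = c(1, 5, 10, 20, 50), nu2 = c(1, 5, 10, 20, 50),
                       alpha = 1) {
  family <- match.arg(family)
  switch(family,
    t = data.frame(nu = nu,
                   bias = vapply(nu, function(v) bias_value(t_bias(v)),
                                 numeric(1))),
    binomial = do.call(rbind, lapply(seq_along(regions), function(k) {
      h <- regions[[k]]
      b <- clamp01(if (h$kind == "full") c(0, 1) else h_bounds(h))
      data.frame(region = sprintf("[%g,%g]", b[1], b[2]), n = n,
                 bias = vapply(n, function(nn)
                   bias_value(binom_bias(nn, h, alpha)), numeric(1)))
    })),
    f = {
      gr <- expand.grid(nu1 = nu1, nu2 = nu2)
      gr$bias <- mapply(function(a, b) bias_value(f_bias(a, b)),
                        gr$nu1, gr$nu2)
      gr
    })
}

#' P-value calibration of the evidence-unit scale
#'
#' For each requested number of evidence units, inverts the EBF closed
#' forms to find the P-value at which the EBF in favour of the
#' alternative equals `base^units`: the two-sided normal test, the
#' chi-squared test with 2 and 3 df, and the 10p rule.  With `units = 0`
#' each column gives the knife-edge P-value at which the EBF is 1.
#'
#' @param units Evidence units (base `2 + sqrt(3)`).
#' @return Data frame with `units`, `ebf` (in favour of H1), and the four
#'   P-value columns.
#' @examples
#' calibration_table(1:4)
#' @export
calibration_table <- function(units = 1:4) {
  B <- evidence_base()
  ebf10 <- B^units
  p_chisq <- function(d) {
    z2 <- d + 2 * ((d / 2) * log(2) + log(ebf10))
    stats::pchisq(z2, d, lower.tail = FALSE)
  }
  data.frame(units = units, ebf = ebf10,
             normal_2sided = p_chisq(1),
             chisq_2df = p_chisq(2),
             chisq_3df = p_chisq(3),
             pvalue_10p = 1 / (10 * ebf10))
}
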