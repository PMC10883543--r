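#' @keywords internal
"_PACKAGE"

## package-level cache: evidence base, bias tables
.ebf_cache <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  .ebf_cache$base <- tryCatch(compute_evidence_base(),
                              error = function(e) 2 + sqrt(3))
}

#' The evidence-unit base 2 + sqrt(3)
#'
#' Belief, as a probability, responds to evidence through the logistic
#' function of the log posterior odds; the effect of a unit of evidence is
#' its first derivative.  The sharpest separation between "weaker" belief
#' (easily moved) and "stronger" belief (not) is where that effect changes
#' fastest, i.e. where the third derivative of the logistic vanishes, at
#' log-odds \eqn{x^* = \log(2+\sqrt 3)}.  A Bayes factor of
#' \eqn{2+\sqrt 3 \approx 3.73} therefore moves any weaker belief to a
#' stronger one and counts as one unit of evidence.
#'
#' The base is obtained numerically by root-finding on the third derivative
#' (and cached at load time); `compute_evidence_base()` exposes the
#' computation itself.
#'
#' @return The base, `2 + sqrt(3)` to full precision.
#' @examples
#' evidence_base()
#' log(13.93, base = evidence_base())  # ~2 units
#' @export
evidence_base <- function() {
  if (is.null(.ebf_cache$base))
    .ebf_cache$base <- tryCatch(compute_evidence_base(),
                                error = function(e) 2 + sqrt(3))
  .ebf_cache$base
}

#' @rdname evidence_base
#' @export
compute_evidence_base <- function() {
  ## sigma'''(x) = sigma'(x) (1 - 6 sigma + 6 sigma^2); root of second factor
  third_factor <- function(x) {
    s <- stats::plogis(x)
    1 - 6 * s + 6 * s^2
  }
  xstar <- stats::uniroot(third_factor, c(0.1, 5), tol = 1e-14)$root
  exp(xstar)
}

#' Convert a Bayes factor to evidence units
#'
#' @param bf Positive Bayes factor(s).
#' @return `log(bf)` in base `2 + sqrt(3)`; one unit is a factor of 3.73.
#' @examples
#' evidence_units(3.73)   # ~1
#' evidence_units(1/13.9) # ~-2
#' @export
evidence_units <- function(bf) {
  if (any(bf <= 0, na.rm = TRUE)) stop("Bayes factor must be positive")
  log(bf) / log(evidence_base())
}

#' Assemble an EBF from two bias-corrected log marginal likelihoods
#'
#' The empirical Bayes factor in favour of H0 over H1 is the ratio of the
#' bias-corrected posterior marginal likelihoods,
#' \deqn{EBF_{01} = \frac{M_{H_0}(x)\,e^{-E_Y b_{H_0}(Y)}}
#'                       {M_{H_1}(x)\,e^{-E_Y b_{H_1}(Y)}}.}
#' All family-specific front ends reduce to this assembly rule.
#'
#' @param log_m0,log_m1 Log posterior marginal likelihoods (nats); `-Inf`
#'   encodes an impossible hypothesis.
#' @param bias0,bias1 Expected biases \eqn{E_Y b_H(Y)} in nats.
#' @param details Optional named list stored on the result (method notes).
#' @return An object of class `ebf`: a list with `ebf01`, `log_ebf01`
#'   (nats), `units` (signed evidence units), `posterior_prob_h0` (at even
#'   prior odds), `favoured` (`"H0"`, `"H1"` or `"neutral"`), and the
#'   assembly components.
#' @examples
#' assemble_ebf(log_m0 = 0, log_m1 = 0, bias0 = 0.5, bias1 = 0.25)
#' @export
assemble_ebf <- function(log_m0, log_m1, bias0 = 0, bias1 = 0,
                         details = list()) {
  bias0 <- bias_value(bias0); bias1 <- bias_value(bias1)
  if (is.infinite(log_m0) && log_m0 < 0 && is.infinite(log_m1) && log_m1 < 0)
    stop("both hypotheses have zero marginal likelihood; evidence undefined")
  log_ebf01 <- (log_m0 - bias0) - (log_m1 - bias1)
  new_ebf(log_ebf01, log_m0 = log_m0, log_m1 = log_m1,
          bias0 = bias0, bias1 = bias1, details = details)
}

bias_value <- function(b) {
  if (inherits(b, "ebf_bias")) b$value else as.numeric(b)
}

new_ebf <- function(log_ebf01, log_m0 = NA_real_, log_m1 = NA_real_,
                    bias0 = NA_real_, bias1 = NA_real_, details = list()) {
  ebf01 <- exp(log_ebf01)
  structure(list(
    ebf01 = ebf01,
    log_ebf01 = log_ebf01,
    units = log_ebf01 / log(evidence_base()),
    posterior_prob_h0 = 1 / (1 + exp(-log_ebf01)),
    favoured = if (log_ebf01 > 0) "H0" else if (log_ebf01 < 0) "H1" else "neutral",
    log_m0 = log_m0, log_m1 = log_m1, bias0 = bias0, bias1 = bias1,
    details = details), class = "ebf")
}

#' @export
print.ebf <- function(x, digits = 4, ...) {
  cat("Empirical Bayes factor\n")
  ebf10 <- exp(-x$log_ebf01)
  cat(sprintf("  EBF01 = %.*g  (EBF10 = %.*g)\n", digits, x$ebf01,
              digits, ebf10))
  cat(sprintf("  log EBF01 = %.*g nats;  %.*g units of evidence (base %.4f)\n",
              digits, x$log_ebf01, digits, x$units, evidence_base()))
  cat(sprintf("  Pr(H0 | even prior odds) = %.*g;  favours %s\n",
              digits, x$posterior_prob_h0, x$favoured))
  if (!is.na(x$bias0) || !is.na(x$bias1))
    cat(sprintf("  bias corrections (nats): H0 %.4g, H1 %.4g\n",
                x$bias0, x$bias1))
  invisible(x)
}

#' Expected-bias specification
#'
#' A small container tying an expected bias \eqn{E_Y b_H(Y)} (nats) to the
#' likelihood family and hypothesis it belongs to.
#'
#' @param value Bias in nats (non-negative for the families implemented).
#' @param family One of `"normal"`, `"t"`, `"binomial"`, `"negbinomial"`,
#'   `"f"`, `"pvalue"`.
#' @param hypothesis The `ebf_hypothesis` the bias refers to.
#' @return Object of class `ebf_bias`.
#' @export
bias_spec <- function(value, family, hypothesis = NULL) {
  structure(list(value = value, family = family, hypothesis = hypothesis),
            class = "ebf_bias")
}

#' @export
print.ebf_bias <- function(x, ...) {
  cat(sprintf("Expected bias %.4g nats (%s family)\n", x$value, x$family))
  invisible(x)
}

#' Expected bias under normal theory
#'
#' For a regular normal model the expected bias of the log posterior
#' marginal likelihood is half the dimension for the unrestricted
#' hypothesis; a directional (half-line) hypothesis halves it to 1/4 unless
#' the opposite sign is impossible by definition, in which case the
#' unrestricted value 1/2 applies; finite-interval and point hypotheses are
#' unbiased.  A vector of d1 one-sided and d2 two-sided components has bias
#' `(d1 + 2*d2)/4`.
#'
#' @param h An `ebf_hypothesis`.
#' @return An `ebf_bias` for the normal family.
#' @examples
#' normal_bias(h_full())        # 0.5
#' normal_bias(h_above(0))      # 0.25
#' normal_bias(h_interval(0, 1))# 0
#' @export
normal_bias <- function(h) {
  validate_hypothesis(h)
  v <- switch(h$kind,
              point    = 0,
              interval = 0,
              lower    = if (h$sign_restricted) 0.5 else 0.25,
              upper    = if (h$sign_restricted) 0.5 else 0.25,
              full     = h$d / 2,
              vector   = (h$d1 + 2 * h$d2) / 4)
  bias_spec(v, "normal", h)
}

## log of a cdf-mass difference, careful in the tails:
## lcdf(b) and lcdf(a) are log cdf values; returns log(cdf(b) - cdf(a))
log_cdf_diff <- function(lcdf_b, lcdf_a) {
  ifelse(is.infinite(lcdf_a) & lcdf_a < 0, lcdf_b,
         lcdf_b + log1p(-exp(lcdf_a - lcdf_b)))
}

## log Pr(a < X < b) from the four log tail probabilities:
## low_* = log F(.), up_* = log (1 - F(.)).  Uses whichever tail keeps the
## difference free of cancellation; a region straddling the median is
## computed as 1 - F(a) - S(b) in linear space (mass is then O(1)).
log_region_mass <- function(low_a, low_b, up_a, up_b) {
  lhalf <- log(0.5)
  ifelse(low_b <= lhalf, log_cdf_diff(low_b, low_a),
         ifelse(up_a <= lhalf, log_cdf_diff(up_a, up_b),
                log1p(-exp(low_a) - exp(up_b))))
}

log_sum_exp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}
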