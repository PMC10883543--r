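#' Hypotheses about a scalar (or independent-component vector) parameter
#'
#' An `ebf_hypothesis` describes the parameter region \eqn{\Theta_H} under a
#' hypothesis: a point, a half-line, a finite interval, the full line, or a
#' vector of independent one- and two-sided components.  The region determines
#' both the marginal-likelihood integrals and the expected-bias correction.
#'
#' @param kind One of `"point"`, `"lower"` (\eqn{\theta < } `upper`),
#'   `"upper"` (\eqn{\theta > } `lower`), `"interval"`, `"full"`, `"vector"`.
#' @param value Parameter value for a point hypothesis.
#' @param lower,upper Region endpoints; `-Inf`/`Inf` allowed.
#' @param d Dimension for `kind = "full"` (number of two-sided components).
#' @param d1,d2 Numbers of one- and two-sided components for `kind = "vector"`.
#' @param sign_restricted For half-line hypotheses: `TRUE` if the opposite
#'   sign is impossible by definition (e.g. a variance component), in which
#'   case the expected bias is that of the unrestricted hypothesis rather
#'   than half of it.
#' @return An object of class `ebf_hypothesis`.
#' @examples
#' h_point(0)
#' h_above(30)
#' h_interval(-1, 1)
#' @export
hypothesis <- function(kind = c("point", "lower", "upper", "interval",
                                "full", "vector"),
                       value = 0, lower = -Inf, upper = Inf,
                       d = 1L, d1 = 0L, d2 = 0L, sign_restricted = FALSE) {
  kind <- match.arg(kind)
  h <- structure(list(kind = kind, value = value, lower = lower,
                      upper = upper, d = as.integer(d),
                      d1 = as.integer(d1), d2 = as.integer(d2),
                      sign_restricted = isTRUE(sign_restricted)),
                 class = "ebf_hypothesis")
  validate_hypothesis(h)
  h
}

validate_hypothesis <- function(h) {
  stopifnot(inherits(h, "ebf_hypothesis"))
  if (h$kind == "interval") {
    if (!is.finite(h$lower) || !is.finite(h$upper))
      stop("interval hypotheses need finite endpoints; use a half-line kind")
    if (h$lower >= h$upper) stop("interval hypothesis needs lower < upper")
  }
  if (h$kind == "point" && !is.finite(h$value))
    stop("point hypothesis needs a finite value")
  if (h$kind == "full" && h$d < 1L) stop("dimension d must be >= 1")
  if (h$kind == "vector" && (h$d1 < 0L || h$d2 < 0L || h$d1 + h$d2 < 1L))
    stop("vector hypothesis needs d1, d2 >= 0 with d1 + d2 >= 1")
  invisible(h)
}

#' @rdname hypothesis
#' @export
h_point <- function(value = 0) hypothesis("point", value = value)

#' @rdname hypothesis
#' @param cut Boundary of a half-line region.
#' @export
h_below <- function(cut = 0, sign_restricted = FALSE)
  hypothesis("lower", upper = cut, sign_restricted = sign_restricted)

#' @rdname hypothesis
#' @export
h_above <- function(cut = 0, sign_restricted = FALSE)
  hypothesis("upper", lower = cut, sign_restricted = sign_restricted)

#' @rdname hypothesis
#' @export
h_interval <- function(lower, upper) hypothesis("interval", lower = lower,
                                                upper = upper)

#' @rdname hypothesis
#' @export
h_full <- function(d = 1L) hypothesis("full", d = d)

#' @rdname hypothesis
#' @export
h_vector <- function(d1 = 0L, d2 = 0L) hypothesis("vector", d1 = d1, d2 = d2)

#' Region endpoints of a scalar hypothesis
#' @param h An `ebf_hypothesis`.
#' @return Numeric `c(lower, upper)`; a point collapses to `c(v, v)`.
#' @keywords internal
h_bounds <- function(h) {
  switch(h$kind,
         point    = c(h$value, h$value),
         lower    = c(-Inf, h$upper),
         upper    = c(h$lower, Inf),
         interval = c(h$lower, h$upper),
         full     = c(-Inf, Inf),
         stop("vector hypotheses have no scalar bounds"))
}

is_composite <- function(h) h$kind != "point"

#' Parse a hypothesis specification string
#'
#' Mini-grammar used by the table interface: `point:<v>`, `greater:<v>`
#' (append `!` for a sign-restricted parameter, e.g. `greater:0!`),
#' `less:<v>`, `interval:<a>,<b>`, `two-sided` (the full line), and
#' `full:<d>` for a d-dimensional unrestricted hypothesis.
#'
#' @param spec Character scalar.
#' @return An `ebf_hypothesis`.
#' @examples
#' parse_hypothesis("interval:0,0.5")
#' @export
parse_hypothesis <- function(spec) {
  spec <- trimws(tolower(spec))
  if (spec %in% c("two-sided", "two.sided", "full")) return(h_full())
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("cannot parse hypothesis spec '", spec, "'")
  kw <- parts[1]
  restricted <- grepl("!$", parts[2])
  arg <- sub("!$", "", parts[2])
  vals <- suppressWarnings(as.numeric(strsplit(arg, ",", fixed = TRUE)[[1]]))
  if (anyNA(vals)) stop("non-numeric value in hypothesis spec '", spec, "'")
  switch(kw,
         point    = h_point(vals[1]),
         greater  = h_above(vals[1], sign_restricted = restricted),
         less     = h_below(vals[1], sign_restricted = restricted),
         interval = {
           if (length(vals) != 2L) stop("interval needs two endpoints")
           h_interval(vals[1], vals[2])
         },
         full     = h_full(d = vals[1]),
         stop("unknown hypothesis keyword '", kw, "'"))
}

#' @export
print.ebf_hypothesis <- function(x, ...) {
  desc <- switch(x$kind,
                 point    = sprintf("theta = %g", x$value),
                 lower    = sprintf("theta < %g%s", x$upper,
                                    if (x$sign_restricted) " (opposite sign impossible)" else ""),
                 upper    = sprintf("theta > %g%s", x$lower,
                                    if (x$sign_restricted) " (opposite sign impossible)" else ""),
                 interval = sprintf("theta in [%g, %g]", x$lower, x$upper),
                 full     = sprintf("theta unrestricted (d = %d)", x$d),
                 vector   = sprintf("vector: %d one-sided, %d two-sided components",
                                    x$d1, x$d2))
  cat("Hypothesis:", desc, "\n")
  invisible(x)
}
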