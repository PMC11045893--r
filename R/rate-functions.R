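#' Generalized gate rate function
#'
#' A rate function is one member of the three-branch generalized family used
#' for every transition rate, steady-state and time-constant curve in the
#' library.  Writing `x = (k1 - v) * k2` for a driver value `v` (usually a
#' membrane voltage), the branches are
#'
#' * `f_t = 0` (exp-linear): `k0 * (k1 - v) / (exp(x) - 1)`
#' * `f_t = 1` (exponential): `k0 * exp(x)`
#' * `f_t = 2` (sigmoid): `k0 / (exp(x) + 1)`
#'
#' and the returned value is `a * f(v) + b`.  The affine wrap (`a`, `b`)
#' extends the bare family so that constant rates (`f_t = 1`, `k2 = 0`),
#' offset time constants and saturating activation curves can be expressed;
#' `a = 1`, `b = 0` recovers the bare branches.
#'
#' Branch 0 has a removable singularity at `x = 0`; [eval_rate()] evaluates
#' the analytic limit `k0 / k2` whenever `|x| < 1e-7` (l'Hopital).
#'
#' @param f_t integer branch selector, one of 0, 1, 2.
#' @param k0,k1,k2 real constants of the branch.
#' @param a,b affine wrap: the evaluated rate is `a * f(v) + b`.
#' @return An object of class `rate_function`.
#' @seealso [eval_rate()], [parse_neuroml_rate()]
#' @examples
#' # alpha_n of the original squid-axon model: 0.01 (V + 10) / (exp((V + 10)/10) - 1)
#' rn <- rate_function(0, k0 = -0.01, k1 = -10, k2 = -0.1)
#' eval_rate(rn, 0)  # 0.1 / (e - 1)
#' @export
rate_function <- function(f_t, k0, k1, k2, a = 1, b = 0) {
  if (length(f_t) != 1L || !f_t %in% c(0, 1, 2))
    stop("'f_t' must be a single value in {0, 1, 2}", call. = FALSE)
  for (nm in c("k0", "k1", "k2", "a", "b")) {
    val <- get(nm)
    if (length(val) != 1L || !is.numeric(val) || !is.finite(val))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
  }
  if (f_t == 0 && k2 == 0)
    stop("branch f_t = 0 requires k2 != 0 (the k2 = 0 limit is not defined)",
         call. = FALSE)
  structure(
    list(f_t = as.integer(f_t), k0 = as.numeric(k0), k1 = as.numeric(k1),
         k2 = as.numeric(k2), a = as.numeric(a), b = as.numeric(b)),
    class = "rate_function")
}

# tolerance below which branch 0 switches to its analytic limit k0/k2
.rate_singularity_eps <- 1e-7

# Vectorized core used by both eval_rate() and the compiled simulator.
# All arguments recycle to a common length (standard R recycling).
.eval_rate_core <- function(f_t, k0, k1, k2, a, b, v) {
  n <- max(length(f_t), length(v))
  f_t <- rep_len(f_t, n); k0 <- rep_len(k0, n); k1 <- rep_len(k1, n)
  k2 <- rep_len(k2, n); a <- rep_len(a, n); b <- rep_len(b, n)
  v <- rep_len(v, n)
  x <- (k1 - v) * k2
  out <- numeric(n)
  i0 <- f_t == 0
  i1 <- f_t == 1
  i2 <- f_t == 2
  if (any(i0)) {
    # k0 * (k1 - v) / (exp(x) - 1), guarded at the removable singularity
    x0 <- x[i0]
    res <- k0[i0] * (k1[i0] - v[i0]) / expm1(x0)
    lim <- which(abs(x0) < .rate_singularity_eps)   # which() drops NAs
    if (length(lim)) res[lim] <- k0[i0][lim] / k2[i0][lim]
    out[i0] <- res
  }
  if (any(i1)) out[i1] <- k0[i1] * exp(x[i1])
  if (any(i2)) out[i2] <- k0[i2] / (exp(x[i2]) + 1)
  a * out + b
}

#' Evaluate a rate function
#'
#' @param r a [rate_function()].
#' @param v numeric vector of driver values (membrane voltage or an auxiliary
#'   state, in the units of the model definition).
#' @return Numeric vector of rates, same length as `v`.
#' @examples
#' eval_rate(rate_function(2, k0 = 1, k1 = -30, k2 = 1 / 5.5), c(-60, -30, 0))
#' @export
eval_rate <- function(r, v) {
  stopifnot(inherits(r, "rate_function"))
  if (!is.numeric(v) || any(!is.finite(v)))
    stop("'v' must be finite numeric", call. = FALSE)
  .eval_rate_core(r$f_t, r$k0, r$k1, r$k2, r$a, r$b, as.numeric(v))
}

#' @export
print.rate_function <- function(x, ...) {
  body <- switch(as.character(x$f_t),
    "0" = sprintf("%g*(%g - v)/(exp((%g - v)*%g) - 1)", x$k0, x$k1, x$k1, x$k2),
    "1" = sprintf("%g*exp((%g - v)*%g)", x$k0, x$k1, x$k2),
    "2" = sprintf("%g/(exp((%g - v)*%g) + 1)", x$k0, x$k1, x$k2))
  wrap <- if (x$a != 1 || x$b != 0) sprintf("%g*[%s] + %g", x$a, body, x$b) else body
  cat("<rate_function> f_t =", x$f_t, ":", wrap, "\n")
  invisible(x)
}
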