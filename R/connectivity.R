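#' Counter-based Squares random numbers
#'
#' The Squares generator is stateless: each 32-bit output is a pure function
#' of a 64-bit counter and a 64-bit key, produced by four middle-square
#' rounds.  Statelessness is what lets connectivity weights be regenerated
#' entry-by-entry on demand instead of being stored: entry `(i, j)` of a
#' weight matrix is always derived from the same counter.
#'
#' `squares32()` returns the raw 32-bit words (as doubles, exact);
#' `uniform01()` divides them by 2^32 to give uniforms in `[0, 1)`.
#'
#' Counters and keys are passed as non-negative doubles and used exactly up
#' to 2^53, far beyond the counter ranges addressed here.
#'
#' @param counter numeric vector of counters (`>= 0`).
#' @param key a single key, ideally from [make_squares_key()].
#' @return `squares32()`: doubles holding integers in `[0, 2^32)`;
#'   `uniform01()`: doubles in `[0, 1)`.
#' @examples
#' key <- make_squares_key(42)
#' squares32(0:4, key)
#' uniform01(0:4, key)
#' @export
squares32 <- function(counter, key) {
  stopifnot(is.numeric(counter), all(counter >= 0), all(is.finite(counter)),
            is.numeric(key), length(key) == 1L, key >= 0, is.finite(key))
  .squares32_cpp(as.numeric(counter), as.numeric(key))
}

#' @rdname squares32
#' @export
uniform01 <- function(counter, key) {
  stopifnot(is.numeric(counter), all(counter >= 0), all(is.finite(counter)),
            is.numeric(key), length(key) == 1L, key >= 0, is.finite(key))
  .squares_u01_cpp(as.numeric(counter), as.numeric(key))
}

#' Construct a Squares key from a seed
#'
#' Squares keys must be irregular 64-bit constants for the middle-square
#' rounds to mix well.  Following the published key-construction procedure,
#' the key is assembled from hexadecimal digits where the low eight digits
#' are pairwise distinct and non-zero with an odd lowest digit, and the high
#' eight digits are pairwise distinct and non-zero.  The digit choices are
#' drawn deterministically from `seed` with a small splitmix-style scrambler,
#' so equal seeds give equal keys.
#'
#' @param seed a single non-negative integer-valued number.
#' @return A double holding the 64-bit key value (below 2^53 so that the
#'   value is exact; the top 11 bits of the key are left zero, which the
#'   middle-square rounds tolerate since all digits in use are non-zero).
#' @export
make_squares_key <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed), seed >= 0)
  # deterministic integer scrambler on 31-bit state (portable in doubles)
  state <- (as.numeric(seed) + 0x9E37) %% 2147483647
  nxt <- function() {
    state <<- (state * 48271) %% 2147483647   # Lehmer step, exact in doubles
    state
  }
  pick_digits <- function(k, odd_first) {
    pool <- 1:15
    digits <- integer(k)
    for (i in seq_len(k)) {
      cand <- pool
      if (i == 1L && odd_first) cand <- cand[cand %% 2L == 1L]
      digits[i] <- cand[(nxt() %% length(cand)) + 1L]
      pool <- setdiff(pool, digits[i])
    }
    digits
  }
  low <- pick_digits(8L, odd_first = TRUE)    # low digits, lowest first
  high <- pick_digits(5L, odd_first = FALSE)  # 13 hex digits total < 2^53
  digits <- c(low, high)
  sum(digits * 16 ^ (seq_along(digits) - 1))
}

#' Inverse standard-normal CDF (probit)
#'
#' Maps uniforms in `(0, 1)` to standard-normal quantiles; used to turn
#' Squares uniforms into Gaussian connectivity weights.
#'
#' @param u numeric vector with all entries strictly inside `(0, 1)`.
#' @return Standard-normal quantiles.
#' @export
probit <- function(u) {
  if (!is.numeric(u) || any(u <= 0) || any(u >= 1))
    stop("'u' must lie strictly inside (0, 1)", call. = FALSE)
  stats::qnorm(u)
}

#' Weight-source specification
#'
#' Describes how a connectivity-weight matrix is generated on the fly, so a
#' network model can carry the recipe instead of the `n^2` values.
#'
#' @param dist `"uniform"` or `"gaussian"`.
#' @param key Squares key (or a seed passed through [make_squares_key()] when
#'   `is_seed = TRUE`).
#' @param mu,sigma mean and standard deviation for the Gaussian mode.
#' @param symmetric mirror the upper triangle onto the lower one?
#' @param scale global multiplier applied to the generated `[0, 1]` weights
#'   (e.g. a gap conductance).
#' @param is_seed treat `key` as a seed for [make_squares_key()]?
#' @return An object of class `weight_source`.
#' @export
weight_source <- function(dist = c("uniform", "gaussian"), key,
                          mu = 0.5, sigma = 0.15, symmetric = TRUE,
                          scale = 1, is_seed = FALSE) {
  dist <- match.arg(dist)
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma), length(sigma) == 1L, sigma >= 0,
            is.logical(symmetric), length(symmetric) == 1L,
            is.numeric(scale), length(scale) == 1L, is.finite(scale))
  if (isTRUE(is_seed)) key <- make_squares_key(key)
  structure(
    list(dist = dist, key = as.numeric(key), mu = as.numeric(mu),
         sigma = as.numeric(sigma), symmetric = isTRUE(symmetric),
         scale = as.numeric(scale)),
    class = "weight_source")
}

# counter addressing: row-major over the zero-based index pair; for
# symmetric matrices the upper-triangle counter (min, max) is shared.
.weight_counter <- function(i, j, n, symmetric) {
  if (symmetric) {
    lo <- pmin(i, j); hi <- pmax(i, j)
    (lo - 1) * n + (hi - 1)
  } else {
    (i - 1) * n + (j - 1)
  }
}

.weight_value <- function(u, src) {
  if (src$dist == "uniform") w <- u
  else {
    u <- pmin(pmax(u, 2^-33), 1 - 2^-33)     # keep probit finite
    w <- src$mu + src$sigma * stats::qnorm(u)
    w <- pmin(pmax(w, 0), 1)                 # weights range 0.0 to 1.0
  }
  w * src$scale
}

#' Generate a connectivity-weight matrix
#'
#' Produces the `n x n` matrix described by a [weight_source()]: zero
#' diagonal, entries in `[0, 1)` (uniform) or `mu + sigma * probit(u)`
#' clipped to `[0, 1]` (Gaussian), times `scale`.  Entry `(i, j)` derives
#' from Squares counter `(i - 1) * n + (j - 1)` (row-major; the
#' upper-triangle counter for symmetric matrices), so any single entry can
#' be regenerated without materializing the matrix — see [weight_entry()].
#'
#' @param n_cells matrix side (`>= 1`).
#' @param source a [weight_source()]; alternatively pass `dist`, `key`, ...
#'   directly as `...` which are forwarded to [weight_source()].
#' @param ... forwarded to [weight_source()] when `source` is missing.
#' @return An `n_cells` x `n_cells` numeric matrix.
#' @export
generate_weights <- function(n_cells, source = NULL, ...) {
  stopifnot(is.numeric(n_cells), length(n_cells) == 1L, n_cells >= 1)
  n <- as.integer(n_cells)
  if (is.null(source)) source <- weight_source(...)
  stopifnot(inherits(source, "weight_source"))
  idx <- expand.grid(j = seq_len(n), i = seq_len(n))   # row-major in i
  ctr <- .weight_counter(idx$i, idx$j, n, source$symmetric)
  u <- uniform01(ctr, source$key)
  w <- matrix(.weight_value(u, source), n, n, byrow = TRUE)
  diag(w) <- 0
  w
}

#' @rdname generate_weights
#' @param i,j entry indices (1-based).
#' @export
weight_entry <- function(i, j, n_cells, source) {
  stopifnot(inherits(source, "weight_source"))
  ctr <- .weight_counter(i, j, as.integer(n_cells), source$symmetric)
  out <- .weight_value(uniform01(ctr, source$key), source)
  out[i == j] <- 0
  out
}

#' Realized weight matrix of a network model
#'
#' Returns the model's weight matrix, generating it from the model's
#' [weight_source()] if necessary; an uncoupled model yields all zeros.
#'
#' @param model a [network_model()].
#' @return Numeric matrix with zero diagonal.
#' @export
realized_weights <- function(model) {
  stopifnot(inherits(model, "network_model"))
  n <- n_cells(model)
  if (is.null(model$weights)) return(matrix(0, n, n))
  if (inherits(model$weights, "weight_source"))
    return(generate_weights(n, model$weights))
  model$weights
}
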