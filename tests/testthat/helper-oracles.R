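# Independent oracles used across the suite.  These are direct
# transcriptions of the printed equations / brute-force emulations, kept
# deliberately separate from the package's code paths.

# -- original squid-axon rate equations (V in original sign convention) ----
# singular points are evaluated by their analytic limits
hh_rates_direct <- list(
  alpha_n = function(V) ifelse(abs(V + 10) < 1e-12, 0.1,
                               0.01 * (V + 10) / (exp((V + 10) / 10) - 1)),
  beta_n = function(V) 0.125 * exp(V / 80),
  alpha_m = function(V) ifelse(abs(V + 25) < 1e-12, 1,
                               0.1 * (V + 25) / (exp((V + 25) / 10) - 1)),
  beta_m = function(V) 4 * exp(V / 18),
  alpha_h = function(V) 0.07 * exp(V / 20),
  beta_h = function(V) 1 / (exp((V + 30) / 10) + 1))

# conductances / reversals used by the scalar step transcription
hh_const <- list(g_na = 120, v_na = -115, g_k = 36, v_k = 12,
                 g_l = 0.3, v_l = -10.613, C = 1)

# one hand-transcribed scalar forward-Euler step of the squid-axon cell
hh_scalar_step <- function(V, n, m, h, i_app, dt) {
  r <- hh_rates_direct
  i_k <- hh_const$g_k * (V - hh_const$v_k) * n^4
  i_na <- hh_const$g_na * (V - hh_const$v_na) * m^3 * h
  i_l <- hh_const$g_l * (V - hh_const$v_l)
  list(V = V + dt * (i_app - i_k - i_na - i_l) / hh_const$C,
       n = n + dt * ((1 - n) * r$alpha_n(V) - n * r$beta_n(V)),
       m = m + dt * ((1 - m) * r$alpha_m(V) - m * r$beta_m(V)),
       h = h + dt * ((1 - h) * r$alpha_h(V) - h * r$beta_h(V)))
}

# -- brute-force dense gap current, naive double loop ----------------------
gap_dense_direct <- function(w, v, c0, c1, c2) {
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    vij <- v[i] - v[j]
    out[i] <- out[i] + w[i, j] * (c0 * exp(c1 * vij^2) + c2) * vij
  }
  out
}

# -- tick-by-tick emulation of the gap kernel's accumulation pipeline ------
# One chunk of `uf` lanes issues per tick; the loop-carried accumulation
# dependency (latency = depth) keeps each cell's window open for at least
# `depth` ticks before its sum can be read out and the next cell started.
pipeline_emulate <- function(n_cells, uf, depth) {
  t <- 0L
  for (cell in seq_len(n_cells)) {
    issued <- 0L
    start <- t
    while (issued * uf < n_cells || t - start < depth) {
      if (issued * uf < n_cells) issued <- issued + 1L
      t <- t + 1L
    }
  }
  t
}

# -- probit oracle: root-finding on the normal CDF -------------------------
probit_root <- function(p) {
  vapply(p, function(pp)
    uniroot(function(z) pnorm(z) - pp, c(-10, 10), tol = 1e-12)$root,
    numeric(1))
}

# small random test network with gap junctions on single-compartment cells
make_test_gap_network <- function(n, symmetric = FALSE, seed = 1) {
  set.seed(seed)
  comp <- compartment_spec(capacitance = 1, g_leak = 0.1, v_leak = -60,
                           has_gap = TRUE, name = "soma")
  w <- matrix(runif(n * n), n, n)
  if (symmetric) w <- (w + t(w)) / 2
  diag(w) <- 0
  network_model(replicate(n, cell_spec(list(comp)), simplify = FALSE),
                c0 = 0.8, c1 = -0.01, c2 = 0.2, weights = w)
}
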