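test_that("one Euler step advances a single gate linearly", {
  ab <- gate_spec("alpha_beta", rate1 = rate_function(1, 1, 0, 0),
                  rate2 = rate_function(1, 1, 0, 0))
  m <- network_model(cell_spec(list(compartment_spec(
    channels = list(channel_spec(0, 0, list(ab)))))))
  st <- structure(list(V = 0, y = 0, s = numeric(0), t = 0),
                  class = "ehh_state")
  st1 <- euler_step(m, st, dt = 0.1)
  expect_equal(st1$y, 0.1)
  expect_equal(st1$t, 0.1)
  # dt = 0 leaves the state untouched
  st0 <- euler_step(m, st, dt = 0)
  expect_equal(st0$V, st$V)
  expect_equal(st0$y, st$y)
  # input state is never modified
  expect_equal(st$y, 0)
})

test_that("one step of the squid-axon cell matches the scalar transcription", {
  m <- build_original_hh()
  v0 <- 0
  st <- init_state(m, v0)
  stim <- list(list(cell = 1, comp = 1, spec = stim_constant(-10)))
  got <- euler_step(m, st, stim, dt = 0.01)
  want <- hh_scalar_step(v0, st$y[1], st$y[2], st$y[3], i_app = -10, dt = 0.01)
  expect_equal(got$V, want$V, tolerance = 1e-12)
  expect_equal(got$y, c(want$n, want$m, want$h), tolerance = 1e-12)
})

test_that("steady-state gate values are the fixed points of the dynamics", {
  m <- build_original_hh()
  y0 <- steady_state_gates(m, 0)
  expect_equal(y0[1], 0.3176769, tolerance = 1e-6)   # n at rest
  # fixed point: derivative vanishes
  cp <- m$cells[[1]]$compartments[[1]]
  gates <- c(cp$channels[[1]]$gates, cp$channels[[2]]$gates)
  for (k in seq_along(gates))
    expect_equal(gate_derivative(gates[[k]], y0[k], 0), 0, tolerance = 1e-14)
  # alpha == beta gives one half
  g <- gate_spec("alpha_beta", rate1 = rate_function(1, 2, 0, 0),
                 rate2 = rate_function(1, 2, 0, 0))
  m2 <- network_model(cell_spec(list(compartment_spec(
    channels = list(channel_spec(1, 0, list(g)))))))
  expect_equal(steady_state_gates(m2, -50), 0.5)
  # relaxation gates return inf exactly
  it <- gate_spec("inf_tau", rate1 = rate_function(2, 1, -30, 0.2),
                  rate2 = rate_function(1, 5, 0, 0))
  m3 <- network_model(cell_spec(list(compartment_spec(
    channels = list(channel_spec(1, 0, list(it)))))))
  expect_identical(steady_state_gates(m3, -42), eval_rate(it$rate1, -42))
})

test_that("stimuli evaluate their kinds and conventions", {
  p <- stim_pulse(5, on = 1, off = 2)
  expect_equal(eval_stimulus(p, 1.5), 5)
  expect_equal(eval_stimulus(p, 2), 0)         # half-open interval
  expect_equal(eval_stimulus(p, 1), 5)
  expect_equal(eval_stimulus(stim_constant(3), c(0, 10, 1e6)), rep(3, 3))
  s <- stim_series(c(1, 2, 4), c(10, 20, 40))
  expect_equal(eval_stimulus(s, c(1, 1.5, 3, 100)), c(10, 10, 20, 40))
  expect_warning(out <- eval_stimulus(s, 0.5), "before the first")
  expect_equal(out, 0)
  expect_error(stim_pulse(1, on = 2, off = 2), "on < off")
  expect_error(stim_series(c(2, 1), c(1, 2)), "increasing")
})

test_that("transition-rate gates stay in the unit interval when dt*(a+b) <= 1", {
  m <- build_original_hh()
  set.seed(99)
  for (amp in runif(4, -30, 5)) {
    stim <- list(list(cell = 1, comp = 1, spec = stim_constant(amp)))
    tr <- run_simulation(m, sim_config(dt = 0.01, n_steps = 1500, v0 = 0,
                                       stimuli = stim, record = "all"))
    v <- tr[, 2]
    # the sufficient condition held on the visited voltage range
    rates <- sapply(hh_rates_direct, function(f) f(v))
    worst <- max(rates[, "alpha_n"] + rates[, "beta_n"],
                 rates[, "alpha_m"] + rates[, "beta_m"],
                 rates[, "alpha_h"] + rates[, "beta_h"])
    expect_lt(0.01 * worst, 1)
    expect_true(all(tr[, 3:5] >= 0 & tr[, 3:5] <= 1))
  }
})

test_that("forward Euler converges at first order on the squid-axon preset", {
  m <- build_original_hh()
  stim <- list(list(cell = 1, comp = 1, spec = stim_constant(-10)))
  t_end <- 4
  run_v <- function(dt) {
    cfg <- sim_config(dt = dt, n_steps = round(t_end / dt), v0 = 0,
                      stimuli = stim)
    run_simulation(m, cfg)[, 2]
  }
  dt_ref <- 0.01 / 64
  ref <- run_v(dt_ref)
  dts <- c(0.04, 0.02, 0.01)
  errs <- vapply(dts, function(dt) {
    v <- run_v(dt)
    idx <- seq(1, length(ref), by = round(dt / dt_ref))
    max(abs(v - ref[idx]))
  }, numeric(1))
  slope <- coef(lm(log(errs) ~ log(dts)))[2]
  expect_gt(slope, 0.85)
  expect_lt(slope, 1.15)
})

test_that("simulations are deterministic and record on the stride", {
  net <- build_io_network(3, weights = weight_source("uniform", key = 5,
                                                     is_seed = TRUE))
  cfg <- sim_config(dt = 0.05, n_steps = 100, v0 = -60, record_stride = 10L)
  tr1 <- run_simulation(net, cfg)
  tr2 <- run_simulation(net, cfg)
  expect_identical(tr1, tr2)
  expect_equal(nrow(tr1), 11L)            # t = 0 plus every 10th step
  expect_equal(tr1[, "time"], seq(0, 5, by = 0.5))
})

test_that("identical cells with symmetric coupling stay permutation-symmetric", {
  w <- matrix(0.04, 4, 4); diag(w) <- 0
  net <- build_io_network(4, weights = w)
  tr <- run_simulation(net, sim_config(dt = 0.05, n_steps = 200, v0 = -60))
  dend <- unclass(tr)[, 2 + 3 * (0:3)]
  for (k in 2:4) expect_identical(unname(dend[, 1]), unname(dend[, k]))
})

test_that("numerical blow-ups raise an instability error naming the variable", {
  m <- build_original_hh()
  st <- structure(list(V = NA_real_, y = c(0.3, 0.05, 0.6), s = numeric(0),
                       t = 0), class = "ehh_state")
  expect_error(euler_step(m, st, dt = 0.01), "finite")
  big <- sim_config(dt = 1e6, n_steps = 50, v0 = 0,
                    stimuli = list(list(cell = 1, comp = 1,
                                        spec = stim_constant(-10))))
  expect_error(run_simulation(m, big), "instability|step")
})
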