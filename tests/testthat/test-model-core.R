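test_that("gate products multiply activations with their exponents", {
  expect_equal(gate_product(0.5, 4), 0.0625)
  expect_equal(gate_product(c(0.2, 0.6), c(3, 1)), 0.0048)
  expect_equal(gate_product(numeric(0), numeric(0)), 1)
  # monotone non-decreasing in each activation for exponents >= 1
  set.seed(7)
  for (rep in 1:20) {
    p <- sample(1:4, 3, replace = TRUE)
    y <- runif(3)
    k <- sample(3, 1)
    y2 <- y; y2[k] <- min(1, y[k] + runif(1, 0, 1 - y[k]))
    expect_gte(gate_product(y2, p), gate_product(y, p))
  }
})

test_that("channel, leak and membrane terms follow their definitions", {
  ch <- channel_spec(36, 12)
  expect_equal(channel_current(ch, 10, 0.0625), 36 * (10 - 12) * 0.0625)
  expect_equal(channel_current(ch, 12, 0.5), 0)
  expect_equal(channel_current(channel_spec(0, 12), 100, 1), 0)

  cp <- compartment_spec(capacitance = 1, g_leak = 0.3, v_leak = -10.613)
  expect_equal(leak_current(cp, 0), 0.3 * 10.613)
  expect_equal(leak_current(cp, -10.613), 0)
  expect_equal(leak_current(compartment_spec(g_leak = 0), 50), 0)

  expect_equal(membrane_derivative(cp, i_app = 10), 10)
  expect_equal(membrane_derivative(cp, i_app = 7, i_channels = 3,
                                   i_leak = 2, i_mc = 1, i_gap = 1), 0)
  cp2 <- compartment_spec(capacitance = 2)
  expect_equal(membrane_derivative(cp2, i_app = 10),
               membrane_derivative(compartment_spec(capacitance = 1),
                                   i_app = 10) / 2)
})

test_that("inter-compartment currents split over the surface ratios", {
  two <- cell_spec(list(compartment_spec(), compartment_spec(p_up = 0.2)),
                   g_int = 0.13)
  expect_equal(mc_current(two, 2, c(-50, -60)), 0.13 * (-10) / 0.2)
  expect_equal(mc_current(two, 1, c(-50, -60)), 0.13 * (10) / 0.8)
  expect_equal(mc_current(two, 2, c(-55, -55)), 0)
  expect_error(mc_current(two, 3, c(-55, -55)), "out of range")

  # interior compartment with symmetric neighbours and equal ratios
  three <- cell_spec(list(compartment_spec(), compartment_spec(p_up = 0.5),
                          compartment_spec(p_up = 0.5)), g_int = 1)
  expect_equal(mc_current(three, 2, c(-60 + 3, -60, -60 - 3)), 0)
  # uniform ratios conserve current within the cell
  v <- c(-71, -55, -62)
  tot <- sum(vapply(1:3, function(i) mc_current(three, i, v), numeric(1)))
  expect_equal(tot, 0, tolerance = 1e-12)
})

test_that("gate and auxiliary derivatives follow their formulations", {
  ab <- gate_spec("alpha_beta",
                  rate1 = rate_function(1, 2, 0, 0),
                  rate2 = rate_function(1, 3, 0, 0))
  expect_equal(gate_derivative(ab, 0, -60), 2)
  expect_equal(gate_derivative(ab, 1, -60), -3)
  it <- gate_spec("inf_tau",
                  rate1 = rate_function(2, 1, -30, 0.2),
                  rate2 = rate_function(1, 5, 0, 0))
  inf <- eval_rate(it$rate1, -42)
  expect_equal(gate_derivative(it, inf, -42), 0)
  bad <- gate_spec("inf_tau", rate1 = rate_function(1, 1, 0, 0),
                   rate2 = rate_function(1, -1, 0, 0))
  expect_error(gate_derivative(bad, 0.5, -60), "time constant")

  aux <- aux_state_spec(1, c_current = -3.0, c_self = -0.075)
  expect_equal(aux_derivative(aux, s = 4, current = -1), 2.7)
  expect_equal(aux_derivative(aux, s = 0, current = 0), 0)
  expect_equal(aux_derivative(aux_state_spec(1, 0, -1), s = 5, current = 9), -5)
})

test_that("dense gap currents match the naive double-loop oracle", {
  set.seed(11)
  n <- 9
  w <- matrix(runif(n * n), n, n); diag(w) <- 0
  v <- runif(n, -80, -30)
  got <- gap_current_dense(w, v, c0 = 0.8, c1 = -0.01, c2 = 0.2)
  expect_equal(got, gap_dense_direct(w, v, 0.8, -0.01, 0.2),
               tolerance = 1e-14)
  # hand-evaluated two-cell case
  two <- gap_current_dense(matrix(c(0, 1, 1, 0), 2), c(10, 0),
                           c0 = 0.8, c1 = -0.01, c2 = 0.2)
  expect_equal(two, c(4.943036, -4.943036), tolerance = 1e-6)
  # zero weights and equal voltages give zero currents
  expect_equal(gap_current_dense(matrix(0, n, n), v, 0.8, -0.01, 0.2),
               numeric(n))
  expect_equal(gap_current_dense(w, rep(-55, n), 0.8, -0.01, 0.2), numeric(n))
  expect_error(gap_current_dense(w[, -1], v, 0.8, -0.01, 0.2), "shape")
})

test_that("symmetric weights conserve total gap current", {
  for (seed in 1:5) {
    net <- make_test_gap_network(10, symmetric = TRUE, seed = seed)
    v <- runif(10, -80, -30)
    ig <- gap_current_dense(net, v)
    expect_lt(abs(sum(ig)) / sum(abs(ig)), 1e-9)
  }
})

test_that("model constructors enforce their invariants", {
  expect_error(channel_spec(-1, 0), "conductance")
  expect_error(compartment_spec(capacitance = 0), "capacitance")
  expect_error(cell_spec(list()), "non-empty")
  gapc <- compartment_spec(has_gap = TRUE)
  expect_error(cell_spec(list(gapc, gapc)), "has_gap")
  expect_error(network_model(cell_spec(list(gapc)), weights = matrix(0, 2, 2)),
               "matrix must be")
  expect_error(
    compartment_spec(channels = list(channel_spec(1, 0)),
                     aux_states = list(aux_state_spec(2, 1, -1))),
    "references channel")
})
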