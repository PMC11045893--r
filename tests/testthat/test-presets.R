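test_that("the squid-axon preset carries the classic three gates", {
  m <- build_original_hh()
  expect_equal(n_cells(m), 1L)
  expect_equal(n_compartments(m), 1L)
  expect_equal(n_gate_vars(m), 3L)
  cp <- m$cells[[1]]$compartments[[1]]
  gates <- unlist(lapply(cp$channels, function(ch)
    vapply(ch$gates, `[[`, character(1), "name")))
  expect_setequal(gates, c("n", "m", "h"))
  exps <- unlist(lapply(cp$channels, function(ch)
    vapply(ch$gates, `[[`, integer(1), "exponent")))
  expect_setequal(exps, c(4L, 3L, 1L))
  # alpha_n at rest and beta_m at V = 18, against hand evaluation
  n_gate <- cp$channels[[1]]$gates[[1]]
  expect_equal(eval_rate(n_gate$rate1, 0), 0.1 / (exp(1) - 1),
               tolerance = 1e-12)
  m_gate <- cp$channels[[2]]$gates[[1]]
  expect_equal(eval_rate(m_gate$rate2, 18), 4 * exp(1), tolerance = 1e-12)
})

test_that("preset rate records reproduce the printed equations on a grid", {
  m <- build_original_hh()
  cp <- m$cells[[1]]$compartments[[1]]
  recs <- list(alpha_n = cp$channels[[1]]$gates[[1]]$rate1,
               beta_n = cp$channels[[1]]$gates[[1]]$rate2,
               alpha_m = cp$channels[[2]]$gates[[1]]$rate1,
               beta_m = cp$channels[[2]]$gates[[1]]$rate2,
               alpha_h = cp$channels[[2]]$gates[[2]]$rate1,
               beta_h = cp$channels[[2]]$gates[[2]]$rate2)
  grid <- seq(-110, 60, by = 0.25)
  for (nm in names(recs)) {
    got <- eval_rate(recs[[nm]], grid)
    want <- hh_rates_direct[[nm]](grid)
    expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("the squid-axon cell rests at its fixed point and fires when driven", {
  m <- build_original_hh()
  vr <- resting_voltage(m)
  expect_lt(abs(vr), 0.05)              # leak reversal balances rest near 0
  # 50 ms unstimulated: stays at rest
  tr <- run_simulation(m, sim_config(dt = 0.01, n_steps = 5000, v0 = vr,
                                     record_stride = 10L))
  expect_lt(max(abs(tr[, 2] - tr[1, 2])), 1e-3)
  # suprathreshold constant current: full action potential within 20 ms
  stim <- list(list(cell = 1, comp = 1, spec = stim_constant(-10)))
  tr2 <- run_simulation(m, sim_config(dt = 0.01, n_steps = 2000, v0 = vr,
                                      stimuli = stim))
  expect_gt(max(abs(tr2[, 2] - vr)), 80)
})

test_that("the olivary cell has the documented compartment and gate layout", {
  cell <- build_io_cell()
  expect_equal(length(cell$compartments), 3L)
  per_comp <- gates_per_compartment(cell)
  expect_equal(sum(per_comp), 13L)
  expect_true(all(per_comp >= 3L & per_comp <= 6L))
  labels <- vapply(cell$compartments, `[[`, character(1), "name")
  expect_equal(labels, c("dendrite", "soma", "axon"))
  expect_true(cell$compartments[[1]]$has_gap)
  expect_false(any(vapply(cell$compartments[2:3], `[[`, logical(1), "has_gap")))
  # the calcium state lives on the dendrite and feeds the KCa gate
  expect_equal(length(cell$compartments[[1]]$aux_states), 1L)
  s_gate <- cell$compartments[[1]]$channels[[2]]$gates[[1]]
  expect_equal(s_gate$driver, "aux")
})

test_that("olivary networks scale counts and decouple at zero weight", {
  net <- build_io_network(8)
  expect_equal(n_compartments(net), 24L)
  expect_equal(n_gate_vars(net), 104L)
  one <- build_io_network(1)
  expect_equal(dim(realized_weights(one)), c(1L, 1L))

  # zero-weight network == independent single-cell runs, element-wise
  z <- build_io_network(3, weights = matrix(0, 3, 3))
  cfgn <- sim_config(dt = 0.05, n_steps = 100, v0 = -60)
  trn <- run_simulation(z, cfgn)
  tr1 <- run_simulation(build_io_network(1), cfgn)
  for (cell in 0:2)
    expect_identical(unname(unclass(trn)[, 2:4 + 3 * cell, drop = FALSE]),
                     unname(unclass(tr1)[, 2:4, drop = FALSE]))
})

test_that("the olivary network is numerically stable at its default step", {
  net <- build_io_network(2, weights = weight_source("uniform", key = 11,
                                                     is_seed = TRUE))
  tr <- run_simulation(net, sim_config(dt = 0.05, n_steps = 2000, v0 = -60,
                                       record_stride = 20L, record = "all"))
  expect_true(all(is.finite(tr)))
  vcols <- grep("/V$", colnames(tr))
  expect_true(all(tr[, vcols] > -120 & tr[, vcols] < 80))
  # gate columns stay in the unit interval
  ycols <- setdiff(seq_len(ncol(tr))[-1], c(vcols, grep("/Ca$", colnames(tr))))
  expect_true(all(tr[, ycols] >= 0 & tr[, ycols] <= 1))
})
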