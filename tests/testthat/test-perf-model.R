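test_that("cell-kernel DRAM throughput follows the per-stream accounting", {
  c1 <- perf_config(uf_cell = 1, f = 1)
  expect_equal(hhmc_dram_throughput(c1, 3, 3), 100 + 44 / 3 + 4 / 9)
  c3 <- perf_config(uf_cell = 3, f = 1)
  expect_equal(hhmc_dram_throughput(c3, 3, 3), 300 + 44 + 4 / 3)
  # strictly increasing in frequency
  f <- c(1e8, 2e8, 3e8)
  th <- vapply(f, function(ff)
    hhmc_dram_throughput(perf_config(uf_cell = 1, f = ff), 3, 3), numeric(1))
  expect_true(all(diff(th) > 0))
})

test_that("gap-kernel DRAM throughput crosses the bandwidth at 118 MHz", {
  expect_equal(gap_dram_throughput(perf_config(uf_gap = 32, f = 118e6)),
               1.5104e10)
  expect_gt(gap_dram_throughput(perf_config(uf_gap = 32, f = 118e6)), 15e9)
  expect_lt(gap_dram_throughput(perf_config(uf_gap = 32, f = 117e6)), 15e9)
  expect_equal(gap_dram_throughput(perf_config(uf_gap = 32, f = 1e-9)), 0,
               tolerance = 1)

  expect_equal(min_freq_exceeding_dram(perf_config(uf_gap = 32)), 118L)
  expect_equal(min_freq_exceeding_dram(perf_config(uf_gap = 16)), 235L)
  # doubling the unroll factor halves the threshold up to integer rounding
  f16 <- min_freq_exceeding_dram(perf_config(uf_gap = 16))
  f32 <- min_freq_exceeding_dram(perf_config(uf_gap = 32))
  expect_lte(abs(f16 - 2 * f32), 1)
})

test_that("memory-block counts multiply the three ceiled ratios", {
  geo <- perf_config()                     # 36 x 1024 x 1 geometry
  expect_equal(mem_blocks(36, 1024, 1, geo), 1)
  expect_equal(mem_blocks(64, 2048, 2, geo), 8)
  # vectorizing 8 values never costs blocks once the store is deep enough
  # (depths a multiple of 8 block-depths, so no ragged rounding penalty)
  set.seed(4)
  for (rep in 1:30) {
    wreq <- sample(8:64, 1); dreq <- 8 * 1024 * sample(1:8, 1)
    preq <- sample(1:4, 1)
    plain <- mem_blocks(wreq, dreq, preq, geo)
    vec <- mem_blocks(wreq * 8, dreq / 8, preq, geo)
    expect_lte(vec, plain)
  }
})

test_that("stage ticks match the tick-by-tick pipeline emulation", {
  for (uf in c(1, 2, 4, 8)) {
    for (d in c(1, 3, 7, 16)) {
      cfg <- perf_config(uf_gap = uf, d_gap = d)
      for (n in c(1:12, 16, 31, 32, 48, 64)) {
        expect_equal(stage_ticks(cfg, n), pipeline_emulate(n, uf, d),
                     info = sprintf("n=%d uf=%d d=%d", n, uf, d))
      }
    }
  }
  # printed-branch examples: depth-bound and saturated
  cfg <- perf_config(uf_gap = 16, d_gap = 90)
  expect_equal(stage_ticks(cfg, 100), 9000)
  expect_equal(stage_ticks(cfg, 3200), 640000)
  expect_equal(stage_ticks(cfg, 3200), 3200^2 / 16)
  # the two regimes agree at the boundary n = d * uf
  expect_equal(stage_ticks(cfg, 90 * 16), (90 * 16) * 90)
})

test_that("multi-kernel ticks reproduce the linear and quadratic regimes", {
  cfg4 <- perf_config(uf_gap = 16, d_gap = 90, n_dfes = 4)
  expect_equal(hhmcg_ticks(cfg4, 6400, 1), 640000)       # saturated
  expect_equal(hhmcg_ticks(cfg4, 64, 1), 5760)           # depth-bound
  cfg1 <- perf_config(uf_gap = 16, d_gap = 90)
  expect_equal(hhmcg_ticks(cfg1, 100, 1), stage_ticks(cfg1, 100))
  # depth-bound regime is linear in N
  ns <- c(16, 32, 64, 128)
  ticks <- vapply(ns, function(n) hhmcg_ticks(cfg4, n, 1), numeric(1))
  expect_equal(ticks / ns, rep(ticks[1] / ns[1], 4))
  # saturated regime is quadratic in N
  nq <- c(6400, 12800)
  tq <- vapply(nq, function(n) hhmcg_ticks(cfg4, n, 1), numeric(1))
  expect_equal(tq[2] / tq[1], 4)
  # perfect scaling: per-kernel ticks fall as 1/K, so the aggregate over
  # all K kernels is constant at fixed total N in the saturated regime
  for (K in c(1, 2, 4, 8)) {
    cfgk <- perf_config(uf_gap = 16, d_gap = 50, n_dfes = K)
    expect_equal(K * hhmcg_ticks(cfgk, 6400, 1), 6400^2 / 16)
  }
})

test_that("cell and monolithic gap tick counts follow their formulas", {
  cfg <- perf_config(uf_cell = 2, size_buffer = 16)
  expect_equal(cell_ticks(cfg, c(4, 5, 4), 10), 10 * (2 + 3 + 2) + 16)
  cfg_big <- perf_config(uf_cell = 8, size_buffer = 16)
  expect_equal(cell_ticks(cfg_big, c(4, 5, 4), 10), 10 * 3 + 16)
  expect_equal(cell_ticks(perf_config(uf_cell = 1, size_buffer = 0), 1, 1), 1)

  expect_equal(gap_ticks_monolithic(perf_config(uf_gap = 16), 64, 2), 512)
  expect_equal(gap_ticks_monolithic(perf_config(uf_gap = 1), 10, 3), 300)
  expect_equal(gap_ticks_monolithic(perf_config(uf_gap = 16), 1, 5), 5)
})

test_that("ring-interconnect throughput stays far below its bandwidth", {
  cfg <- perf_config(uf_gap = 16, d_gap = 90, f = 250e6)
  expect_equal(maxring_throughput(cfg, 3200), 5e6)
  expect_lt(maxring_throughput(cfg, 3200), cfg$bw_maxring / 100)
  # saturated regime: decreasing in the cell count
  ns <- c(2000, 4000, 8000)
  th <- vapply(ns, function(n) maxring_throughput(cfg, n), numeric(1))
  expect_true(all(diff(th) < 0))
  # saturated regime closed form: 4 f uf / N
  expect_equal(th, 4 * cfg$f * cfg$uf_gap / ns)
})

test_that("execution time picks the binding resource", {
  cfg <- perf_config(f = 170e6, bw_dram = 15e9)
  et <- exec_time(cfg, ticks = 1e6, bytes_per_tick = 0)
  expect_equal(et$t_exec, 1e6 / 170e6)
  expect_equal(et$bottleneck, "compute")
  expect_equal(exec_time(cfg, 0, 64)$t_exec, 0)
  # crossover: memory binds exactly when bytes_per_tick * f > bw
  for (bpt in c(4, 64, 88, 89, 512)) {
    et <- exec_time(cfg, 1e6, bpt)
    expect_equal(et$bottleneck,
                 if (bpt * cfg$f > cfg$bw_dram) "memory" else "compute")
  }
  # for the gap kernel the crossover bandwidth is 4 * uf * f exactly
  cfgg <- perf_config(uf_gap = 16, f = 2e8)
  bw_cross <- 4 * cfgg$uf_gap * cfgg$f
  for (mult in c(0.99, 1.01)) {
    ci <- cfgg; ci$bw_dram <- bw_cross * mult
    et <- exec_time(ci, 1e4, 4 * cfgg$uf_gap)
    expect_equal(et$bottleneck, if (mult < 1) "memory" else "compute")
  }
  # exec time never increases with bandwidth
  bws <- c(5e9, 15e9, 60e9)
  ts <- vapply(bws, function(bw) {
    ci <- cfg; ci$bw_dram <- bw
    exec_time(ci, 1e6, 100)$t_exec
  }, numeric(1))
  expect_true(all(diff(ts) <= 0))
})

test_that("performance sweeps tabulate the model over the grid", {
  sw <- perf_sweep(perf_config(), f_mhz = c(100, 200), uf_gap = c(16, 32),
                   n_cells_gap = 500)
  expect_equal(nrow(sw), 4L)
  expect_equal(sw$gap_dram_bytes_s, 4 * sw$uf_gap * sw$f_mhz * 1e6)
  expect_identical(sw$exceeds_dram, sw$gap_dram_bytes_s > 15e9)
})
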