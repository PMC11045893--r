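#' Hardware performance-model configuration
#'
#' Parameters of the analytical model of the dataflow implementation: unroll
#' factors, clock frequency, memory bandwidths, pipeline depth and data
#' sizes.  Defaults follow the accelerator platform the library emulates:
#' 15 GB/s on-board DRAM bandwidth per DIMM, 5 GB/s ring-interconnect
#' bandwidth, 4-byte (single-float) values.  The gap-kernel pipeline depth
#' `d_gap` and the cell-kernel inner-loop buffer `size_buffer` are exposed
#' placeholders (90 and 16): they depend on the synthesized design.
#'
#' @param uf_cell,uf_gap positive integer unroll factors of the cell and gap
#'   kernels.
#' @param f clock frequency in Hz.
#' @param bw_dram DRAM bandwidth in bytes/s (per DIMM).
#' @param bw_maxring ring-interconnect bandwidth in bytes/s.
#' @param d_gap gap-kernel accumulation pipeline depth in ticks.
#' @param size_buffer cell-kernel inner-loop buffer in ticks.
#' @param bytes_per_value size of one streamed value in bytes.
#' @param n_dfes,n_gapkernels_per_dfe device counts for the multi-device
#'   partitioned model.
#' @param mem_width,mem_depth,mem_ports hardware geometry of one on-chip
#'   memory block (bits, words, ports).
#' @return An object of class `perf_config`.
#' @export
perf_config <- function(uf_cell = 1L, uf_gap = 16L, f = 170e6,
                        bw_dram = 15e9, bw_maxring = 5e9, d_gap = 90L,
                        size_buffer = 16L, bytes_per_value = 4L,
                        n_dfes = 1L, n_gapkernels_per_dfe = 1L,
                        mem_width = 36L, mem_depth = 1024L, mem_ports = 1L) {
  for (nm in c("uf_cell", "uf_gap", "f", "bw_dram", "bw_maxring", "d_gap",
               "bytes_per_value", "n_dfes", "n_gapkernels_per_dfe",
               "mem_width", "mem_depth", "mem_ports")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !(val > 0))
      stop(sprintf("'%s' must be a single positive number", nm), call. = FALSE)
  }
  stopifnot(is.numeric(size_buffer), size_buffer >= 0)
  structure(
    list(uf_cell = as.integer(uf_cell), uf_gap = as.integer(uf_gap),
         f = as.numeric(f), bw_dram = as.numeric(bw_dram),
         bw_maxring = as.numeric(bw_maxring), d_gap = as.integer(d_gap),
         size_buffer = as.integer(size_buffer),
         bytes_per_value = as.integer(bytes_per_value),
         n_dfes = as.integer(n_dfes),
         n_gapkernels_per_dfe = as.integer(n_gapkernels_per_dfe),
         mem_width = as.integer(mem_width), mem_depth = as.integer(mem_depth),
         mem_ports = as.integer(mem_ports)),
    class = "perf_config")
}

#' @export
print.perf_config <- function(x, ...) {
  cat("<perf_config> uf_cell =", x$uf_cell, "uf_gap =", x$uf_gap,
      "f =", x$f / 1e6, "MHz\n  bw_dram =", x$bw_dram / 1e9,
      "GB/s  bw_maxring =", x$bw_maxring / 1e9, "GB/s  d_gap =", x$d_gap,
      " buffer =", x$size_buffer, "\n  devices:", x$n_dfes, "x",
      x$n_gapkernels_per_dfe, "gap kernel(s)\n")
  invisible(x)
}

#' Required DRAM throughput of the cell kernel
#'
#' Per-stream accounting of the cell kernel's DRAM traffic: a 100-byte
#' stream touched every tick times the unroll factor, a 44-byte stream
#' touched once per gate-loop pass, and a 4-byte stream touched once per
#' compartment pass:
#' `(96 + 4) uf f + (32 + 4 + 4 + 4) f / ceil(Ng/uf) + 4 f / (ceil(Ng/uf) Nc)`.
#'
#' @param cfg a [perf_config()].
#' @param n_comps_cell compartments per cell (`>= 1`).
#' @param n_gates_comp gates per compartment (`>= 1`).
#' @return Required throughput in bytes/s.
#' @export
hhmc_dram_throughput <- function(cfg, n_comps_cell, n_gates_comp) {
  stopifnot(inherits(cfg, "perf_config"), n_comps_cell >= 1, n_gates_comp >= 1)
  passes <- ceiling(n_gates_comp / cfg$uf_cell)
  (96 + 4) * cfg$uf_cell * cfg$f +
    (32 + 4 + 4 + 4) * cfg$f / passes +
    4 * cfg$f / (passes * n_comps_cell)
}

#' Required DRAM throughput of the gap kernel
#'
#' The gap kernel streams one 4-byte connectivity weight per unrolled lane
#' per tick: `4 * uf_gap * f` bytes/s.
#'
#' @param cfg a [perf_config()].
#' @return Required throughput in bytes/s.
#' @export
gap_dram_throughput <- function(cfg) {
  stopifnot(inherits(cfg, "perf_config"))
  4 * cfg$uf_gap * cfg$f
}

#' Smallest clock frequency exceeding the DRAM bandwidth
#'
#' The smallest integer frequency in MHz at which the gap kernel's required
#' DRAM throughput `4 * uf_gap * f` strictly exceeds `bw_dram`.
#'
#' @param cfg a [perf_config()].
#' @return Integer MHz.
#' @export
min_freq_exceeding_dram <- function(cfg) {
  stopifnot(inherits(cfg, "perf_config"))
  thresh <- cfg$bw_dram / (4 * cfg$uf_gap * 1e6)
  as.integer(floor(thresh) + 1)
}

#' On-chip memory blocks needed for a data store
#'
#' `ceil(w_req / w_hw) * ceil(d_req / d_hw) * ceil(p_req / p_hw)` over the
#' block geometry: width in bits, depth in words, read/write ports.
#'
#' @param w_req,d_req,p_req required width, depth and ports (`>= 1`).
#' @param cfg a [perf_config()] carrying the hardware geometry.
#' @return Integer block count.
#' @export
mem_blocks <- function(w_req, d_req, p_req, cfg = perf_config()) {
  stopifnot(w_req >= 1, d_req >= 1, p_req >= 1, inherits(cfg, "perf_config"))
  ceiling(w_req / cfg$mem_width) * ceiling(d_req / cfg$mem_depth) *
    ceiling(p_req / cfg$mem_ports)
}

#' Ticks per ring stage of the gap kernel
#'
#' `N * max(d_gap, ceil(N / uf_gap))` for `N` cells held by the kernel: each
#' cell's accumulation occupies the pipeline for the larger of the pipeline
#' depth and the number of unrolled iterations.  Depth-bound (`d_gap`
#' dominates) gives ticks linear in `N`; a saturated pipeline gives
#' `N^2 / uf_gap`.
#'
#' @param cfg a [perf_config()].
#' @param n_cells_gap cells per gap kernel (`>= 1`).
#' @return Ticks per stage.
#' @export
stage_ticks <- function(cfg, n_cells_gap) {
  stopifnot(inherits(cfg, "perf_config"), n_cells_gap >= 1)
  n_iter <- ceiling(n_cells_gap / cfg$uf_gap)
  n_cells_gap * pmax(cfg$d_gap, n_iter)
}

#' Required ring-interconnect throughput
#'
#' One block of voltages (`bytes_per_value * N` bytes) is transferred per
#' ring stage: `bytes * N * f / stage_ticks`.
#'
#' @inheritParams stage_ticks
#' @return Bytes/s.
#' @export
maxring_throughput <- function(cfg, n_cells_gap) {
  stopifnot(inherits(cfg, "perf_config"))
  (cfg$bytes_per_value * n_cells_gap) * cfg$f / stage_ticks(cfg, n_cells_gap)
}

#' Total ticks of the partitioned gap computation
#'
#' With `K = n_dfes * n_gapkernels_per_dfe` gap kernels, each time step runs
#' `K` ring stages of `stage_ticks` each over blocks of `N / K` cells
#' (padded up per the partition rule when `K` does not divide `N`):
#' `N_steps * K * stage_ticks(N_padded / K)`.  Linear in `N` while
#' depth-bound, quadratic once the pipelines saturate.
#'
#' @param cfg a [perf_config()].
#' @param n_cells_total total cells in the network.
#' @param n_steps simulation steps.
#' @return Total ticks.
#' @export
hhmcg_ticks <- function(cfg, n_cells_total, n_steps = 1) {
  stopifnot(inherits(cfg, "perf_config"), n_cells_total >= 1, n_steps >= 0)
  K <- cfg$n_dfes * cfg$n_gapkernels_per_dfe
  block <- ceiling(n_cells_total / K)
  n_steps * K * stage_ticks(cfg, block)
}

#' Ticks of the cell kernel
#'
#' `N_steps * sum_i ceil(N_gates[i] / uf_cell) + size_buffer`, over all
#' compartments of the network; the inner-loop buffer is charged once.
#'
#' @param cfg a [perf_config()].
#' @param gates_per_comp integer vector: gates of each compartment.
#' @param n_steps simulation steps.
#' @return Total ticks.
#' @export
cell_ticks <- function(cfg, gates_per_comp, n_steps = 1) {
  stopifnot(inherits(cfg, "perf_config"), length(gates_per_comp) >= 1)
  n_steps * sum(ceiling(gates_per_comp / cfg$uf_cell)) + cfg$size_buffer
}

#' Ticks of a monolithic (single-kernel) gap computation
#'
#' `N_steps * N * ceil(N / uf_gap)`; equals `N_steps * N^2 / uf_gap` when
#' the unroll factor divides the cell count.
#'
#' @param cfg a [perf_config()].
#' @param n_cells cells in the network.
#' @param n_steps simulation steps.
#' @return Total ticks.
#' @export
gap_ticks_monolithic <- function(cfg, n_cells, n_steps = 1) {
  stopifnot(inherits(cfg, "perf_config"), n_cells >= 1)
  n_steps * n_cells * ceiling(n_cells / cfg$uf_gap)
}

#' Predicted execution time and bottleneck
#'
#' `T_comp = ticks / f`; `T_DRAM = bytes_per_tick * ticks / bw_dram`; the
#' execution time is the larger of the two and the bottleneck label names
#' it.  The ring interconnect is omitted: its required throughput sits
#' orders of magnitude below its bandwidth (see [maxring_throughput()]).
#'
#' @param cfg a [perf_config()].
#' @param ticks total ticks (`>= 0`).
#' @param bytes_per_tick DRAM bytes moved per tick.
#' @return List with `t_exec` (seconds), `t_comp`, `t_dram`, and
#'   `bottleneck` (`"compute"` or `"memory"`).
#' @export
exec_time <- function(cfg, ticks, bytes_per_tick) {
  stopifnot(inherits(cfg, "perf_config"), ticks >= 0, bytes_per_tick >= 0)
  t_comp <- ticks / cfg$f
  t_dram <- bytes_per_tick * ticks / cfg$bw_dram
  list(t_exec = max(t_comp, t_dram), t_comp = t_comp, t_dram = t_dram,
       bottleneck = if (t_dram > t_comp) "memory" else "compute")
}

#' Tabular performance sweeps
#'
#' Evaluates the throughput and timing model over a grid of frequencies and
#' unroll factors, as a plain data frame ready for delimited-text export —
#' the data behind the roofline-style throughput plots.
#'
#' @param cfg a [perf_config()] providing fixed parameters.
#' @param f_mhz numeric vector of frequencies to sweep (MHz).
#' @param uf_gap integer vector of gap unroll factors to sweep.
#' @param n_cells_gap cells per gap kernel used for the ring columns.
#' @return A data frame with one row per (f, uf) combination.
#' @export
perf_sweep <- function(cfg = perf_config(), f_mhz = seq(50, 300, by = 10),
                       uf_gap = c(1, 2, 4, 8, 16, 32), n_cells_gap = 1000) {
  grid <- expand.grid(f_mhz = f_mhz, uf_gap = uf_gap)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ci <- cfg
    ci$f <- grid$f_mhz[i] * 1e6
    ci$uf_gap <- as.integer(grid$uf_gap[i])
    data.frame(
      f_mhz = grid$f_mhz[i], uf_gap = ci$uf_gap,
      gap_dram_bytes_s = gap_dram_throughput(ci),
      exceeds_dram = gap_dram_throughput(ci) > ci$bw_dram,
      stage_ticks = stage_ticks(ci, n_cells_gap),
      maxring_bytes_s = maxring_throughput(ci, n_cells_gap))
  })
  do.call(rbind, rows)
}
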