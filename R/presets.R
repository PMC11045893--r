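#' Original squid-axon Hodgkin-Huxley preset
#'
#' A single cell with a single compartment carrying the classic potassium
#' (gate `n`, exponent 4), sodium (gates `m` exponent 3 and `h` exponent 1)
#' and leak conductances, with every transition rate expressed as a
#' generalized [rate_function()] record:
#'
#' * `alpha_n = 0.01 (V + 10) / (exp((V + 10)/10) - 1)` — branch 0
#' * `beta_n = 0.125 exp(V / 80)` — branch 1
#' * `alpha_m = 0.1 (V + 25) / (exp((V + 25)/10) - 1)` — branch 0
#' * `beta_m = 4 exp(V / 18)` — branch 1
#' * `alpha_h = 0.07 exp(V / 20)` — branch 1
#' * `beta_h = 1 / (exp((V + 30)/10) + 1)` — branch 2
#'
#' Units and signs follow the 1952 source: voltages are displacements from
#' rest in mV with depolarization negative (`V_Na = -115`, `V_K = +12`,
#' `V_leak = -10.613`), conductances in mS/cm^2 (`g_Na = 120`, `g_K = 36`,
#' `g_leak = 0.3`), `C = 1` uF/cm^2, time in ms.  Rest is at `V = 0`.
#'
#' @return A [network_model()] with one single-compartment cell and no gap
#'   junctions.
#' @export
build_original_hh <- function() {
  n_gate <- gate_spec("alpha_beta",
                      rate1 = rate_function(0, k0 = -0.01, k1 = -10, k2 = -0.1),
                      rate2 = rate_function(1, k0 = 0.125, k1 = 0, k2 = -1 / 80),
                      exponent = 4L, name = "n")
  m_gate <- gate_spec("alpha_beta",
                      rate1 = rate_function(0, k0 = -0.1, k1 = -25, k2 = -0.1),
                      rate2 = rate_function(1, k0 = 4, k1 = 0, k2 = -1 / 18),
                      exponent = 3L, name = "m")
  h_gate <- gate_spec("alpha_beta",
                      rate1 = rate_function(1, k0 = 0.07, k1 = 0, k2 = -1 / 20),
                      rate2 = rate_function(2, k0 = 1, k1 = -30, k2 = -0.1),
                      exponent = 1L, name = "h")
  comp <- compartment_spec(
    capacitance = 1, g_leak = 0.3, v_leak = -10.613,
    channels = list(
      channel_spec(36, 12, list(n_gate), name = "K"),
      channel_spec(120, -115, list(m_gate, h_gate), name = "Na")),
    name = "soma")
  network_model(cell_spec(list(comp), g_int = 0, name = "hh"))
}

# --- inferior olive preset ------------------------------------------------
#
# Three-compartment (dendrite / soma / axon) cell transcribed from the
# published De Gruijl / Schweighofer olivary model.  Units: mV, ms,
# mS/cm^2, uA/cm^2; C = 1 uF/cm^2 per compartment.  All rate curves are
# expressed in the affine-wrapped generalized family; three curves whose
# published forms fall outside that family (tau_q, tau_l, and the
# calcium-dependent activation rate of the KCa gate) are represented by
# closest-fit members, see the methods vignette.

.io_sigmoid <- function(k0, k1, k2, a = 1, b = 0) rate_function(2, k0, k1, k2, a, b)
.io_const <- function(value) rate_function(1, k0 = value, k1 = 0, k2 = 0)

.io_dendrite <- function() {
  # high-threshold calcium: I = 4.5 r^2 (V - 120), alpha/beta scaled by 1/5
  r_gate <- gate_spec("alpha_beta",
    rate1 = .io_sigmoid(1.7, 5, 1 / 13.9, a = 0.2),
    rate2 = rate_function(0, k0 = -0.02, k1 = -8.5, k2 = -0.2, a = 0.2),
    exponent = 2L, name = "r")
  # calcium-gated potassium: alpha_s saturates in the calcium concentration
  s_gate <- gate_spec("alpha_beta",
    rate1 = rate_function(1, k0 = 1, k1 = 0, k2 = 0.002, a = -0.01, b = 0.01),
    rate2 = .io_const(0.015),
    exponent = 1L, driver = "aux", driver_index = 1L, name = "s")
  # hyperpolarization-activated cation current
  q_gate <- gate_spec("inf_tau",
    rate1 = .io_sigmoid(1, -80, -1 / 4),
    rate2 = .io_sigmoid(1005.8407, -64.28296, -0.13366719, b = 66.58334),
    exponent = 1L, name = "q")
  compartment_spec(
    capacitance = 1, g_leak = 0.016, v_leak = 10,
    channels = list(
      channel_spec(4.5, 120, list(r_gate), name = "CaH"),
      channel_spec(35, -75, list(s_gate), name = "KCa"),
      channel_spec(0.125, -43, list(q_gate), name = "h")),
    has_gap = TRUE,
    aux_states = list(aux_state_spec(1L, c_current = -3.0, c_self = -0.075,
                                     name = "Ca")),
    name = "dendrite")
}

.io_soma <- function() {
  k_gate <- gate_spec("inf_tau",                       # low-threshold Ca act.
    rate1 = .io_sigmoid(1, -61, 1 / 4.2),
    rate2 = .io_const(1),
    exponent = 3L, name = "k")
  l_gate <- gate_spec("inf_tau",                       # low-threshold Ca inact.
    rate1 = .io_sigmoid(1, -85.5, -1 / 8.5),
    rate2 = .io_sigmoid(145.27728, -74.22811, -0.1573992, b = 38.32392),
    exponent = 1L, name = "l")
  m_gate <- gate_spec("inf_tau",                       # Na activation
    rate1 = .io_sigmoid(1, -30, 1 / 5.5),
    rate2 = .io_const(0.05),                           # quasi-instantaneous
    exponent = 3L, name = "m")
  h_gate <- gate_spec("inf_tau",                       # Na inactivation
    rate1 = .io_sigmoid(1, -70, -1 / 5.8),
    rate2 = rate_function(1, k0 = 3, k1 = -40, k2 = 1 / 33),
    exponent = 1L, name = "h")
  n_gate <- gate_spec("inf_tau",                       # delayed rectifier
    rate1 = .io_sigmoid(1, -3, 1 / 10),
    rate2 = rate_function(1, k0 = 47, k1 = -50, k2 = -1 / 900, b = 5),
    exponent = 4L, name = "n")
  xs_gate <- gate_spec("alpha_beta",                   # fast potassium
    rate1 = rate_function(0, k0 = 0.13, k1 = -25, k2 = 0.1),
    rate2 = rate_function(1, k0 = 1.69, k1 = -35, k2 = 0.0125),
    exponent = 4L, name = "x_s")
  compartment_spec(
    capacitance = 1, g_leak = 0.016, v_leak = 10,
    channels = list(
      channel_spec(0.68, 120, list(k_gate, l_gate), name = "CaL"),
      channel_spec(150, 55, list(m_gate, h_gate), name = "Na_s"),
      channel_spec(9.0, -75, list(n_gate), name = "Kdr"),
      channel_spec(5, -75, list(xs_gate), name = "K_s")),
    p_up = 0.25,                                       # soma : dendrite
    name = "soma")
}

.io_axon <- function() {
  ma_gate <- gate_spec("inf_tau",
    rate1 = .io_sigmoid(1, -30, 1 / 5.5),
    rate2 = .io_const(0.05),
    exponent = 3L, name = "m_a")
  ha_gate <- gate_spec("inf_tau",
    rate1 = .io_sigmoid(1, -60, -1 / 5.8),
    rate2 = rate_function(1, k0 = 1.5, k1 = -40, k2 = 1 / 33),
    exponent = 1L, name = "h_a")
  xa_gate <- gate_spec("alpha_beta",
    rate1 = rate_function(0, k0 = 0.13, k1 = -25, k2 = 0.1),
    rate2 = rate_function(1, k0 = 1.69, k1 = -35, k2 = 0.0125),
    exponent = 4L, name = "x_a")
  compartment_spec(
    capacitance = 1, g_leak = 0.016, v_leak = 10,
    channels = list(
      channel_spec(240, 55, list(ma_gate, ha_gate), name = "Na_a"),
      channel_spec(20, -75, list(xa_gate), name = "K_a")),
    p_up = 0.15,                                       # axon : soma
    name = "axon")
}

#' Three-compartment inferior-olive cell preset
#'
#' One olivary cell with dendrite, soma and axon compartments chained by an
#' internal conductance `g_int = 0.13` (surface ratios 0.25 soma:dendrite,
#' 0.15 axon:soma).  The dendrite carries the high-threshold calcium,
#' calcium-gated potassium and h currents plus the calcium concentration as
#' an auxiliary state, and terminates the gap junctions; the soma carries
#' the low-threshold calcium, sodium, delayed-rectifier and fast potassium
#' currents; the axon carries sodium and potassium.  Thirteen gate variables
#' per cell in total (4 / 6 / 3 per compartment, counting the calcium
#' state).
#'
#' @return A [cell_spec()].
#' @export
build_io_cell <- function() {
  cell_spec(list(.io_dendrite(), .io_soma(), .io_axon()),
            g_int = 0.13, name = "io")
}

#' Inferior-olive network preset
#'
#' `n_cells` identical three-compartment olivary cells with all-to-all
#' dendro-dendritic gap junctions whose conductance depends on the voltage
#' difference as `0.8 exp(-0.01 Vij^2) + 0.2` (times the weight).  Weights
#' come from an explicit matrix or a [weight_source()] recipe; generated
#' weights in `[0, 1]` are scaled by the gap conductance `g_gap`.
#'
#' @param n_cells number of cells (`>= 1`).
#' @param weights an explicit `n_cells` x `n_cells` matrix of effective
#'   weights, a [weight_source()], or `NULL` for an uncoupled network.
#' @param g_gap global gap-junction conductance applied to generated
#'   weights (default 0.04 mS/cm^2); ignored for explicit matrices.
#' @return A [network_model()].
#' @export
build_io_network <- function(n_cells, weights = NULL, g_gap = 0.04) {
  stopifnot(is.numeric(n_cells), length(n_cells) == 1L)
  if (n_cells < 1) stop("'n_cells' must be >= 1", call. = FALSE)
  if (inherits(weights, "weight_source")) weights$scale <- g_gap
  cells <- replicate(as.integer(n_cells), build_io_cell(), simplify = FALSE)
  network_model(cells, c0 = 0.8, c1 = -0.01, c2 = 0.2, weights = weights)
}
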