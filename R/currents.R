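#' Per-term current and derivative evaluators
#'
#' These small pure functions implement each term of the membrane equation
#' `C dV/dt = I_app - I_channels - I_leak - I_mc - I_gap` and the gate and
#' auxiliary-state dynamics.  The simulator assembles them over a compiled
#' model layout; they are exported so every term can be exercised and checked
#' in isolation.
#'
#' @name currents
NULL

#' Product of gate activation variables
#'
#' Returns `prod(y_k ^ p_k)` for a channel's gates; the empty product is 1.
#'
#' @param values numeric vector of gate activations.
#' @param exponents non-negative integer exponents, same length as `values`.
#' @return A single number.
#' @export
gate_product <- function(values, exponents) {
  if (length(values) == 0L) return(1)
  stopifnot(length(values) == length(exponents),
            all(is.finite(values)),
            all(exponents >= 0), all(exponents == round(exponents)))
  prod(values ^ exponents)
}

#' Channel current
#'
#' `I = g * (V - V_rev) * yProd` where `yProd` is the channel's
#' [gate_product()].
#'
#' @param channel a [channel_spec()].
#' @param v membrane voltage of the channel's compartment.
#' @param y_prod the gate-activation product (`>= 0`).
#' @return Current (positive = outward under the model's sign convention).
#' @export
channel_current <- function(channel, v, y_prod = 1) {
  stopifnot(inherits(channel, "channel_spec"), y_prod >= 0)
  channel$conductance * (v - channel$reversal) * y_prod
}

#' Leak current
#'
#' The standard ohmic leak `g_leak * (V - v_leak)` with per-compartment
#' constants.
#'
#' @param compartment a [compartment_spec()].
#' @param v membrane voltage.
#' @return Leak current.
#' @export
leak_current <- function(compartment, v) {
  stopifnot(inherits(compartment, "compartment_spec"))
  compartment$g_leak * (v - compartment$v_leak)
}

#' Inter-compartment current
#'
#' Current leaving compartment `i` of a serially chained cell:
#' `g_int * sum_j (V_i - V_j) / p_ij` over the (at most two) chain neighbours
#' `j`.  For the link between chain positions `u` and `u + 1` with surface
#' ratio `p = p_up[u + 1]`, the later compartment sees divisor `p` and the
#' earlier one `1 - p`, so a symmetric (`p = 0.5`) chain conserves current
#' exactly.
#'
#' @param cell a [cell_spec()].
#' @param i compartment index in the chain (1-based).
#' @param v numeric vector of all compartment voltages of the cell.
#' @return Inter-compartment current for compartment `i`.
#' @export
mc_current <- function(cell, i, v) {
  stopifnot(inherits(cell, "cell_spec"))
  ncomp <- length(cell$compartments)
  if (length(v) != ncomp) stop("'v' must have one voltage per compartment",
                               call. = FALSE)
  if (i < 1 || i > ncomp) stop("compartment index out of range", call. = FALSE)
  out <- 0
  if (i > 1) {                         # link to the previous compartment
    p <- cell$compartments[[i]]$p_up
    out <- out + (v[i] - v[i - 1]) / p
  }
  if (i < ncomp) {                     # link to the next compartment
    p <- cell$compartments[[i + 1]]$p_up
    out <- out + (v[i] - v[i + 1]) / (1 - p)
  }
  cell$g_int * out
}

#' Dense gap-junction currents
#'
#' The all-to-all reference evaluation of the gap-junction current into every
#' cell: `I[i] = sum_j w[i, j] * (c0 * exp(c1 * Vij^2) + c2) * Vij` with
#' `Vij = V[i] - V[j]`, summed over `j` in ascending order.  This is the
#' oracle the ring-partitioned computation ([compute_gap_partitioned()]) is
#' checked against.
#'
#' @param model a [network_model()] with realized (matrix) weights, or a
#'   plain weight matrix.
#' @param v_gap numeric vector of gap-compartment voltages, one per cell.
#' @param c0,c1,c2 gap constants; taken from `model` when it is a
#'   `network_model`.
#' @return Numeric vector of per-cell gap currents.
#' @export
gap_current_dense <- function(model, v_gap, c0 = NULL, c1 = NULL, c2 = NULL) {
  if (inherits(model, "network_model")) {
    w <- realized_weights(model)
    c0 <- model$c0; c1 <- model$c1; c2 <- model$c2
  } else {
    w <- as.matrix(model)
    stopifnot(!is.null(c0), !is.null(c1), !is.null(c2))
  }
  n <- length(v_gap)
  if (nrow(w) != n || ncol(w) != n)
    stop("weight matrix shape does not match the number of voltages",
         call. = FALSE)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      vij <- v_gap[i] - v_gap[j]
      acc <- acc + w[i, j] * (c0 * exp(c1 * vij * vij) + c2) * vij
    }
    out[i] <- acc
  }
  out
}

#' Gate derivative
#'
#' `dy/dt` under the gate's formulation: `(1 - y) * alpha - y * beta` for
#' `alpha_beta`, `(inf - y) / tau` for `inf_tau`.
#'
#' @param gate a [gate_spec()].
#' @param y current activation value.
#' @param v driver value (voltage or auxiliary state).
#' @return Rate of change of the gate.
#' @export
gate_derivative <- function(gate, y, v) {
  stopifnot(inherits(gate, "gate_spec"))
  r1 <- eval_rate(gate$rate1, v)
  r2 <- eval_rate(gate$rate2, v)
  if (gate$formulation == "alpha_beta") {
    (1 - y) * r1 - y * r2
  } else {
    if (any(r2 <= 0))
      stop("inf_tau gate has non-positive time constant at driver value ", v,
           call. = FALSE)
    (r1 - y) / r2
  }
}

#' Auxiliary-state derivative
#'
#' `ds/dt = c_current * I + c_self * s` for a calcium-like state fed by one
#' channel current.
#'
#' @param aux an [aux_state_spec()].
#' @param s current state value.
#' @param current the referenced channel's current.
#' @return Rate of change of the auxiliary state.
#' @export
aux_derivative <- function(aux, s, current) {
  stopifnot(inherits(aux, "aux_state_spec"))
  aux$c_current * current + aux$c_self * s
}

#' Membrane-voltage derivative
#'
#' `dV/dt = (I_app - I_channels - I_leak - I_mc - I_gap) / C`.  The
#' inter-compartment and gap terms default to zero for single-compartment
#' cells and cells without gap junctions.
#'
#' @param compartment a [compartment_spec()].
#' @param i_app applied stimulus current.
#' @param i_channels,i_leak,i_mc,i_gap current terms (defaults 0).
#' @return Rate of change of the membrane voltage.
#' @export
membrane_derivative <- function(compartment, i_app = 0, i_channels = 0,
                                i_leak = 0, i_mc = 0, i_gap = 0) {
  stopifnot(inherits(compartment, "compartment_spec"))
  (i_app - i_channels - i_leak - i_mc - i_gap) / compartment$capacitance
}
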