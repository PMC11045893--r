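#' Gate specification
#'
#' A gate is one activation variable `y` in `[0, 1]` of an ion channel.  Its
#' dynamics follow either the transition-rate form
#' `dy/dt = (1 - y) * alpha - y * beta` (`formulation = "alpha_beta"`, with
#' `rate1` = alpha and `rate2` = beta) or the relaxation form
#' `dy/dt = (inf - y) / tau` (`formulation = "inf_tau"`, with `rate1` = inf
#' and `rate2` = tau).  The channel conductance is scaled by `y^exponent`.
#'
#' The driving variable defaults to the membrane voltage of the gate's own
#' compartment; setting `driver = "aux"` makes the gate respond to an
#' auxiliary (calcium-like) state of the compartment instead, selected by
#' `driver_index` among the compartment's auxiliary states.
#'
#' @param formulation `"alpha_beta"` or `"inf_tau"`.
#' @param rate1,rate2 [rate_function()] records: alpha/beta, or inf/tau.
#' @param exponent non-negative integer power of the gate in the channel's
#'   open-fraction product.
#' @param driver `"voltage"` (default) or `"aux"`.
#' @param driver_index index of the auxiliary state within the compartment
#'   when `driver = "aux"`.
#' @param name optional label used in trace headers and error messages.
#' @return An object of class `gate_spec`.
#' @export
gate_spec <- function(formulation = c("alpha_beta", "inf_tau"), rate1, rate2,
                      exponent = 1L, driver = c("voltage", "aux"),
                      driver_index = 1L, name = NULL) {
  formulation <- match.arg(formulation)
  driver <- match.arg(driver)
  stopifnot(inherits(rate1, "rate_function"), inherits(rate2, "rate_function"))
  if (length(exponent) != 1L || exponent < 0 || exponent != round(exponent))
    stop("'exponent' must be a single non-negative integer", call. = FALSE)
  structure(
    list(formulation = formulation, rate1 = rate1, rate2 = rate2,
         exponent = as.integer(exponent), driver = driver,
         driver_index = as.integer(driver_index),
         name = if (is.null(name)) NA_character_ else as.character(name)),
    class = "gate_spec")
}

#' Channel specification
#'
#' An ionic membrane current `I = g * (V - V_rev) * prod(y_k ^ p_k)` over the
#' channel's gates.  A channel with no gates is purely ohmic.
#'
#' @param conductance maximal conductance `g >= 0`.
#' @param reversal reversal potential `V_rev`.
#' @param gates list of [gate_spec()] records (possibly empty).
#' @param name optional label.
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(conductance, reversal, gates = list(), name = NULL) {
  if (!is.numeric(conductance) || length(conductance) != 1L || conductance < 0)
    stop("'conductance' must be a single number >= 0", call. = FALSE)
  if (!is.numeric(reversal) || length(reversal) != 1L || !is.finite(reversal))
    stop("'reversal' must be a single finite number", call. = FALSE)
  if (inherits(gates, "gate_spec")) gates <- list(gates)
  if (!all(vapply(gates, inherits, logical(1), "gate_spec")))
    stop("'gates' must be a list of gate_spec objects", call. = FALSE)
  structure(
    list(conductance = as.numeric(conductance), reversal = as.numeric(reversal),
         gates = gates,
         name = if (is.null(name)) NA_character_ else as.character(name)),
    class = "channel_spec")
}

#' Auxiliary (calcium-like) state specification
#'
#' A first-order linear state `s` driven by one channel current of the same
#' compartment: `ds/dt = c_current * I_channel + c_self * s`.  The inferior
#' olive preset uses it for the dendritic calcium concentration that drives
#' the calcium-gated potassium channel.
#'
#' @param channel index of the source channel within the compartment.
#' @param c_current coefficient multiplying the source-channel current.
#' @param c_self self-relaxation coefficient (negative for decay).
#' @param name optional label.
#' @return An object of class `aux_state_spec`.
#' @export
aux_state_spec <- function(channel, c_current, c_self, name = NULL) {
  stopifnot(is.numeric(channel), length(channel) == 1L, channel >= 1,
            is.numeric(c_current), length(c_current) == 1L, is.finite(c_current),
            is.numeric(c_self), length(c_self) == 1L, is.finite(c_self))
  structure(
    list(channel = as.integer(channel), c_current = as.numeric(c_current),
         c_self = as.numeric(c_self),
         name = if (is.null(name)) NA_character_ else as.character(name)),
    class = "aux_state_spec")
}

#' Compartment specification
#'
#' One electrically lumped section of a cell.  Compartments are connected in
#' a serial chain (no branching); `p_up` is the surface ratio of this
#' compartment relative to the previous one in the chain and controls how the
#' inter-compartment current divides between the two sides of the link (see
#' [mc_current()]).  `p_up` of the first compartment is ignored.
#'
#' @param capacitance membrane capacitance `C > 0`.
#' @param g_leak leak conductance `>= 0`.
#' @param v_leak leak reversal potential.
#' @param channels list of [channel_spec()] records.
#' @param p_up surface ratio to the previous compartment (`> 0`, `< 1`).
#' @param has_gap does this compartment terminate gap junctions?
#' @param aux_states list of [aux_state_spec()] records.
#' @param name optional label.
#' @return An object of class `compartment_spec`.
#' @export
compartment_spec <- function(capacitance = 1, g_leak = 0, v_leak = 0,
                             channels = list(), p_up = 0.5, has_gap = FALSE,
                             aux_states = list(), name = NULL) {
  stopifnot(is.numeric(capacitance), length(capacitance) == 1L, capacitance > 0,
            is.numeric(g_leak), length(g_leak) == 1L, g_leak >= 0,
            is.numeric(v_leak), length(v_leak) == 1L, is.finite(v_leak),
            is.numeric(p_up), length(p_up) == 1L, p_up > 0, p_up < 1,
            is.logical(has_gap), length(has_gap) == 1L)
  if (inherits(channels, "channel_spec")) channels <- list(channels)
  if (!all(vapply(channels, inherits, logical(1), "channel_spec")))
    stop("'channels' must be a list of channel_spec objects", call. = FALSE)
  if (inherits(aux_states, "aux_state_spec")) aux_states <- list(aux_states)
  if (!all(vapply(aux_states, inherits, logical(1), "aux_state_spec")))
    stop("'aux_states' must be a list of aux_state_spec objects", call. = FALSE)
  for (a in aux_states)
    if (a$channel > length(channels))
      stop("aux state references channel ", a$channel,
           " but the compartment has only ", length(channels), call. = FALSE)
  structure(
    list(capacitance = as.numeric(capacitance), g_leak = as.numeric(g_leak),
         v_leak = as.numeric(v_leak), channels = channels,
         p_up = as.numeric(p_up), has_gap = isTRUE(has_gap),
         aux_states = aux_states,
         name = if (is.null(name)) NA_character_ else as.character(name)),
    class = "compartment_spec")
}

#' Cell specification
#'
#' An ordered serial chain of compartments sharing one internal conductance
#' `g_int`.  At most one compartment may terminate gap junctions.
#'
#' @param compartments list of [compartment_spec()] records (at least one).
#' @param g_int internal (inter-compartment) conductance `>= 0`.
#' @param name optional label.
#' @return An object of class `cell_spec`.
#' @export
cell_spec <- function(compartments, g_int = 0, name = NULL) {
  if (inherits(compartments, "compartment_spec")) compartments <- list(compartments)
  if (length(compartments) < 1L ||
      !all(vapply(compartments, inherits, logical(1), "compartment_spec")))
    stop("'compartments' must be a non-empty list of compartment_spec objects",
         call. = FALSE)
  stopifnot(is.numeric(g_int), length(g_int) == 1L, g_int >= 0)
  if (sum(vapply(compartments, `[[`, logical(1), "has_gap")) > 1L)
    stop("at most one compartment per cell may have has_gap = TRUE", call. = FALSE)
  structure(
    list(compartments = compartments, g_int = as.numeric(g_int),
         name = if (is.null(name)) NA_character_ else as.character(name)),
    class = "cell_spec")
}

#' Network model
#'
#' A heterogeneous collection of cells coupled through gap junctions on their
#' gap compartments.  The junction current into cell `i` is
#' `I_gap[i] = sum_j w[i, j] * (c0 * exp(c1 * Vij^2) + c2) * Vij` with
#' `Vij = V[i] - V[j]` taken between gap-compartment voltages; diagonal
#' weights are ignored (forced to zero).
#'
#' The weight source is either an explicit square matrix or a generator
#' specification from [weight_source()], realized lazily with
#' [generate_weights()] when the model is compiled.
#'
#' @param cells list of [cell_spec()] records.
#' @param c0,c1,c2 gap-junction conductance constants.
#' @param weights square numeric matrix (side = number of cells), a
#'   [weight_source()] generator specification, or `NULL` for an uncoupled
#'   network (all-zero weights).
#' @return An object of class `network_model`.
#' @export
network_model <- function(cells, c0 = 0, c1 = 0, c2 = 0, weights = NULL) {
  if (inherits(cells, "cell_spec")) cells <- list(cells)
  if (length(cells) < 1L || !all(vapply(cells, inherits, logical(1), "cell_spec")))
    stop("'cells' must be a non-empty list of cell_spec objects", call. = FALSE)
  for (nm in c("c0", "c1", "c2")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
  }
  n <- length(cells)
  if (!is.null(weights) && !inherits(weights, "weight_source")) {
    weights <- as.matrix(weights)
    if (nrow(weights) != n || ncol(weights) != n)
      stop("weight matrix must be ", n, " x ", n, " (one row/column per cell)",
           call. = FALSE)
    if (any(!is.finite(weights)))
      stop("all weights must be finite", call. = FALSE)
    diag(weights) <- 0
    dimnames(weights) <- NULL
  }
  structure(
    list(cells = cells, c0 = as.numeric(c0), c1 = as.numeric(c1),
         c2 = as.numeric(c2), weights = weights),
    class = "network_model")
}

#' Number of cells, compartments and gate variables of a model
#'
#' `n_gate_vars()` counts gate variables in the hardware sense: gating states
#' plus auxiliary (calcium-like) states, since both occupy one slot of the
#' per-gate state pipeline.  `gates_per_compartment()` returns that count per
#' compartment of one cell.
#'
#' @param model a [network_model()] (or a [cell_spec()] for the per-cell
#'   helpers).
#' @return Integer counts.
#' @export
n_cells <- function(model) {
  stopifnot(inherits(model, "network_model"))
  length(model$cells)
}

#' @rdname n_cells
#' @export
n_compartments <- function(model) {
  stopifnot(inherits(model, "network_model"))
  sum(vapply(model$cells, function(cl) length(cl$compartments), integer(1)))
}

#' @rdname n_cells
#' @param cell a [cell_spec()].
#' @export
gates_per_compartment <- function(cell) {
  stopifnot(inherits(cell, "cell_spec"))
  vapply(cell$compartments, function(cp) {
    sum(vapply(cp$channels, function(ch) length(ch$gates), integer(1))) +
      length(cp$aux_states)
  }, integer(1))
}

#' @rdname n_cells
#' @export
n_gate_vars <- function(model) {
  if (inherits(model, "cell_spec")) return(sum(gates_per_compartment(model)))
  stopifnot(inherits(model, "network_model"))
  sum(vapply(model$cells, function(cl) sum(gates_per_compartment(cl)), integer(1)))
}

#' @export
print.network_model <- function(x, ...) {
  nc <- n_cells(x)
  cat("<network_model>", nc, "cell(s),", n_compartments(x), "compartment(s),",
      n_gate_vars(x), "gate variable(s)\n")
  gap <- vapply(x$cells, function(cl)
    any(vapply(cl$compartments, `[[`, logical(1), "has_gap")), logical(1))
  if (any(gap)) {
    cat("  gap junctions: c0 =", x$c0, "c1 =", x$c1, "c2 =", x$c2, "\n")
    if (is.null(x$weights)) cat("  weights: none (uncoupled)\n")
    else if (inherits(x$weights, "weight_source"))
      cat("  weights: generated (", x$weights$dist, ", key ",
          format(x$weights$key), ")\n", sep = "")
    else cat("  weights: explicit", nc, "x", nc, "matrix\n")
  }
  invisible(x)
}

#' @export
summary.network_model <- function(object, ...) {
  print(object)
  for (i in seq_along(object$cells)) {
    cl <- object$cells[[i]]
    cat("cell", i, if (!is.na(cl$name)) paste0("(", cl$name, ")") else "",
        ": g_int =", cl$g_int, "\n")
    for (j in seq_along(cl$compartments)) {
      cp <- cl$compartments[[j]]
      cat(sprintf("  comp %d%s: C=%g g_leak=%g v_leak=%g channels=%d gates=%d aux=%d%s\n",
                  j, if (!is.na(cp$name)) paste0(" (", cp$name, ")") else "",
                  cp$capacitance, cp$g_leak, cp$v_leak, length(cp$channels),
                  sum(vapply(cp$channels, function(ch) length(ch$gates), integer(1))),
                  length(cp$aux_states), if (cp$has_gap) " [gap]" else ""))
    }
  }
  invisible(object)
}
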