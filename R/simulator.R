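# Internal compiled-model layout: the nested spec objects are flattened into
# parallel arrays once per run so each Euler step is a handful of vectorized
# operations.  Gate -> channel product accumulation is rank-partitioned
# (first gate of each channel, second gate, ...) so repeated-index updates
# stay vectorized.
compile_model <- function(model) {
  stopifnot(inherits(model, "network_model"))
  comp <- list(C = numeric(0), g_leak = numeric(0), v_leak = numeric(0),
               cell = integer(0), label = character(0))
  link <- list(lo = integer(0), hi = integer(0), p = numeric(0), g = numeric(0))
  chan <- list(g = numeric(0), rev = numeric(0), comp = integer(0),
               label = character(0))
  gate <- list(form = integer(0), exponent = numeric(0), channel = integer(0),
               comp = integer(0), drv_type = integer(0), drv_idx = integer(0),
               rank = integer(0), label = character(0))
  for (p in c("ft", "k0", "k1", "k2", "a", "b"))
    for (r in 1:2) gate[[paste0(p, r)]] <- numeric(0)
  aux <- list(comp = integer(0), channel = integer(0), cI = numeric(0),
              cS = numeric(0), label = character(0))
  gap_comp <- integer(0)                 # global gap-compartment index per cell

  for (ci in seq_along(model$cells)) {
    cl <- model$cells[[ci]]
    comp_base <- length(comp$C)
    cell_gap <- NA_integer_
    for (pi in seq_along(cl$compartments)) {
      cp <- cl$compartments[[pi]]
      gi <- comp_base + pi
      comp$C <- c(comp$C, cp$capacitance)
      comp$g_leak <- c(comp$g_leak, cp$g_leak)
      comp$v_leak <- c(comp$v_leak, cp$v_leak)
      comp$cell <- c(comp$cell, ci)
      comp$label <- c(comp$label,
                      if (is.na(cp$name)) paste0("comp", pi) else cp$name)
      if (pi > 1) {
        link$lo <- c(link$lo, gi - 1L); link$hi <- c(link$hi, gi)
        link$p <- c(link$p, cp$p_up); link$g <- c(link$g, cl$g_int)
      }
      if (cp$has_gap) cell_gap <- gi
      aux_base <- length(aux$comp)
      chan_base <- length(chan$g)
      for (ki in seq_along(cp$channels)) {
        ch <- cp$channels[[ki]]
        chan$g <- c(chan$g, ch$conductance)
        chan$rev <- c(chan$rev, ch$reversal)
        chan$comp <- c(chan$comp, gi)
        chan$label <- c(chan$label,
                        if (is.na(ch$name)) paste0("ch", ki) else ch$name)
        for (gk in seq_along(ch$gates)) {
          g <- ch$gates[[gk]]
          gate$form <- c(gate$form, if (g$formulation == "alpha_beta") 1L else 2L)
          gate$exponent <- c(gate$exponent, g$exponent)
          gate$channel <- c(gate$channel, chan_base + ki)
          gate$comp <- c(gate$comp, gi)
          gate$drv_type <- c(gate$drv_type, if (g$driver == "voltage") 0L else 1L)
          gate$drv_idx <- c(gate$drv_idx,
                            if (g$driver == "voltage") gi
                            else aux_base + g$driver_index)
          gate$rank <- c(gate$rank, gk)
          gate$label <- c(gate$label,
                          if (is.na(g$name)) paste0("y", length(gate$form)) else g$name)
          for (r in 1:2) {
            rr <- if (r == 1) g$rate1 else g$rate2
            gate[[paste0("ft", r)]] <- c(gate[[paste0("ft", r)]], rr$f_t)
            gate[[paste0("k0", r)]] <- c(gate[[paste0("k0", r)]], rr$k0)
            gate[[paste0("k1", r)]] <- c(gate[[paste0("k1", r)]], rr$k1)
            gate[[paste0("k2", r)]] <- c(gate[[paste0("k2", r)]], rr$k2)
            gate[[paste0("a", r)]] <- c(gate[[paste0("a", r)]], rr$a)
            gate[[paste0("b", r)]] <- c(gate[[paste0("b", r)]], rr$b)
          }
        }
      }
      for (ai in seq_along(cp$aux_states)) {
        a <- cp$aux_states[[ai]]
        aux$comp <- c(aux$comp, gi)
        aux$channel <- c(aux$channel, chan_base + a$channel)
        aux$cI <- c(aux$cI, a$c_current)
        aux$cS <- c(aux$cS, a$c_self)
        aux$label <- c(aux$label,
                       if (is.na(a$name)) paste0("s", length(aux$comp)) else a$name)
      }
    }
    gap_comp <- c(gap_comp, cell_gap)
  }
  n_comp <- length(comp$C)
  comp_f <- factor(seq_len(n_comp), levels = seq_len(n_comp))
  # rank partition: indices of gates holding rank r within their channel
  ranks <- if (length(gate$rank)) lapply(seq_len(max(gate$rank)), function(r)
    which(gate$rank == r)) else list()
  has_gap <- any(!is.na(gap_comp)) && !is.null(model$weights)
  list(model = model, comp = comp, link = link, chan = chan, gate = gate,
       aux = aux, gap_comp = gap_comp, n_comp = n_comp, n_gate = length(gate$form),
       n_aux = length(aux$comp), n_chan = length(chan$g), ranks = ranks,
       comp_levels = comp_f, has_gap = has_gap,
       weights = if (has_gap) realized_weights(model) else NULL)
}

# per-channel open-fraction products from the gate vector
.y_products <- function(cm, y) {
  yp <- rep(1, cm$n_chan)
  for (idx in cm$ranks) {
    if (!length(idx)) next
    yp[cm$gate$channel[idx]] <- yp[cm$gate$channel[idx]] *
      y[idx] ^ cm$gate$exponent[idx]
  }
  yp
}

# full derivative of the flattened state; gap currents are computed through
# the ring-partitioned engine over the plan in `gap`
.state_derivative <- function(cm, V, y, s, i_app, gap = NULL) {
  g <- cm$gate
  v_drv <- numeric(cm$n_gate)
  if (cm$n_gate) {
    iv <- g$drv_type == 0L
    v_drv[iv] <- V[g$drv_idx[iv]]
    if (any(!iv)) v_drv[!iv] <- s[g$drv_idx[!iv]]
  }
  r1 <- .eval_rate_core(g$ft1, g$k01, g$k11, g$k21, g$a1, g$b1, v_drv)
  r2 <- .eval_rate_core(g$ft2, g$k02, g$k12, g$k22, g$a2, g$b2, v_drv)
  dy <- numeric(cm$n_gate)
  ab <- g$form == 1L
  dy[ab] <- (1 - y[ab]) * r1[ab] - y[ab] * r2[ab]
  it <- !ab
  if (any(it)) {
    bad_tau <- which(r2[it] <= 0)
    if (length(bad_tau))
      stop("non-positive time constant for gate '",
           g$label[it][bad_tau[1]], "'", call. = FALSE)
    dy[it] <- (r1[it] - y[it]) / r2[it]
  }
  yp <- .y_products(cm, y)
  ich <- cm$chan$g * (V[cm$chan$comp] - cm$chan$rev) * yp
  i_channels <- as.numeric(rowsum(c(ich, numeric(cm$n_comp)),
                                  c(cm$chan$comp, seq_len(cm$n_comp))))
  i_leak <- cm$comp$g_leak * (V - cm$comp$v_leak)
  i_mc <- numeric(cm$n_comp)
  if (length(cm$link$lo)) {
    lk <- cm$link
    i_mc[lk$hi] <- i_mc[lk$hi] + lk$g * (V[lk$hi] - V[lk$lo]) / lk$p
    i_mc[lk$lo] <- i_mc[lk$lo] + lk$g * (V[lk$lo] - V[lk$hi]) / (1 - lk$p)
  }
  i_gap <- numeric(cm$n_comp)
  if (cm$has_gap && !is.null(gap)) {
    gcells <- which(!is.na(cm$gap_comp))
    v_gap <- V[cm$gap_comp[gcells]]
    ig <- compute_gap_partitioned(cm$weights, v_gap, gap$plan,
                                  order = gap$order, c0 = cm$model$c0,
                                  c1 = cm$model$c1, c2 = cm$model$c2)
    i_gap[cm$gap_comp[gcells]] <- ig
  }
  dV <- (i_app - i_channels - i_leak - i_mc - i_gap) / cm$comp$C
  ds <- if (cm$n_aux) cm$aux$cI * ich[cm$aux$channel] + cm$aux$cS * s
        else numeric(0)
  list(dV = dV, dy = dy, ds = ds, ich = ich)
}

#' Stimulus specifications
#'
#' A stimulus is an applied current `I_app(t)` attached to one compartment.
#' `stim_constant()` is a constant amplitude; `stim_pulse()` is `amplitude`
#' on the half-open interval `[on, off)` and 0 outside; `stim_series()`
#' holds each sampled value from its time until the next sample
#' (zero-order hold), and is 0 before the first sample (with a warning).
#'
#' @param amplitude current amplitude.
#' @param on,off pulse start and end times (`on < off`).
#' @param times strictly increasing sample times.
#' @param values sampled amplitudes, same length as `times`.
#' @return An object of class `stimulus_spec`.
#' @export
stim_constant <- function(amplitude) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, is.finite(amplitude))
  structure(list(kind = "constant", amplitude = as.numeric(amplitude)),
            class = "stimulus_spec")
}

#' @rdname stim_constant
#' @export
stim_pulse <- function(amplitude, on, off) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L,
            is.numeric(on), length(on) == 1L, is.numeric(off), length(off) == 1L)
  if (!(on < off)) stop("pulse requires on < off", call. = FALSE)
  structure(list(kind = "pulse", amplitude = as.numeric(amplitude),
                 on = as.numeric(on), off = as.numeric(off)),
            class = "stimulus_spec")
}

#' @rdname stim_constant
#' @export
stim_series <- function(times, values) {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values), length(times) >= 1L)
  if (any(diff(times) <= 0))
    stop("series times must be strictly increasing", call. = FALSE)
  structure(list(kind = "series", times = as.numeric(times),
                 values = as.numeric(values)),
            class = "stimulus_spec")
}

#' Evaluate a stimulus at given times
#'
#' @param spec a [stim_constant()], [stim_pulse()] or [stim_series()].
#' @param t numeric vector of times (`>= 0`).
#' @return Applied current at each time.
#' @export
eval_stimulus <- function(spec, t) {
  stopifnot(inherits(spec, "stimulus_spec"), is.numeric(t), all(t >= 0))
  switch(spec$kind,
    constant = rep(spec$amplitude, length(t)),
    pulse = ifelse(t >= spec$on & t < spec$off, spec$amplitude, 0),
    series = {
      idx <- findInterval(t, spec$times)
      if (any(idx == 0))
        warning("stimulus evaluated before the first series sample; using 0",
                call. = FALSE)
      ifelse(idx == 0, 0, spec$values[pmax(idx, 1L)])
    })
}

#' Simulation configuration
#'
#' @param dt time step (`> 0`), in the model's time units.
#' @param n_steps number of forward-Euler steps (`>= 1`).
#' @param stimuli list of entries `list(cell =, comp =, spec =)` attaching a
#'   [stimulus_spec] to a compartment (1-based indices).
#' @param record_stride record every `record_stride`-th state (the initial
#'   state at `t = 0` is always recorded).
#' @param init `"steady_state"` (gates and auxiliary states initialized to
#'   their fixed points at voltage `v0`) or `"explicit"` (supply `state`).
#' @param v0 initial voltage for steady-state initialization (scalar or one
#'   value per compartment).
#' @param state an `ehh_state` for explicit initialization.
#' @param n_gap_kernels number of emulated gap kernels `K` for the
#'   ring-partitioned gap computation.
#' @param gap_order accumulation order of the partitioned gap sums,
#'   `"ascending"` (default; results independent of `K`) or `"schedule"`.
#' @param record `"voltage"` (default) or `"all"` (also gates and auxiliary
#'   states).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt, n_steps, stimuli = list(), record_stride = 1L,
                       init = c("steady_state", "explicit"), v0 = 0,
                       state = NULL, n_gap_kernels = 1L,
                       gap_order = c("ascending", "schedule"),
                       record = c("voltage", "all")) {
  init <- match.arg(init)
  gap_order <- match.arg(gap_order)
  record <- match.arg(record)
  if (!is.numeric(dt) || length(dt) != 1L || !(dt > 0))
    stop("'dt' must be a single positive number", call. = FALSE)
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1)
    stop("'n_steps' must be >= 1", call. = FALSE)
  if (!is.numeric(record_stride) || record_stride < 1)
    stop("'record_stride' must be >= 1", call. = FALSE)
  if (init == "explicit" && is.null(state))
    stop("explicit initialization requires 'state'", call. = FALSE)
  for (st in stimuli)
    if (!is.list(st) || !all(c("cell", "comp", "spec") %in% names(st)) ||
        !inherits(st$spec, "stimulus_spec"))
      stop("each stimulus entry must be list(cell =, comp =, spec = stimulus_spec)",
           call. = FALSE)
  structure(
    list(dt = as.numeric(dt), n_steps = as.integer(n_steps), stimuli = stimuli,
         record_stride = as.integer(record_stride), init = init,
         v0 = as.numeric(v0), state = state,
         n_gap_kernels = as.integer(n_gap_kernels), gap_order = gap_order,
         record = record),
    class = "sim_config")
}

#' Steady-state gate values at a voltage
#'
#' Fixed points of the gate dynamics at driver value `v`: `alpha / (alpha +
#' beta)` for transition-rate gates, `inf(v)` for relaxation gates.  Gates
#' driven by auxiliary states are evaluated at that state's steady value
#' when called through [init_state()]; called directly, `v` is used for
#' every gate.
#'
#' @param model a [network_model()].
#' @param v driver value (scalar, or one value per gate variable).
#' @return Numeric vector of gate values in model order (gating states only,
#'   no auxiliary states).
#' @export
steady_state_gates <- function(model, v) {
  cm <- if (inherits(model, "network_model")) compile_model(model) else model
  g <- cm$gate
  vv <- rep_len(as.numeric(v), cm$n_gate)
  r1 <- .eval_rate_core(g$ft1, g$k01, g$k11, g$k21, g$a1, g$b1, vv)
  r2 <- .eval_rate_core(g$ft2, g$k02, g$k12, g$k22, g$a2, g$b2, vv)
  out <- numeric(cm$n_gate)
  ab <- g$form == 1L
  if (any(ab)) {
    tot <- r1[ab] + r2[ab]
    zero <- which(tot == 0)
    if (length(zero))
      stop("degenerate gate: alpha + beta = 0 for gate '",
           g$label[ab][zero[1]], "'", call. = FALSE)
    out[ab] <- r1[ab] / tot
  }
  out[!ab] <- r1[!ab]
  out
}

#' Construct an initial state
#'
#' Builds an `ehh_state` at `t = 0` with all compartments at voltage `v0`,
#' voltage-driven gates at their steady state, auxiliary states at their
#' fixed point given the resulting channel currents, and auxiliary-driven
#' gates at their steady state for those values.
#'
#' @param model a [network_model()].
#' @param v0 initial voltage (scalar or per compartment).
#' @return An object of class `ehh_state` with fields `V`, `y`, `s`, `t`.
#' @export
init_state <- function(model, v0 = 0) {
  cm <- if (inherits(model, "network_model")) compile_model(model) else model
  V <- rep_len(as.numeric(v0), cm$n_comp)
  g <- cm$gate
  y <- steady_state_gates(cm, if (cm$n_gate) V[g$comp] else numeric(0))
  s <- numeric(cm$n_aux)
  if (cm$n_aux) {
    yp <- .y_products(cm, y)
    ich <- cm$chan$g * (V[cm$chan$comp] - cm$chan$rev) * yp
    if (any(cm$aux$cS >= 0))
      stop("auxiliary steady state requires a negative self coefficient",
           call. = FALSE)
    s <- -cm$aux$cI * ich[cm$aux$channel] / cm$aux$cS
    idx <- which(g$drv_type == 1L)
    if (length(idx)) {
      drv <- s[g$drv_idx[idx]]
      r1 <- .eval_rate_core(g$ft1[idx], g$k01[idx], g$k11[idx], g$k21[idx],
                            g$a1[idx], g$b1[idx], drv)
      r2 <- .eval_rate_core(g$ft2[idx], g$k02[idx], g$k12[idx], g$k22[idx],
                            g$a2[idx], g$b2[idx], drv)
      y[idx] <- ifelse(g$form[idx] == 1L, r1 / (r1 + r2), r1)
    }
  }
  structure(list(V = V, y = y, s = s, t = 0), class = "ehh_state")
}

#' Resting voltage of a single-compartment cell
#'
#' Solves `I_channels(V) + I_leak(V) = 0` with gates at steady state, by
#' root bracketing.  Only defined for models whose cells have one
#' compartment and no gap coupling.
#'
#' @param model a [network_model()] of single-compartment cells.
#' @param interval search interval for the root.
#' @return The resting voltage.
#' @export
resting_voltage <- function(model, interval = c(-50, 50)) {
  cm <- compile_model(model)
  if (any(cm$comp$cell != cm$comp$cell[1]) || cm$n_comp != 1L)
    stop("resting_voltage() supports single-cell, single-compartment models",
         call. = FALSE)
  total <- function(v) {
    y <- steady_state_gates(cm, rep(v, cm$n_gate))
    yp <- .y_products(cm, y)
    sum(cm$chan$g * (v - cm$chan$rev) * yp) +
      cm$comp$g_leak * (v - cm$comp$v_leak)
  }
  stats::uniroot(total, interval, tol = 1e-12)$root
}

# applied currents per compartment at time t
.applied_currents <- function(cm, stimuli, t) {
  i_app <- numeric(cm$n_comp)
  for (st in stimuli) {
    idx <- which(cm$comp$cell == st$cell)[st$comp]
    if (is.na(idx)) stop("stimulus targets a non-existent compartment",
                         call. = FALSE)
    i_app[idx] <- i_app[idx] + eval_stimulus(st$spec, t)
  }
  i_app
}

#' One forward-Euler step
#'
#' Advances the whole state synchronously: `u + dt * f(u)` with every term
#' of the membrane equation assembled from the pre-step snapshot.  The input
#' state is not modified.
#'
#' @param model a [network_model()] (or an internal compiled model).
#' @param state an `ehh_state`.
#' @param stimuli list of stimulus entries as in [sim_config()].
#' @param dt time step (`>= 0`; `dt = 0` only advances bookkeeping).
#' @param gap optional list(plan =, order =) controlling the partitioned gap
#'   computation; defaults to a single kernel.
#' @return The advanced `ehh_state`.
#' @export
euler_step <- function(model, state, stimuli = list(), dt, gap = NULL) {
  cm <- if (inherits(model, "network_model")) compile_model(model) else model
  stopifnot(inherits(state, "ehh_state"), dt >= 0)
  if (length(state$V) != cm$n_comp || length(state$y) != cm$n_gate)
    stop("state layout does not match the model", call. = FALSE)
  if (is.null(gap) && cm$has_gap) {
    n_gapcells <- sum(!is.na(cm$gap_comp))
    gap <- list(plan = make_partition(n_gapcells, 1L), order = "ascending")
  }
  i_app <- .applied_currents(cm, stimuli, state$t)
  d <- .state_derivative(cm, state$V, state$y, state$s, i_app, gap)
  bad <- c(!is.finite(d$dV), !is.finite(d$dy), !is.finite(d$ds))
  if (any(bad)) {
    labels <- c(paste0("V[", cm$comp$label, "]"),
                paste0("y[", cm$gate$label, "]"),
                paste0("s[", cm$aux$label, "]"))
    stop("numerical instability: non-finite derivative for ",
         labels[which(bad)[1]], " at t = ", state$t, call. = FALSE)
  }
  structure(list(V = state$V + dt * d$dV, y = state$y + dt * d$dy,
                 s = state$s + dt * d$ds, t = state$t + dt),
            class = "ehh_state")
}

#' Run a simulation
#'
#' Iterates the forward-Euler step over the configured number of steps and
#' records the state every `record_stride` steps (plus the initial state).
#' Deterministic: identical model, configuration and weights give
#' byte-identical traces.
#'
#' @param model a [network_model()].
#' @param config a [sim_config()].
#' @return An object of class `ehh_trace`: a numeric matrix with a `time`
#'   column followed by one column per recorded variable, named
#'   `cell<i>/<compartment>/<variable>`.
#' @export
run_simulation <- function(model, config) {
  stopifnot(inherits(model, "network_model"), inherits(config, "sim_config"))
  cm <- compile_model(model)
  state <- if (config$init == "steady_state") init_state(cm, config$v0)
           else config$state
  if (!inherits(state, "ehh_state"))
    stop("explicit initialization requires an 'ehh_state'", call. = FALSE)
  gap <- NULL
  if (cm$has_gap) {
    n_gapcells <- sum(!is.na(cm$gap_comp))
    gap <- list(plan = make_partition(n_gapcells, config$n_gap_kernels),
                order = config$gap_order)
  }
  labels <- paste0("cell", cm$comp$cell, "/", cm$comp$label, "/V")
  if (config$record == "all") {
    labels <- c(labels,
      paste0("cell", cm$comp$cell[cm$gate$comp], "/",
             cm$comp$label[cm$gate$comp], "/", cm$gate$label),
      if (cm$n_aux) paste0("cell", cm$comp$cell[cm$aux$comp], "/",
                           cm$comp$label[cm$aux$comp], "/", cm$aux$label))
  }
  take <- function(st) if (config$record == "all") c(st$V, st$y, st$s) else st$V
  n_rec <- 1L + config$n_steps %/% config$record_stride
  out <- matrix(NA_real_, n_rec, 1L + length(labels),
                dimnames = list(NULL, c("time", labels)))
  out[1L, ] <- c(state$t, take(state))
  row <- 1L
  for (step in seq_len(config$n_steps)) {
    state <- tryCatch(
      euler_step(cm, state, config$stimuli, config$dt, gap),
      error = function(e)
        stop("at step ", step, ": ", conditionMessage(e), call. = FALSE))
    if (step %% config$record_stride == 0L) {
      row <- row + 1L
      out[row, ] <- c(state$t, take(state))
    }
  }
  structure(out[seq_len(row), , drop = FALSE], class = "ehh_trace",
            dt = config$dt, record_stride = config$record_stride)
}

#' @export
print.ehh_trace <- function(x, ...) {
  cat("<ehh_trace>", nrow(x), "recorded steps x", ncol(x) - 1L,
      "variables, t in [", x[1, "time"], ",", x[nrow(x), "time"], "]\n")
  invisible(x)
}

#' @export
plot.ehh_trace <- function(x, columns = NULL, ...) {
  cols <- if (is.null(columns)) setdiff(colnames(x), "time")[1] else columns
  graphics::matplot(x[, "time"], unclass(x)[, cols, drop = FALSE], type = "l",
                    xlab = "time", ylab = "value", ...)
  graphics::legend("topright", legend = cols, lty = seq_along(cols),
                   col = seq_along(cols), bty = "n")
  invisible(x)
}
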