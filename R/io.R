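# numeric attribute possibly carrying a unit suffix ("10mV", "1.2 per_ms");
# values are taken in the file's declared units, no conversion is attempted
.nml_num <- function(x, what) {
  m <- regmatches(x, regexec("^\\s*([-+]?[0-9.]+([eE][-+]?[0-9]+)?)\\s*[A-Za-z_]*\\s*$", x))[[1]]
  if (length(m) < 2L)
    stop("cannot parse numeric attribute '", x, "' for ", what, call. = FALSE)
  as.numeric(m[2])
}

# supported rate-element spellings: current type names and the legacy
# "...Variable" spellings used by older documents
.nml_rate_kinds <- list(
  sigmoid = c("HHSigmoidRate", "HHSigmoidVariable"),
  exponential = c("HHExpRate", "HHExponentialRate", "HHExpVariable",
                  "HHExponentialVariable"),
  explinear = c("HHExpLinearRate", "HHExpLinearVariable"))

#' Convert a NeuroML HH rate element to a rate function
#'
#' Maps the three supported NeuroML rate forms, written in terms of
#' `rate`, `midpoint` and `scale` attributes, onto the generalized
#' three-branch family:
#'
#' * sigmoid `rate / (1 + exp((midpoint - v)/scale))` ->
#'   `(f_t = 2, k0 = rate, k1 = midpoint, k2 = 1/scale)`
#' * exponential `rate * exp((v - midpoint)/scale)` ->
#'   `(f_t = 1, k0 = rate, k1 = midpoint, k2 = -1/scale)`
#' * exp-linear `rate * x / (1 - exp(-x))`, `x = (v - midpoint)/scale` ->
#'   `(f_t = 0, k0 = rate/scale, k1 = midpoint, k2 = 1/scale)`
#'
#' The mappings are algebraic identities, so the converted record agrees
#' with the source formula to rounding error on any voltage grid.  Both the
#' current type names and the legacy `...Variable` spellings are accepted;
#' any other rate element raises an unsupported-feature error naming it.
#'
#' @param node an `xml2` element with `type`, `rate`, `midpoint` and
#'   `scale` attributes.
#' @return A [rate_function()].
#' @export
parse_neuroml_rate <- function(node) {
  type <- xml2::xml_attr(node, "type")
  if (is.na(type)) type <- xml2::xml_name(node)
  kind <- NULL
  for (k in names(.nml_rate_kinds))
    if (type %in% .nml_rate_kinds[[k]]) kind <- k
  if (is.null(kind))
    stop("unsupported NeuroML rate element '", type,
         "' (supported: HH sigmoid / exp / exp-linear forms)", call. = FALSE)
  rate <- .nml_num(xml2::xml_attr(node, "rate"), "rate")
  midpoint <- .nml_num(xml2::xml_attr(node, "midpoint"), "midpoint")
  scale <- .nml_num(xml2::xml_attr(node, "scale"), "scale")
  if (scale == 0)
    stop("NeuroML rate element '", type, "' has scale = 0", call. = FALSE)
  switch(kind,
    sigmoid = rate_function(2, k0 = rate, k1 = midpoint, k2 = 1 / scale),
    exponential = rate_function(1, k0 = rate, k1 = midpoint, k2 = -1 / scale),
    explinear = rate_function(0, k0 = rate / scale, k1 = midpoint,
                              k2 = 1 / scale))
}

#' Convert a NeuroML gate element to a gate specification
#'
#' Supports `gateHHrates` (children `forwardRate` / `reverseRate` ->
#' alpha/beta formulation) and `gateHHtauInf` (children `steadyState` /
#' `timeCourse` -> inf/tau formulation); the `instances` attribute becomes
#' the gate exponent.  Rate children are converted with
#' [parse_neuroml_rate()]; a `timeCourse` of type `fixedTimeCourse` maps to
#' a constant rate.  Any other gate element raises an unsupported-feature
#' error naming it.
#'
#' @param node an `xml2` element.
#' @return A [gate_spec()].
#' @export
parse_neuroml_gate <- function(node) {
  name <- xml2::xml_name(node)
  gname <- xml2::xml_attr(node, "id")
  inst <- xml2::xml_attr(node, "instances")
  exponent <- if (is.na(inst)) 1L else as.integer(.nml_num(inst, "instances"))
  child <- function(tag) {
    nd <- xml2::xml_find_first(node, paste0("./*[local-name() = '", tag, "']"))
    if (inherits(nd, "xml_missing"))
      stop("gate '", if (is.na(gname)) name else gname, "' lacks a <", tag,
           "> child", call. = FALSE)
    nd
  }
  if (name == "gateHHrates") {
    gate_spec("alpha_beta",
              rate1 = parse_neuroml_rate(child("forwardRate")),
              rate2 = parse_neuroml_rate(child("reverseRate")),
              exponent = exponent, name = gname)
  } else if (name == "gateHHtauInf") {
    tc <- child("timeCourse")
    tau <- if (identical(xml2::xml_attr(tc, "type"), "fixedTimeCourse"))
      rate_function(1, k0 = .nml_num(xml2::xml_attr(tc, "tau"), "tau"),
                    k1 = 0, k2 = 0)
    else parse_neuroml_rate(tc)
    gate_spec("inf_tau",
              rate1 = parse_neuroml_rate(child("steadyState")),
              rate2 = tau, exponent = exponent, name = gname)
  } else {
    stop("unsupported NeuroML gate element '", name,
         "' (supported: gateHHrates, gateHHtauInf)", call. = FALSE)
  }
}

#' Import all HH gates from a NeuroML document
#'
#' @param path file path of a NeuroML (XML) document.
#' @return A named list of [gate_spec()] records, one per supported gate
#'   element found anywhere in the document.
#' @export
read_neuroml_gates <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(
    doc, "//*[local-name() = 'gateHHrates' or local-name() = 'gateHHtauInf']")
  gates <- lapply(nodes, parse_neuroml_gate)
  names(gates) <- vapply(gates, function(g)
    if (is.na(g$name)) "" else g$name, character(1))
  gates
}

# ---- native configuration documents --------------------------------------

.cfg_check_fields <- function(obj, allowed, required, path) {
  extra <- setdiff(names(obj), allowed)
  if (length(extra))
    stop("schema violation at ", path, ": unknown field '", extra[1], "'",
         call. = FALSE)
  missing <- setdiff(required, names(obj))
  if (length(missing))
    stop("schema violation at ", path, ": missing field '", missing[1], "'",
         call. = FALSE)
}

.rate_to_list <- function(r)
  list(f_t = r$f_t, k0 = r$k0, k1 = r$k1, k2 = r$k2, a = r$a, b = r$b)

.rate_from_list <- function(x, path) {
  .cfg_check_fields(x, c("f_t", "k0", "k1", "k2", "a", "b"),
                    c("f_t", "k0", "k1", "k2"), path)
  rate_function(x$f_t, x$k0, x$k1, x$k2,
                a = if (is.null(x$a)) 1 else x$a,
                b = if (is.null(x$b)) 0 else x$b)
}

.gate_to_list <- function(g) {
  list(name = if (is.na(g$name)) NULL else g$name,
       formulation = g$formulation, exponent = g$exponent,
       driver = g$driver, driver_index = g$driver_index,
       rate1 = .rate_to_list(g$rate1), rate2 = .rate_to_list(g$rate2))
}

.channel_to_list <- function(ch) {
  list(name = if (is.na(ch$name)) NULL else ch$name,
       conductance = ch$conductance, reversal = ch$reversal,
       gates = lapply(ch$gates, .gate_to_list))
}

.comp_to_list <- function(cp) {
  list(name = if (is.na(cp$name)) NULL else cp$name,
       capacitance = cp$capacitance, g_leak = cp$g_leak,
       v_leak = cp$v_leak, p_up = cp$p_up, has_gap = cp$has_gap,
       channels = lapply(cp$channels, .channel_to_list),
       aux_states = lapply(cp$aux_states, function(a)
         list(name = if (is.na(a$name)) NULL else a$name,
              channel = a$channel, c_current = a$c_current,
              c_self = a$c_self)))
}

.model_to_list <- function(model) {
  cells <- lapply(model$cells, function(cl)
    list(name = if (is.na(cl$name)) NULL else cl$name,
         g_int = cl$g_int,
         compartments = lapply(cl$compartments, .comp_to_list)))
  weights <-
    if (is.null(model$weights)) list(kind = "none")
    else if (inherits(model$weights, "weight_source"))
      list(kind = "generated", dist = model$weights$dist,
           key = model$weights$key, mu = model$weights$mu,
           sigma = model$weights$sigma, symmetric = model$weights$symmetric,
           scale = model$weights$scale)
    else list(kind = "matrix", values = unclass(model$weights))
  list(c0 = model$c0, c1 = model$c1, c2 = model$c2, cells = cells,
       weights = weights)
}

.model_from_list <- function(x, path = "model") {
  .cfg_check_fields(x, c("c0", "c1", "c2", "cells", "weights"),
                    c("cells", "weights"), path)
  cells <- lapply(seq_along(x$cells), function(i) {
    cl <- x$cells[[i]]
    cpath <- paste0(path, ".cells[", i, "]")
    .cfg_check_fields(cl, c("name", "g_int", "compartments"),
                      "compartments", cpath)
    comps <- lapply(seq_along(cl$compartments), function(j) {
      cp <- cl$compartments[[j]]
      ppath <- paste0(cpath, ".compartments[", j, "]")
      .cfg_check_fields(cp, c("name", "capacitance", "g_leak", "v_leak",
                              "p_up", "has_gap", "channels", "aux_states"),
                        "capacitance", ppath)
      chans <- lapply(seq_along(cp$channels), function(k) {
        ch <- cp$channels[[k]]
        hpath <- paste0(ppath, ".channels[", k, "]")
        .cfg_check_fields(ch, c("name", "conductance", "reversal", "gates"),
                          c("conductance", "reversal"), hpath)
        gates <- lapply(seq_along(ch$gates), function(m) {
          g <- ch$gates[[m]]
          gpath <- paste0(hpath, ".gates[", m, "]")
          .cfg_check_fields(g, c("name", "formulation", "exponent", "driver",
                                 "driver_index", "rate1", "rate2"),
                            c("formulation", "rate1", "rate2"), gpath)
          gate_spec(g$formulation,
                    rate1 = .rate_from_list(g$rate1, paste0(gpath, ".rate1")),
                    rate2 = .rate_from_list(g$rate2, paste0(gpath, ".rate2")),
                    exponent = if (is.null(g$exponent)) 1L else g$exponent,
                    driver = if (is.null(g$driver)) "voltage" else g$driver,
                    driver_index = if (is.null(g$driver_index)) 1L
                                   else g$driver_index,
                    name = g$name)
        })
        channel_spec(ch$conductance, ch$reversal, gates, name = ch$name)
      })
      auxs <- lapply(seq_along(cp$aux_states), function(k) {
        a <- cp$aux_states[[k]]
        apath <- paste0(ppath, ".aux_states[", k, "]")
        .cfg_check_fields(a, c("name", "channel", "c_current", "c_self"),
                          c("channel", "c_current", "c_self"), apath)
        aux_state_spec(a$channel, a$c_current, a$c_self, name = a$name)
      })
      compartment_spec(
        capacitance = cp$capacitance,
        g_leak = if (is.null(cp$g_leak)) 0 else cp$g_leak,
        v_leak = if (is.null(cp$v_leak)) 0 else cp$v_leak,
        channels = chans,
        p_up = if (is.null(cp$p_up)) 0.5 else cp$p_up,
        has_gap = isTRUE(cp$has_gap), aux_states = auxs, name = cp$name)
    })
    cell_spec(comps, g_int = if (is.null(cl$g_int)) 0 else cl$g_int,
              name = cl$name)
  })
  wpath <- paste0(path, ".weights")
  w <- x$weights
  .cfg_check_fields(w, c("kind", "values", "dist", "key", "mu", "sigma",
                         "symmetric", "scale"), "kind", wpath)
  weights <- switch(w$kind,
    none = NULL,
    matrix = {
      vals <- do.call(rbind, lapply(w$values, unlist))
      if (is.null(vals)) stop("schema violation at ", wpath,
                              ": matrix weights need 'values'", call. = FALSE)
      vals
    },
    generated = weight_source(
      dist = w$dist, key = w$key,
      mu = if (is.null(w$mu)) 0.5 else w$mu,
      sigma = if (is.null(w$sigma)) 0.15 else w$sigma,
      symmetric = if (is.null(w$symmetric)) TRUE else w$symmetric,
      scale = if (is.null(w$scale)) 1 else w$scale),
    stop("schema violation at ", wpath, ": unknown weights kind '", w$kind,
         "'", call. = FALSE))
  has_gap <- any(vapply(cells, function(cl)
    any(vapply(cl$compartments, `[[`, logical(1), "has_gap")), logical(1)))
  if (has_gap && is.null(x$weights$kind))
    stop("schema violation at ", wpath,
         ": gap compartments present but no weight source", call. = FALSE)
  network_model(cells,
                c0 = if (is.null(x$c0)) 0 else x$c0,
                c1 = if (is.null(x$c1)) 0 else x$c1,
                c2 = if (is.null(x$c2)) 0 else x$c2,
                weights = weights)
}

.stim_to_list <- function(st) {
  out <- list(cell = st$cell, comp = st$comp, kind = st$spec$kind)
  c(out, st$spec[setdiff(names(st$spec), "kind")])
}

.stim_from_list <- function(x, path) {
  .cfg_check_fields(x, c("cell", "comp", "kind", "amplitude", "on", "off",
                         "times", "values"), c("cell", "comp", "kind"), path)
  spec <- switch(x$kind,
    constant = stim_constant(x$amplitude),
    pulse = stim_pulse(x$amplitude, x$on, x$off),
    series = stim_series(unlist(x$times), unlist(x$values)),
    stop("schema violation at ", path, ": unknown stimulus kind '", x$kind,
         "'", call. = FALSE))
  list(cell = x$cell, comp = x$comp, spec = spec)
}

#' Export a model and simulation configuration as a native document
#'
#' The native format is a versioned JSON document carrying the full network
#' description (cells, compartments, channels, gates, auxiliary states, gap
#' constants, weight source) plus the solver settings.  Export, load and
#' re-export is byte-stable.
#'
#' @param model a [network_model()].
#' @param config optionally a [sim_config()].
#' @param path optional file to write; when `NULL` the JSON text is
#'   returned.
#' @return The JSON text, invisibly when written to a file.
#' @export
export_config <- function(model, config = NULL, path = NULL) {
  stopifnot(inherits(model, "network_model"))
  doc <- list(format = "ehh-config", version = 1L,
              model = .model_to_list(model))
  if (!is.null(config)) {
    stopifnot(inherits(config, "sim_config"))
    init <- if (config$init == "steady_state")
      list(policy = "steady_state", v0 = config$v0)
    else list(policy = "explicit", V = config$state$V, y = config$state$y,
              s = config$state$s)
    doc$sim <- list(dt = config$dt, n_steps = config$n_steps,
                    record_stride = config$record_stride,
                    record = config$record,
                    n_gap_kernels = config$n_gap_kernels,
                    gap_order = config$gap_order, init = init,
                    stimuli = lapply(config$stimuli, .stim_to_list))
  }
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(as.character(json))
}

#' Load a native configuration document
#'
#' Validates the document against the schema (unknown fields are rejected
#' with the offending path) and reconstructs the model and, when present,
#' the simulation configuration.
#'
#' @param path file path, or a JSON string.
#' @return A list with elements `model` ([network_model()]) and `config`
#'   ([sim_config()] or `NULL`).
#' @export
load_config <- function(path) {
  txt <- if (length(path) == 1L && file.exists(path))
    paste(readLines(path, warn = FALSE), collapse = "\n") else path
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  .cfg_check_fields(doc, c("format", "version", "model", "sim"),
                    c("format", "version", "model"), "document")
  if (!identical(doc$format, "ehh-config"))
    stop("schema violation at document.format: not an ehh-config document",
         call. = FALSE)
  if (!identical(as.integer(doc$version), 1L))
    stop("schema violation at document.version: unsupported version ",
         doc$version, call. = FALSE)
  model <- .model_from_list(doc$model)
  config <- NULL
  if (!is.null(doc$sim)) {
    s <- doc$sim
    .cfg_check_fields(s, c("dt", "n_steps", "record_stride", "record",
                           "n_gap_kernels", "gap_order", "init", "stimuli"),
                      c("dt", "n_steps"), "sim")
    init <- if (is.null(s$init)) list(policy = "steady_state", v0 = 0) else s$init
    .cfg_check_fields(init, c("policy", "v0", "V", "y", "s"), "policy",
                      "sim.init")
    state <- NULL
    if (identical(init$policy, "explicit"))
      state <- structure(list(V = unlist(init$V), y = unlist(init$y),
                              s = if (is.null(init$s)) numeric(0)
                                  else unlist(init$s), t = 0),
                         class = "ehh_state")
    config <- sim_config(
      dt = s$dt, n_steps = s$n_steps,
      stimuli = lapply(seq_along(s$stimuli), function(i)
        .stim_from_list(s$stimuli[[i]], paste0("sim.stimuli[", i, "]"))),
      record_stride = if (is.null(s$record_stride)) 1L else s$record_stride,
      init = init$policy,
      v0 = if (is.null(init$v0)) 0 else unlist(init$v0), state = state,
      n_gap_kernels = if (is.null(s$n_gap_kernels)) 1L else s$n_gap_kernels,
      gap_order = if (is.null(s$gap_order)) "ascending" else s$gap_order,
      record = if (is.null(s$record)) "voltage" else s$record)
  }
  list(model = model, config = config)
}

#' Write and read simulation traces
#'
#' Traces are tab-delimited text with a header row (`time`, then one
#' `cell/compartment/variable` identifier per column) and one row per
#' recorded step.  Numbers are written with 17 significant digits so the
#' read-back trace equals the in-memory trace exactly.
#'
#' @param trace an `ehh_trace` (or plain matrix with a `time` column).
#' @param path destination / source file path.
#' @return `read_trace()` returns the trace matrix.
#' @export
write_trace <- function(trace, path) {
  if (nrow(trace) == 0L) stop("trace is empty", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(trace), collapse = "\t"), con)
  body <- apply(unclass(trace), 1L, function(row)
    paste(sprintf("%.17g", row), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  dat <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(dat)
  rownames(m) <- NULL
  structure(m, class = "ehh_trace")
}

#' Write and read weight matrices as delimited text
#'
#' One matrix row per line, tab-separated, full double precision.
#'
#' @param w square numeric matrix.
#' @param path destination / source file path.
#' @return `read_weights()` returns the matrix.
#' @export
write_weights <- function(w, path) {
  w <- as.matrix(w)
  writeLines(apply(w, 1L, function(row)
    paste(sprintf("%.17g", row), collapse = "\t")), path)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  unname(as.matrix(utils::read.delim(path, header = FALSE)))
}
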