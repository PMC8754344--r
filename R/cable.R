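# ---------------------------------------------------------------------------
# Circuit assembly and the passive cable simulation front end.  The integrator
# itself (backward Euler + Hines tree solve) lives in src/simulate.cpp; this
# file owns unit conversion, indexing and the result container.
#
# Internal units: mV, ms, nS, pA, pF, um.  Specific quantities are entered in
# the conventional Ohm*cm / uF/cm^2 / S/cm^2 units and converted per
# compartment via its membrane area.
# ---------------------------------------------------------------------------

#' Passive membrane and cytoplasm properties
#'
#' @param axial_resistivity cytoplasmic specific resistance, Ohm cm (75).
#' @param specific_capacitance membrane capacitance, uF/cm^2 (1).
#' @param leak_conductance passive membrane conductance, S/cm^2 (6e-5).
#' @param resting_potential leak reversal / resting potential, mV (-60).
#' @return a `passive_props` object.
#' @export
passive_props <- function(axial_resistivity = 75, specific_capacitance = 1,
                          leak_conductance = 6e-5, resting_potential = -60) {
  stopifnot(axial_resistivity > 0, specific_capacitance > 0,
            leak_conductance > 0)
  structure(list(axial_resistivity = axial_resistivity,
                 specific_capacitance = specific_capacitance,
                 leak_conductance = leak_conductance,
                 resting_potential = resting_potential),
            class = "passive_props")
}

#' Place a discretized cell in a circuit
#'
#' @param tree a [discretize()]d `compartment_tree`.
#' @param passive a [passive_props()].
#' @param soma_xy planar soma position in network coordinates, um; the tree
#'   is translated so its soma sits there.
#' @param stream_seed integer seed of this cell's private RNG stream (release
#'   draws and synapse placement); identical seeds replay bit-exactly.
#' @return a `sim_cell`.
#' @export
make_cell <- function(tree, passive = passive_props(), soma_xy = c(0, 0),
                      stream_seed = 1L) {
  stopifnot(inherits(tree, "compartment_tree"), inherits(passive,
                                                         "passive_props"))
  shift <- soma_xy - c(tree$x[1], tree$y[1])
  tree$x <- tree$x + shift[1]
  tree$y <- tree$y + shift[2]
  structure(list(tree = tree, passive = passive,
                 soma_xy = as.numeric(soma_xy),
                 stream_seed = as.integer(stream_seed)),
            class = "sim_cell")
}

empty_exc <- function() data.frame(cell = integer(0), comp = integer(0),
                                   x = numeric(0), y = numeric(0),
                                   d = numeric(0), pfac = numeric(0),
                                   refill = numeric(0), weight = numeric(0),
                                   mult = numeric(0))
empty_inh <- function() data.frame(pre_cell = integer(0), pre_comp = integer(0),
                                   post_cell = integer(0),
                                   post_comp = integer(0), weight = numeric(0),
                                   e_rev = numeric(0))

#' Assemble a simulatable circuit
#'
#' Collects cells, excitatory (ribbon) synapses, inhibitory (GABA) synapses,
#' voltage clamps and current injections into one indexed structure.  Cells
#' are electrically independent except through synapses.
#'
#' @param cells list of [make_cell()] objects.
#' @param exc_synapses data frame with columns cell, comp, x, y, d, pfac,
#'   refill, weight, mult (see [attach_bc_synapses()]).
#' @param inh_synapses data frame with columns pre_cell, pre_comp, post_cell,
#'   post_comp, weight, e_rev.
#' @param clamps data frame with columns cell, comp, level (mV).
#' @param injections data frame with columns cell, comp, amp_pa, t0, t1 (ms).
#' @param gaba_threshold presynaptic activation threshold, mV.
#' @param gaba_rate event rate while active, Hz.
#' @return a `circuit`.
#' @export
build_circuit <- function(cells, exc_synapses = empty_exc(),
                          inh_synapses = empty_inh(), clamps = NULL,
                          injections = NULL, gaba_threshold = -50,
                          gaba_rate = 200) {
  stopifnot(length(cells) >= 1L,
            all(vapply(cells, inherits, logical(1), "sim_cell")))
  n_comp <- vapply(cells, function(cl) nrow(cl$tree), integer(1))
  offset <- c(0L, cumsum(n_comp))[seq_along(cells)]
  parent <- c_pf <- g_leak <- e_rest <- g_ax <- numeric(0)
  soma_global <- integer(length(cells))
  for (ci in seq_along(cells)) {
    cl <- cells[[ci]]; tr <- cl$tree; pp <- cl$passive
    par_local <- ifelse(is.na(tr$parent), -1L, tr$parent - 1L + offset[ci])
    parent <- c(parent, par_local)
    c_pf <- c(c_pf, pp$specific_capacitance * tr$area_cm2 * 1e6)
    g_leak <- c(g_leak, pp$leak_conductance * tr$area_cm2 * 1e9)
    e_rest <- c(e_rest, rep(pp$resting_potential, nrow(tr)))
    # half-compartment axial resistances, Ohm; L and r in um
    r_half <- pp$axial_resistivity * 1e4 * (tr$length / 2) /
      (pi * tr$r_mid^2)
    gx <- numeric(nrow(tr))
    has_par <- !is.na(tr$parent)
    gx[has_par] <- 1e9 / (r_half[has_par] + r_half[tr$parent[has_par]])
    g_ax <- c(g_ax, gx)
    soma_global[ci] <- offset[ci] + 1L
  }
  structure(list(cells = cells, n_comp = n_comp, offset = offset,
                 soma_global = soma_global,
                 comp = list(parent = as.integer(parent), c_pf = c_pf,
                             g_leak_ns = g_leak, e_rest_mv = e_rest,
                             g_ax_ns = g_ax),
                 exc = exc_synapses, inh = inh_synapses,
                 clamps = clamps, injections = injections,
                 gaba_threshold = gaba_threshold, gaba_rate = gaba_rate),
            class = "circuit")
}

# global 0-based compartment index
.gcomp <- function(circuit, cell, comp) circuit$offset[cell] + comp - 1L

#' Simulate a circuit
#'
#' Integrates the passive branched-cable equations with synaptic
#' conductances, current injections and voltage clamps by backward Euler at
#' step `dt`, solving the per-step linear tree system exactly.  Synaptic
#' conductances are evaluated at the start-of-step voltage, keeping each step
#' linear.  The initial condition is the resting potential everywhere.
#'
#' @param circuit a [build_circuit()] result.
#' @param stim an `intensity_matrix` whose rows follow the order of
#'   `circuit$exc` (or NULL if the circuit has no ribbon synapses).
#' @param duration simulated time, ms.
#' @param dt integration step, ms (0.025).
#' @param deterministic expected-value vesicle release (noise-free).
#' @param record data frame (cell, comp) of recording sites; defaults to the
#'   soma of every cell.
#' @param exc_kernel,inh_kernel conductance kernels for ribbon and GABA
#'   synapses (defaults: 0.89/1.84 ms reversal 0 mV; 3/30 ms with per-synapse
#'   reversal).
#' @param pool_max vesicle pool capacity (70).
#' @return a `simulation_result` with voltage traces (mV) per recorded
#'   compartment, clamp current traces (pA), and per-synapse release totals.
#' @export
simulate_circuit <- function(circuit, stim = NULL, duration, dt = 0.025,
                             deterministic = FALSE, record = NULL,
                             exc_kernel = bipolar_kernel(1),
                             inh_kernel = gaba_kernel(1), pool_max = 70) {
  stopifnot(inherits(circuit, "circuit"), dt > 0, duration > 0)
  n_steps <- round(duration / dt)
  exc <- circuit$exc
  if (nrow(exc) > 0) {
    if (is.null(stim)) stop("circuit has ribbon synapses but no stimulus")
    if (nrow(stim) != nrow(exc))
      stop("stimulus rows must match the excitatory synapse table")
  } else {
    stim <- matrix(0, 1, 1)
    attr(stim, "dt") <- 1
  }
  streams <- vapply(circuit$cells, function(cl) cl$stream_seed, integer(1))
  exc_list <- list(
    comp = as.integer(.gcomp(circuit, exc$cell, exc$comp)),
    stim_row = as.integer(seq_len(nrow(exc)) - 1L),
    stream = as.integer(exc$cell - 1L),
    pfac = as.numeric(exc$pfac), refill = as.numeric(exc$refill),
    weight = as.numeric(exc$weight), mult = as.numeric(exc$mult),
    tau_r = exc_kernel$tau_rise, tau_d = exc_kernel$tau_decay,
    e_rev = exc_kernel$reversal, pool_max = pool_max,
    stream_seed = as.integer(streams))
  inh <- circuit$inh
  inh_list <- list(
    pre = as.integer(.gcomp(circuit, inh$pre_cell, inh$pre_comp)),
    post = as.integer(.gcomp(circuit, inh$post_cell, inh$post_comp)),
    weight = as.numeric(inh$weight), e_rev = as.numeric(inh$e_rev),
    tau_r = inh_kernel$tau_rise, tau_d = inh_kernel$tau_decay,
    thresh = circuit$gaba_threshold,
    period_ms = 1000 / circuit$gaba_rate)
  cl <- circuit$clamps
  clamp_list <- if (is.null(cl)) list(comp = integer(0), level = numeric(0))
    else list(comp = as.integer(.gcomp(circuit, cl$cell, cl$comp)),
              level = as.numeric(cl$level))
  inj <- circuit$injections
  inj_list <- if (is.null(inj))
    list(comp = integer(0), amp_pa = numeric(0), t0 = numeric(0),
         t1 = numeric(0))
    else list(comp = as.integer(.gcomp(circuit, inj$cell, inj$comp)),
              amp_pa = as.numeric(inj$amp_pa), t0 = as.numeric(inj$t0),
              t1 = as.numeric(inj$t1))
  if (is.null(record))
    record <- data.frame(cell = seq_along(circuit$cells),
                         comp = rep(1L, length(circuit$cells)))
  rec <- as.integer(.gcomp(circuit, record$cell, record$comp))

  out <- simulate_circuit_cpp(circuit$comp, exc_list, inh_list, clamp_list,
                              inj_list, rec, unclass(stim),
                              attr(stim, "dt"), dt, as.integer(n_steps),
                              deterministic)
  structure(list(t = seq(0, duration, by = dt), v = out$v,
                 clamp_i = out$clamp_i, release_total = out$release_total,
                 record = record, dt = dt, duration = duration),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result: %d traces, %.0f ms at dt = %g ms, V in [%.1f, %.1f] mV>\n",
    nrow(x$v), x$duration, x$dt, min(x$v), max(x$v)))
  invisible(x)
}

#' @export
plot.simulation_result <- function(x, traces = seq_len(nrow(x$v)), ...) {
  graphics::matplot(x$t, t(x$v[traces, , drop = FALSE]), type = "l", lty = 1,
                    xlab = "time (ms)", ylab = "V (mV)", ...)
  invisible(x)
}

#' Voltage-clamp a compartment and return the clamp current trace
#'
#' The compartment is held exactly at `level` (ideal clamp); the returned
#' current is what must be injected to maintain it (positive = into the
#' cell).
#'
#' @param circuit a [build_circuit()] result.
#' @param cell,comp clamped compartment.
#' @param level holding potential, mV.
#' @param duration,dt,... passed to [simulate_circuit()].
#' @return clamp current trace, pA.
#' @export
voltage_clamp <- function(circuit, cell, comp, level, duration = 200,
                          dt = 0.025, ...) {
  circuit$clamps <- rbind(circuit$clamps,
                          data.frame(cell = cell, comp = comp, level = level))
  res <- simulate_circuit(circuit, duration = duration, dt = dt, ...)
  res$clamp_i[nrow(res$clamp_i), ]
}

#' Measure somatic input resistance from current steps
#'
#' Injects each current at the soma, reads the steady-state voltage
#' deflection, and returns the least-squares slope of deflection versus
#' current.
#'
#' @param cell a [make_cell()] object.
#' @param current_steps injected currents, pA (at least two distinct values).
#' @param duration step duration, ms; the last fifth is averaged as steady
#'   state.
#' @param dt integration step, ms.
#' @return input resistance, MOhm.
#' @export
measure_input_resistance <- function(cell, current_steps = c(-10, -5, 5, 10),
                                     duration = 300, dt = 0.025) {
  if (length(unique(current_steps)) < 2L)
    stop("need at least two distinct current amplitudes")
  dv <- vapply(current_steps, function(amp) {
    circ <- build_circuit(list(cell),
                          injections = data.frame(cell = 1L, comp = 1L,
                                                  amp_pa = amp, t0 = 0,
                                                  t1 = duration))
    res <- simulate_circuit(circ, duration = duration, dt = dt)
    tail_idx <- res$t >= duration * 0.8
    mean(res$v[1, tail_idx]) - cell$passive$resting_potential
  }, numeric(1))
  fit <- lm(dv ~ current_steps)
  slope <- coef(fit)[["current_steps"]]        # mV / pA = GOhm
  slope * 1000
}
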