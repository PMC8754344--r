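# ---------------------------------------------------------------------------
# Assay orchestration: single-SAC rings, SAC-network inhibition sweep, the
# SAC->DSGC moving-bar circuit, the paired voltage-clamp validation, and the
# stimulus-symmetry control.
# ---------------------------------------------------------------------------

# Per-compartment ring stimulus matrices (expanding + collapsing), compiled
# once and sliced per synapse table.  The heavy per-position evaluation is
# shared across genomes whose synapses sit on the same compartments.
precompile_ring_stim <- function(tree, soma_xy, duration = 1500,
                                 stim_dt = 1, field_size = c(315, 315),
                                 temporal_frequency = 2,
                                 spatial_period = 450) {
  pos <- cbind(tree$x, tree$y)
  mk <- function(kind) {
    spec <- ring_stimulus(kind, field_size = field_size,
                          field_origin = soma_xy - c(135, 125),
                          center = soma_xy,
                          temporal_frequency = temporal_frequency,
                          spatial_period = spatial_period,
                          duration = duration)
    compile_stimulus(spec, pos, dt = stim_dt)
  }
  list(expanding = mk("expanding_rings"), collapsing = mk("collapsing_rings"),
       time_c = 1000 / (2 * temporal_frequency), stim_dt = stim_dt)
}

slice_stim <- function(mat, rows) {
  structure(unclass(mat)[rows, , drop = FALSE], dt = attr(mat, "dt"),
            class = "intensity_matrix")
}

#' Single-SAC expanding/collapsing rings assay
#'
#' Places the bipolar-cell synapses defined by the genome on the cell,
#' presents expanding and collapsing rings centered on the soma (identical
#' release RNG streams for the two runs), and computes the centrifugal
#' selectivity (CSI) and rise-time (RTI) indices from the somatic voltage,
#' discarding the first stimulus cycle.
#'
#' @param g a [genome_params()].
#' @param morphology a `morphology`; default is the synthetic planar star
#'   SAC ([generate_star_sac()]).
#' @param passive a [passive_props()].
#' @param seed integer seed of the cell's placement/release stream.
#' @param duration stimulus duration, ms (1500).
#' @param dt integration step, ms (0.025).
#' @param stim_dt stimulus sampling step, ms (1).
#' @param kinetics_mode `"standard"`, `"reversed"` or `"fixed"`.
#' @param deterministic expected-value release and placement (noise-free).
#' @param soma_xy soma position in field coordinates, um.
#' @param field_size stimulation field, um (315 x 315).
#' @param record_dendrites additionally record this many dendritic sites
#'   (at ~80\% of the arbor extent).
#' @param comp_stim optional [precompile_ring_stim()] cache.
#' @param max_seg_len compartment length cap, um (7).
#' @return a `sac_assay` with csi, rti, the full metrics and both traces.
#' @export
run_single_sac_assay <- function(g, morphology = NULL,
                                 passive = passive_props(), seed = 1L,
                                 duration = 1500, dt = 0.025, stim_dt = 1,
                                 kinetics_mode = "standard",
                                 deterministic = FALSE,
                                 soma_xy = c(135, 125),
                                 field_size = c(315, 315),
                                 record_dendrites = 0L, comp_stim = NULL,
                                 max_seg_len = 7) {
  if (is.null(morphology)) morphology <- generate_star_sac()
  tree <- discretize(morphology, max_seg_len)
  cell <- make_cell(tree, passive, soma_xy, stream_seed = seed)
  exc <- attach_bc_synapses(1L, cell, g, kinetics_mode,
                            deterministic = deterministic)
  if (is.null(comp_stim))
    comp_stim <- precompile_ring_stim(cell$tree, soma_xy, duration, stim_dt,
                                      field_size)
  record <- data.frame(cell = 1L, comp = 1L)
  if (record_dendrites > 0L) {
    ext <- attr(tree, "max_extent")
    cand <- which(tree$path_dist >= 0.75 * ext & tree$path_dist <= 0.85 * ext)
    picks <- cand[round(seq(1, length(cand),
                            length.out = min(record_dendrites,
                                             length(cand))))]
    record <- rbind(record, data.frame(cell = 1L, comp = picks))
  }
  circ <- build_circuit(list(cell), exc_synapses = exc)
  run1 <- function(mat) simulate_circuit(
    circ, stim = slice_stim(mat, exc$comp), duration = duration, dt = dt,
    deterministic = deterministic, record = record)
  res_exp <- run1(comp_stim$expanding)
  res_col <- run1(comp_stim$collapsing)
  met <- ring_response_metrics(res_exp$v[1, ], res_col$v[1, ], dt,
                               comp_stim$time_c,
                               passive$resting_potential)
  dend <- NULL
  if (record_dendrites > 0L && nrow(record) > 1L) {
    dend <- lapply(2:nrow(record), function(k)
      ring_response_metrics(res_exp$v[k, ], res_col$v[k, ], dt,
                            comp_stim$time_c, passive$resting_potential))
  }
  structure(list(csi = met$csi, rti = met$rti, metrics = met,
                 objectives = ga_objectives(met), dendritic = dend,
                 v_exp = res_exp$v, v_col = res_col$v, t = res_exp$t,
                 genome = g, n_synapses = nrow(exc), record = record,
                 dt = dt, time_c = comp_stim$time_c),
            class = "sac_assay")
}

#' @export
print.sac_assay <- function(x, ...) {
  cat(sprintf("<sac_assay: CSI %.3f, RTI %.3f, %d synapses>\n",
              x$csi, x$rti, x$n_synapses))
  invisible(x)
}

#' Build the single-SAC rings evaluator used by the genetic search
#'
#' Precomputes the morphology, discretization and per-compartment stimulus
#' matrices once, so that evaluating a genome only places synapses and
#' integrates the cable equations.
#'
#' @param morphology,passive,seed,duration,dt,stim_dt,max_seg_len see
#'   [run_single_sac_assay()].
#' @param kinetics_mode input kinetics applied to every evaluation.
#' @return function `f(genome)` returning the [ga_objectives()] list.
#' @export
make_sac_evaluator <- function(morphology = NULL, passive = passive_props(),
                               seed = 1L, duration = 1500, dt = 0.025,
                               stim_dt = 1, kinetics_mode = "standard",
                               max_seg_len = 7) {
  if (is.null(morphology)) morphology <- generate_star_sac()
  tree <- discretize(morphology, max_seg_len)
  soma_xy <- c(135, 125)
  cell <- make_cell(tree, passive, soma_xy, stream_seed = seed)
  comp_stim <- precompile_ring_stim(cell$tree, soma_xy, duration, stim_dt)
  function(g) {
    exc <- attach_bc_synapses(1L, cell, g, kinetics_mode)
    if (nrow(exc) == 0L)
      return(list(obj1 = .ga_penalty, obj2 = .ga_penalty,
                  obj3 = .ga_penalty))
    circ <- build_circuit(list(cell), exc_synapses = exc)
    v_exp <- simulate_circuit(circ,
                              stim = slice_stim(comp_stim$expanding,
                                                exc$comp),
                              duration = duration, dt = dt)$v[1, ]
    v_col <- simulate_circuit(circ,
                              stim = slice_stim(comp_stim$collapsing,
                                                exc$comp),
                              duration = duration, dt = dt)$v[1, ]
    met <- ring_response_metrics(v_exp, v_col, dt, comp_stim$time_c,
                                 passive$resting_potential)
    ga_objectives(met)
  }
}

# clone one discretized morphology across a population layout; the cell
# flagged as recorded gets the bare assay seed so that, at zero coupling,
# its trace replays the single-cell assay bit-exactly
layout_cells <- function(layout, tree, passive, seed) {
  lapply(seq_len(nrow(layout)), function(i)
    make_cell(tree, passive, c(layout$x[i], layout$y[i]),
              stream_seed = if (layout$recorded[i]) seed
                            else seed + 1009L * i))
}

#' SAC-network rings assay with an inhibition-strength sweep
#'
#' Builds the 13-cell two-grid network of clones of one genome, wires
#' reciprocal GABA synapses at process intersections (release confined to
#' the distal third), and presents expanding/collapsing rings centered on
#' the central cell for each inhibition weight.  CSI and RTI of the central
#' cell are reported per weight; at weight 0 the network reproduces the
#' single-cell response exactly.
#'
#' @param g a [genome_params()].
#' @param inhibition_weights GABA conductances to sweep, nS.
#' @param layout a [build_sac_grid()] layout.
#' @param morphology,passive,seed,duration,dt,stim_dt,kinetics_mode,max_seg_len
#'   see [run_single_sac_assay()].
#' @param field_size stimulation field, um.
#' @return a `network_assay`: per-weight summary plus the central-cell
#'   traces.
#' @export
run_network_assay <- function(g, inhibition_weights = c(0, 0.005, 0.01,
                                                        0.05, 0.1, 1),
                              layout = build_sac_grid(), morphology = NULL,
                              passive = passive_props(), seed = 1L,
                              duration = 1500, dt = 0.025, stim_dt = 1,
                              kinetics_mode = "standard",
                              field_size = c(565, 565), max_seg_len = 7) {
  if (is.null(morphology)) morphology <- generate_star_sac()
  tree <- discretize(morphology, max_seg_len)
  cells <- layout_cells(layout, tree, passive, seed)
  central <- which(layout$recorded)
  exc <- do.call(rbind, lapply(seq_along(cells), function(i)
    attach_bc_synapses(i, cells[[i]], g, kinetics_mode)))
  center <- cells[[central]]$soma_xy
  mkstim <- function(kind) {
    spec <- ring_stimulus(kind, field_size = field_size,
                          field_origin = center - field_size / 2,
                          center = center, duration = duration)
    compile_stimulus(spec, cbind(exc$x, exc$y), dt = stim_dt)
  }
  stim_exp <- mkstim("expanding_rings")
  stim_col <- mkstim("collapsing_rings")
  contacts <- wire_sac_sac(cells, conductance = 1)
  record <- data.frame(cell = central, comp = 1L)
  time_c <- 250
  rows <- list(); traces <- list()
  for (w in inhibition_weights) {
    inh <- contacts
    inh$weight <- w
    circ <- build_circuit(cells, exc_synapses = exc, inh_synapses = inh)
    v_exp <- simulate_circuit(circ, stim = stim_exp, duration = duration,
                              dt = dt, record = record)$v[1, ]
    v_col <- simulate_circuit(circ, stim = stim_col, duration = duration,
                              dt = dt, record = record)$v[1, ]
    met <- ring_response_metrics(v_exp, v_col, dt, time_c,
                                 passive$resting_potential)
    rows[[length(rows) + 1L]] <-
      data.frame(weight = w, csi = met$csi, rti = met$rti,
                 amp_exp = met$amp_exp, amp_col = met$amp_col,
                 rt_exp = met$rt_exp, rt_col = met$rt_col)
    traces[[as.character(w)]] <- list(v_exp = v_exp, v_col = v_col)
  }
  structure(list(summary = do.call(rbind, rows), traces = traces,
                 n_contacts = nrow(contacts), central = central,
                 genome = g, dt = dt, seed = seed),
            class = "network_assay")
}

#' @export
print.network_assay <- function(x, ...) {
  cat(sprintf("<network_assay: %d GABA contacts; central cell %d>\n",
              x$n_contacts, x$central))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' SAC-network / DSGC moving-bar assay
#'
#' Embeds a ganglion cell in the 13-SAC network, wires SAC-to-DSGC GABA
#' synapses either by the antiparallel (null-side) rule or at random, and
#' presents a bar sweeping twice in each direction (preferred first).  The
#' first preferred/null pair is excluded; DSI and PD activation are computed
#' from the second pair of sweeps of the DSGC somatic voltage.
#'
#' @param g a [genome_params()] (drives the bipolar input of SACs and of
#'   the DSGC).
#' @param mode SAC-DSGC connectivity: `"asymmetric"` or `"random"`.
#' @param sac_sac_weight reciprocal SAC inhibition, nS (0 or 0.1).
#' @param noise logical, or a [flicker_noise_spec()]: flickering-spot
#'   background.
#' @param preferred_direction DSGC preferred direction (unit planar vector).
#' @param dsgc_morphology default [generate_star_dsgc()].
#' @param sac_dsgc_weight SAC-DSGC conductance, nS (0.5).
#' @param dsgc_resting DSGC resting potential, mV (-52).
#' @param layout,morphology,passive,seed,dt,stim_dt,kinetics_mode,max_seg_len
#'   see [run_network_assay()].
#' @param bar geometry list: length, width, velocity (um/s), x_perimeter.
#' @return a `dsgc_assay` with dsi, pd_activation and the DSGC trace.
#' @export
run_dsgc_assay <- function(g, mode = c("asymmetric", "random"),
                           sac_sac_weight = 0.1, noise = FALSE,
                           preferred_direction = c(1, 0),
                           dsgc_morphology = NULL,
                           sac_dsgc_weight = 0.5, dsgc_resting = -52,
                           layout = build_sac_grid(), morphology = NULL,
                           passive = passive_props(), seed = 1L,
                           dt = 0.025, stim_dt = 1,
                           kinetics_mode = "standard", max_seg_len = 7,
                           bar = list(length = 250, width = 600,
                                      velocity = 1000, x_perimeter = 500)) {
  mode <- match.arg(mode)
  if (is.null(morphology)) morphology <- generate_star_sac()
  if (is.null(dsgc_morphology)) dsgc_morphology <- generate_star_dsgc()
  tree <- discretize(morphology, max_seg_len)
  sac_cells <- layout_cells(layout, tree, passive, seed)
  central <- which(layout$recorded)
  center <- sac_cells[[central]]$soma_xy
  dsgc_passive <- passive
  dsgc_passive$resting_potential <- dsgc_resting
  dsgc <- make_cell(discretize(dsgc_morphology, max_seg_len), dsgc_passive,
                    center, stream_seed = seed + 999983L)
  cells <- c(sac_cells, list(dsgc))
  n_sac <- length(sac_cells)
  exc <- rbind(
    do.call(rbind, lapply(seq_len(n_sac), function(i)
      attach_bc_synapses(i, cells[[i]], g, kinetics_mode))),
    attach_bc_synapses(n_sac + 1L, dsgc, g, kinetics_mode))
  inh <- rbind(
    wire_sac_sac(sac_cells, conductance = sac_sac_weight),
    wire_sac_dsgc(sac_cells, dsgc, preferred_direction,
                  conductance = sac_dsgc_weight, rng_seed = seed + 77L,
                  mode = mode, dsgc_cell_index = n_sac + 1L))
  sweep_ms <- 1000 * (bar$x_perimeter + bar$length) / bar$velocity
  duration <- 4 * sweep_ms                    # PD, ND, PD, ND
  noise_spec <- if (isTRUE(noise)) flicker_noise_spec(rng_seed = seed * 13L +
                                                        1L)
                else if (inherits(noise, "flicker_noise_spec")) noise
  spec <- bar_stimulus(bar_length = bar$length, bar_width = bar$width,
                       velocity = bar$velocity,
                       x_perimeter = bar$x_perimeter, center = center,
                       first_direction = sign(preferred_direction[1]),
                       duration = duration, noise = noise_spec)
  stim <- compile_stimulus(spec, cbind(exc$x, exc$y), dt = stim_dt)
  circ <- build_circuit(cells, exc_synapses = exc, inh_synapses = inh)
  record <- data.frame(cell = c(n_sac + 1L, central), comp = 1L)
  res <- simulate_circuit(circ, stim = stim, duration = duration, dt = dt,
                          record = record)
  v <- res$v[1, ]
  per_sweep <- round(sweep_ms / dt)
  seg <- function(k) v[(k - 1L) * per_sweep + seq_len(per_sweep)]
  v_pd <- seg(3L); v_nd <- seg(4L)
  thr <- min(v) + 11
  structure(list(dsi = dsi(v_pd, v_nd, dt, reference = -60),
                 pd_activation = pd_activation(v_pd, thr, dt),
                 threshold = thr, v_dsgc = v, v_sac = res$v[2, ],
                 t = res$t, v_pd = v_pd, v_nd = v_nd, mode = mode,
                 sac_sac_weight = sac_sac_weight,
                 noise = !is.null(noise_spec),
                 n_sac_dsgc = sum(inh$post_cell == n_sac + 1L), dt = dt),
            class = "dsgc_assay")
}

#' @export
print.dsgc_assay <- function(x, ...) {
  cat(sprintf(
    "<dsgc_assay: %s wiring, SAC-SAC %.3g nS, noise %s; DSI %.3f, PD activation %.1f mV ms>\n",
    x$mode, x$sac_sac_weight, x$noise, x$dsi, x$pd_activation))
  invisible(x)
}

#' Paired voltage-clamp validation of the SAC-SAC GABA synapse
#'
#' For neighboring SAC pairs of the network layout, the presynaptic soma is
#' clamped to -40 mV (above the -50 mV release threshold, driving 200 Hz
#' GABA trains at the distal contacts) and the postsynaptic soma to -5 mV;
#' the steady current required to hold the postsynaptic clamp is collected
#' across pairs.
#'
#' @param conductance GABA conductance per contact, nS (0.1).
#' @param pre_level,post_level holding potentials, mV.
#' @param layout,morphology,passive,max_seg_len network geometry.
#' @param n_pairs number of neighboring pairs to test.
#' @param duration,dt simulation control, ms; the last quarter is averaged.
#' @return list with mean, sd and per-pair steady clamp currents (pA).
#' @export
run_paired_clamp_validation <- function(conductance = 0.1, pre_level = -40,
                                        post_level = -5,
                                        layout = build_sac_grid(),
                                        morphology = NULL,
                                        passive = passive_props(),
                                        n_pairs = 6L, duration = 400,
                                        dt = 0.025, max_seg_len = 7) {
  if (is.null(morphology)) morphology <- generate_star_sac()
  tree <- discretize(morphology, max_seg_len)
  cells <- layout_cells(layout, tree, passive, seed = 1L)
  pr <- t(utils::combn(nrow(layout), 2L))
  d <- sqrt((layout$x[pr[, 1]] - layout$x[pr[, 2]])^2 +
              (layout$y[pr[, 1]] - layout$y[pr[, 2]])^2)
  keep <- order(d)[seq_len(min(n_pairs, sum(d < 2 * attr(tree,
                                                         "max_extent"))))]
  cur <- vapply(keep, function(k) {
    pair <- list(cells[[pr[k, 1]]], cells[[pr[k, 2]]])
    inh <- wire_sac_sac(pair, conductance)
    inh <- inh[inh$pre_cell == 1L, , drop = FALSE]   # pre -> post only
    circ <- build_circuit(pair, inh_synapses = inh,
                          clamps = data.frame(cell = c(1L, 2L), comp = 1L,
                                              level = c(pre_level,
                                                        post_level)))
    res <- simulate_circuit(circ, duration = duration, dt = dt)
    mean(res$clamp_i[2L, res$t >= duration * 0.75])
  }, numeric(1))
  list(mean = mean(cur), sd = sd(cur), per_pair = cur,
       n_pairs = length(cur))
}

#' Stimulus-symmetry control: left vs right bars on a symmetric SAC
#'
#' Runs the alternating-bar assay twice on a rotationally symmetric star
#' SAC with distance-uniform input kinetics, deterministic release and
#' deterministic synapse placement, starting once towards +x and once
#' towards -x.  For an even number of primary processes the two runs are
#' related by a 180-degree rotation, so the direction-selectivity index of
#' the post-first-cycle responses must vanish.
#'
#' @param g genome; the default has distance-independent kinetics
#'   (`release_probability = 0` with a nonzero baseline).
#' @param morphology even-armed star SAC.
#' @param passive,dt,stim_dt,max_seg_len simulation control.
#' @param bar bar geometry as in [run_dsgc_assay()].
#' @return list with the DSI between the two runs and both traces.
#' @export
run_bar_symmetry_control <- function(g = genome_params(
                                       refilling_rate = 1,
                                       release_probability = 0,
                                       k_transition_start_point = 0.08),
                                     morphology = generate_star_sac(),
                                     passive = passive_props(), dt = 0.025,
                                     stim_dt = 1, max_seg_len = 7,
                                     bar = list(length = 250, width = 600,
                                                velocity = 1000,
                                                x_perimeter = 500)) {
  tree <- discretize(morphology, max_seg_len)
  cell <- make_cell(tree, passive, c(0, 0), stream_seed = 1L)
  exc <- attach_bc_synapses(1L, cell, g, kinetics_mode = "fixed",
                            deterministic = TRUE)
  circ <- build_circuit(list(cell), exc_synapses = exc)
  sweep_ms <- 1000 * (bar$x_perimeter + bar$length) / bar$velocity
  duration <- 4 * sweep_ms
  run_dir <- function(dir) {
    spec <- bar_stimulus(bar_length = bar$length, bar_width = bar$width,
                         velocity = bar$velocity,
                         x_perimeter = bar$x_perimeter, center = c(0, 0),
                         first_direction = dir, duration = duration)
    stim <- compile_stimulus(spec, cbind(exc$x, exc$y), dt = stim_dt)
    simulate_circuit(circ, stim = stim, duration = duration, dt = dt,
                     deterministic = TRUE)$v[1, ]
  }
  v_right <- run_dir(1); v_left <- run_dir(-1)
  half <- (length(v_right) - 1L) %/% 2L
  win <- (half + 1L):length(v_right)          # exclude the first cycle
  list(dsi = dsi(v_right[win], v_left[win], dt,
                 reference = passive$resting_potential),
       v_right = v_right, v_left = v_left, dt = dt)
}
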