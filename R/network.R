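# ---------------------------------------------------------------------------
# Population layout, process-intersection detection, and the retina-specific
# synapse placement rules: distance-dependent bipolar-cell input density,
# distal SAC-SAC GABA release sites, and the antiparallel SAC->DSGC rule.
# ---------------------------------------------------------------------------

#' Two-grid SAC population layout
#'
#' A 3x3 grid with the bottom-left soma at (0, 0) and 125 um spacing,
#' overlaid with a 2x2 grid cornered at (62, 67): 13 cells in total.  The
#' central cell of the 3x3 grid is flagged as the recorded cell.
#'
#' @param nx,ny first-grid dimensions.
#' @param spacing soma spacing, um.
#' @param origin bottom-left soma of the first grid, um.
#' @param second_dims second-grid dimensions (`c(0, 0)` to omit it).
#' @param second_origin bottom-left soma of the second grid, um.
#' @return a `population_layout` data frame: cell, x, y, layer, recorded.
#' @export
build_sac_grid <- function(nx = 3L, ny = 3L, spacing = 125,
                           origin = c(0, 0), second_dims = c(2L, 2L),
                           second_origin = c(62, 67)) {
  g1 <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  layout <- data.frame(x = origin[1] + g1$ix * spacing,
                       y = origin[2] + g1$iy * spacing, layer = 0L)
  if (all(second_dims > 0)) {
    g2 <- expand.grid(ix = seq_len(second_dims[1]) - 1L,
                      iy = seq_len(second_dims[2]) - 1L)
    layout <- rbind(layout,
                    data.frame(x = second_origin[1] + g2$ix * spacing,
                               y = second_origin[2] + g2$iy * spacing,
                               layer = 1L))
  }
  if (anyDuplicated(layout[, c("x", "y")])) stop("soma positions collide")
  layout$cell <- seq_len(nrow(layout))
  center <- c(origin[1] + (nx - 1L) / 2 * spacing,
              origin[2] + (ny - 1L) / 2 * spacing)
  d2 <- (layout$x - center[1])^2 + (layout$y - center[2])^2
  layout$recorded <- seq_len(nrow(layout)) == which.min(d2)
  structure(layout[, c("cell", "x", "y", "layer", "recorded")],
            class = c("population_layout", "data.frame"))
}

#' Bipolar-cell synapse density along a SAC process
#'
#' `density(x) = max(1 - (scaling_factor * 0.5 * (1 + tanh(x -
#' anatomical_transition_point)) + offset), 0)` synapses per um, so the
#' proximal density is `1 - offset` and the distal limit is
#' `1 - (scaling_factor + offset)`.
#'
#' @param x path distance from the soma, um (vectorized).
#' @param g a [genome_params()].
#' @param width sigmoid width, um (1: the tanh argument is raw distance).
#' @return synapse density per um.
#' @export
bc_density <- function(x, g, width = 1) {
  pmax(1 - (g$scaling_factor * 0.5 *
              (1 + tanh((x - g$anatomical_transition_point) / width)) +
              g$offset), 0)
}

#' Place bipolar-cell synapses on a compartment tree
#'
#' Synapses are drawn as a Poisson process along arc length at the
#' [bc_density()] rate (one draw per compartment with mean density times
#' compartment length).  In deterministic mode each compartment instead
#' carries a single synapse instance whose conductance is scaled by the
#' expected count, which removes placement noise.
#'
#' @param tree a `compartment_tree`.
#' @param g a [genome_params()].
#' @param rng_seed placement seed (the caller's RNG state is untouched).
#' @param deterministic expected-count placement (no sampling).
#' @param width sigmoid width passed to [bc_density()].
#' @return data frame: comp, x, y, d (path distance, um), mult.
#' @export
place_bc_synapses <- function(tree, g, rng_seed = 1L, deterministic = FALSE,
                              width = 1) {
  stopifnot(inherits(tree, "compartment_tree"))
  dend <- which(!tree$is_soma)
  lambda <- bc_density(tree$path_dist[dend], g, width) * tree$length[dend]
  if (deterministic) {
    keep <- lambda > 0
    idx <- dend[keep]
    return(data.frame(comp = idx, x = tree$x[idx], y = tree$y[idx],
                      d = tree$path_dist[idx], mult = lambda[keep]))
  }
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(rng_seed)
  counts <- rpois(length(dend), lambda)
  idx <- rep(dend, counts)
  data.frame(comp = idx, x = tree$x[idx], y = tree$y[idx],
             d = tree$path_dist[idx], mult = rep(1, length(idx)))
}

#' Build the excitatory synapse table of a cell
#'
#' Combines [place_bc_synapses()] with the distance-dependent kinetics of
#' [release_prob_at()] / [refill_rate_at()] into the table consumed by
#' [build_circuit()].
#'
#' @param cell_index index of the cell within the circuit's cell list.
#' @param cell a [make_cell()] object (placement uses its stream seed).
#' @param g a [genome_params()].
#' @param kinetics_mode `"standard"`, `"reversed"` or `"fixed"`.
#' @param extent dendritic extent for the reversed transform, um; defaults
#'   to the tree's maximal path distance.
#' @param deterministic expected-count placement.
#' @return an excitatory synapse data frame.
#' @export
attach_bc_synapses <- function(cell_index, cell, g,
                               kinetics_mode = "standard", extent = NULL,
                               deterministic = FALSE) {
  tree <- cell$tree
  if (is.null(extent)) extent <- attr(tree, "max_extent")
  placed <- place_bc_synapses(tree, g, rng_seed = cell$stream_seed,
                              deterministic = deterministic)
  if (nrow(placed) == 0L) return(empty_exc())
  data.frame(cell = cell_index, comp = placed$comp, x = placed$x,
             y = placed$y, d = placed$d,
             pfac = release_prob_at(placed$d, g, 1, kinetics_mode, extent),
             refill = refill_rate_at(placed$d, g, kinetics_mode, extent),
             weight = g$synaptic_conductance, mult = placed$mult)
}

#' Find planar intersections between the processes of two cells
#'
#' All compartment pairs whose x-y distance is at most `threshold`.  By
#' default, pairs lying on the same (pre-section, post-section) branch pair
#' are collapsed to the single closest pair, so contact counts do not
#' inflate with finer discretization.
#'
#' @param pre,post `compartment_tree`s (in shared network coordinates).
#' @param threshold maximal planar distance, um (5).
#' @param dedupe collapse per branch pair to the closest compartment pair.
#' @return data frame: pre_comp, post_comp, dist.
#' @export
find_intersections <- function(pre, post, threshold = 5, dedupe = TRUE) {
  stopifnot(threshold > 0)
  pi_ <- which(!pre$is_soma); po <- which(!post$is_soma)
  dx <- outer(pre$x[pi_], post$x[po], "-")
  dy <- outer(pre$y[pi_], post$y[po], "-")
  d <- sqrt(dx^2 + dy^2)
  hit <- which(d <= threshold, arr.ind = TRUE)
  out <- data.frame(pre_comp = pi_[hit[, 1]], post_comp = po[hit[, 2]],
                    dist = d[hit])
  if (dedupe && nrow(out) > 0) {
    key <- paste(pre$section[out$pre_comp], post$section[out$post_comp])
    out <- do.call(rbind, lapply(split(out, key),
                                 function(b) b[which.min(b$dist), ]))
    rownames(out) <- NULL
  }
  out[order(out$pre_comp, out$post_comp), , drop = FALSE]
}

#' Wire reciprocal SAC-SAC GABA synapses
#'
#' GABA synapses are created at process intersections whose presynaptic
#' compartment lies in the distal `distal_fraction` of the presynaptic
#' arbor (SAC release sites are confined to the distal third of the
#' process).
#'
#' @param cells list of [make_cell()] SACs (network coordinates).
#' @param conductance synaptic conductance, nS (0 gives an uncoupled
#'   network).
#' @param distal_fraction release-site fraction of the arbor (1/3).
#' @param threshold intersection threshold, um (5).
#' @param e_rev GABA reversal potential, mV (-75).
#' @param max_soma_dist only cell pairs closer than this are tested, um.
#' @return an inhibitory synapse data frame for [build_circuit()].
#' @export
wire_sac_sac <- function(cells, conductance, distal_fraction = 1 / 3,
                         threshold = 5, e_rev = -75, max_soma_dist = NULL) {
  stopifnot(conductance >= 0, distal_fraction >= 0, distal_fraction <= 1)
  out <- empty_inh()
  n <- length(cells)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    si <- cells[[i]]$soma_xy; sj <- cells[[j]]$soma_xy
    ext_i <- attr(cells[[i]]$tree, "max_extent")
    reach <- ext_i + attr(cells[[j]]$tree, "max_extent") + threshold
    if (!is.null(max_soma_dist)) reach <- min(reach, max_soma_dist)
    if (sqrt(sum((si - sj)^2)) > reach) next
    hits <- find_intersections(cells[[i]]$tree, cells[[j]]$tree, threshold)
    if (nrow(hits) == 0L) next
    distal <- cells[[i]]$tree$path_dist[hits$pre_comp] >
      (1 - distal_fraction) * ext_i
    hits <- hits[distal, , drop = FALSE]
    if (nrow(hits) == 0L) next
    out <- rbind(out, data.frame(pre_cell = i, pre_comp = hits$pre_comp,
                                 post_cell = j, post_comp = hits$post_comp,
                                 weight = conductance, e_rev = e_rev))
  }
  out
}

#' Wire asymmetric SAC-to-DSGC GABA synapses
#'
#' For each SAC/DSGC process intersection, the SAC process direction `u`
#' (contact site relative to the SAC soma) is compared with the DSGC's
#' preferred direction: the synapse is accepted with probability
#' `arccos(u . PD) / pi` (0 for parallel, 1 for antiparallel), implementing
#' null-side wiring.  Random mode accepts every contact with probability
#' 0.5.
#'
#' @param sac_cells list of [make_cell()] SACs.
#' @param dsgc a [make_cell()] DSGC in the same coordinates.
#' @param preferred_direction unit planar vector, the DSGC's PD.
#' @param conductance synaptic conductance, nS (0.5).
#' @param rng_seed acceptance-draw seed.
#' @param mode `"asymmetric"` or `"random"`.
#' @param prob_form `"arccos"` (literal inverse cosine over pi) or
#'   `"half_cosine"` (`(1 - cos) / 2`); both are monotone in the angle.
#' @param threshold intersection threshold, um (5).
#' @param e_rev reversal potential, mV (-60).
#' @param distal_fraction SAC release sites are confined to this distal
#'   fraction of the SAC arbor (1/3, as for SAC-SAC synapses).
#' @param dsgc_cell_index index the DSGC will have in the circuit cell list.
#' @return an inhibitory synapse data frame (pre cells indexed as in
#'   `sac_cells`).
#' @export
wire_sac_dsgc <- function(sac_cells, dsgc, preferred_direction,
                          conductance = 0.5, rng_seed = 1L,
                          mode = c("asymmetric", "random"),
                          prob_form = c("arccos", "half_cosine"),
                          threshold = 5, e_rev = -60, distal_fraction = 1 / 3,
                          dsgc_cell_index = length(sac_cells) + 1L) {
  mode <- match.arg(mode)
  prob_form <- match.arg(prob_form)
  pd <- preferred_direction / sqrt(sum(preferred_direction^2))
  out <- empty_inh()
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(rng_seed)
  for (i in seq_along(sac_cells)) {
    sac <- sac_cells[[i]]
    hits <- find_intersections(sac$tree, dsgc$tree, threshold)
    ext <- attr(sac$tree, "max_extent")
    hits <- hits[sac$tree$path_dist[hits$pre_comp] >
                   (1 - distal_fraction) * ext, , drop = FALSE]
    if (nrow(hits) == 0L) next
    p_acc <- if (mode == "random") rep(0.5, nrow(hits)) else {
      ux <- sac$tree$x[hits$pre_comp] - sac$soma_xy[1]
      uy <- sac$tree$y[hits$pre_comp] - sac$soma_xy[2]
      nn <- pmax(sqrt(ux^2 + uy^2), 1e-12)
      cs <- pmin(pmax((ux * pd[1] + uy * pd[2]) / nn, -1), 1)
      if (prob_form == "arccos") acos(cs) / pi else (1 - cs) / 2
    }
    keep <- runif(nrow(hits)) < p_acc
    if (!any(keep)) next
    out <- rbind(out,
                 data.frame(pre_cell = i, pre_comp = hits$pre_comp[keep],
                            post_cell = dsgc_cell_index,
                            post_comp = hits$post_comp[keep],
                            weight = conductance, e_rev = e_rev))
  }
  out
}

#' Contact-acceptance probability of the antiparallel wiring rule
#'
#' @param u SAC process direction (planar vector, need not be unit).
#' @param pd DSGC preferred direction.
#' @param prob_form `"arccos"` or `"half_cosine"`.
#' @return acceptance probability in \[0, 1\].
#' @export
sac_dsgc_acceptance <- function(u, pd, prob_form = c("arccos",
                                                     "half_cosine")) {
  prob_form <- match.arg(prob_form)
  cs <- sum(u * pd) / sqrt(sum(u^2) * sum(pd^2))
  cs <- min(max(cs, -1), 1)
  if (prob_form == "arccos") acos(cs) / pi else (1 - cs) / 2
}

#' Per-contact conductance from a total pairwise conductance
#'
#' Divides a measured total synaptic conductance between a connected cell
#' pair by the assumed number of anatomical contacts, giving the conductance
#' assigned to each synapse instance (e.g. 9 nS over ~14 SAC-DSGC contacts
#' gives ~0.6 nS per contact).
#'
#' @param total_ns total pairwise conductance, nS.
#' @param n_contacts assumed contact count.
#' @return per-contact conductance, nS.
#' @export
per_contact_conductance <- function(total_ns, n_contacts) {
  stopifnot(total_ns >= 0, n_contacts >= 1)
  total_ns / n_contacts
}
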