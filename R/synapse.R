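# ---------------------------------------------------------------------------
# Bipolar-cell -> SAC stochastic ribbon synapse, double-exponential
# conductance kernels, voltage-gated GABA event trains, and the
# sustained-transient index (STI) machinery.
# ---------------------------------------------------------------------------

#' Synaptic genome: the 8 parameters of the excitatory input architecture
#'
#' The distribution and kinetics of bipolar-cell inputs onto a SAC are
#' governed by eight parameters.  Three shape the synapse density along the
#' processes (`scaling_factor`, `anatomical_transition_point`, `offset`);
#' four shape the release kinetics as a function of distance from the soma
#' (`refilling_rate`, `release_probability`, `k_transition_start_point`,
#' `k_transition_end_point`); the eighth is the per-synapse peak conductance.
#' Defaults are an example centrifugal-preferring parameter set.
#'
#' @param refilling_rate vesicle pool refill rate, vesicles per ms.
#' @param release_probability slope of the per-time-step release probability
#'   with normalized distance.
#' @param k_transition_start_point baseline release probability and the
#'   fractional distance at which the refill rate starts to drop.
#' @param k_transition_end_point distance (um) beyond which kinetics stay at
#'   their most transient value (symbol m).
#' @param synaptic_conductance peak conductance per vesicle event, nS.
#' @param anatomical_transition_point center of the density sigmoid, um.
#' @param scaling_factor drop of synapse density across the sigmoid.
#' @param offset distal density complement; distal density is
#'   `1 - (scaling_factor + offset)`.
#' @return a `genome_params` object.
#' @export
genome_params <- function(refilling_rate = 3.7, release_probability = 0.08,
                          k_transition_start_point = 0,
                          k_transition_end_point = 135,
                          synaptic_conductance = 0.0025,
                          anatomical_transition_point = 102,
                          scaling_factor = 0.254, offset = 0.6144) {
  g <- list(refilling_rate = refilling_rate,
            release_probability = release_probability,
            k_transition_start_point = k_transition_start_point,
            k_transition_end_point = k_transition_end_point,
            synaptic_conductance = synaptic_conductance,
            anatomical_transition_point = anatomical_transition_point,
            scaling_factor = scaling_factor, offset = offset)
  if (any(vapply(g, length, integer(1)) != 1L) || any(!is.finite(unlist(g))))
    stop("genome parameters must be finite scalars")
  if (g$k_transition_end_point <= 0)
    stop("k_transition_end_point must be positive")
  if (g$refilling_rate < 0 || g$release_probability < 0 ||
      g$synaptic_conductance < 0 || g$k_transition_start_point < 0)
    stop("genome parameters must be non-negative")
  structure(g, class = "genome_params")
}

#' @export
print.genome_params <- function(x, ...) {
  cat("<genome_params>\n")
  for (nm in names(x)) cat(sprintf("  %-28s %g\n", nm, x[[nm]]))
  invisible(x)
}

# distance transform shared by the kinetics rules
.kinetic_distance <- function(d, extent, kinetics_mode) {
  switch(kinetics_mode,
         standard = d,
         reversed = extent - d,
         fixed = rep(0, length(d)),
         stop("unknown kinetics mode: ", kinetics_mode))
}

#' Per-time-step vesicle release probability at a dendritic location
#'
#' `p = min(k_transition_start_point + release_probability * min(d, m) / m,
#' 1) * v_intensity` with `m = k_transition_end_point`; beyond `m` the (most
#' transient) kinetics stay constant.  Reversed mode substitutes
#' `d -> extent - d`; fixed mode freezes the kinetics at their somatic value.
#'
#' @param d path distance of the synapse from the soma, um (vectorized).
#' @param g a [genome_params()].
#' @param v_intensity visual input intensity in \[0, 1\].
#' @param kinetics_mode `"standard"`, `"reversed"` or `"fixed"`.
#' @param extent dendritic extent used by reversed mode, um.
#' @return release probability per time step.
#' @export
release_prob_at <- function(d, g, v_intensity = 1,
                            kinetics_mode = "standard", extent = 210) {
  if (g$k_transition_end_point == 0) stop("k_transition_end_point is zero")
  if (any(d < 0)) stop("distance must be non-negative")
  d <- .kinetic_distance(d, extent, kinetics_mode)
  m <- g$k_transition_end_point
  u <- pmin(d, m) / m
  pmin(g$k_transition_start_point + g$release_probability * u, 1) * v_intensity
}

#' Vesicle pool refill rate at a dendritic location
#'
#' With `u = min(d, m) / m`: the full `refilling_rate` applies while
#' `k_transition_start_point > u` (proximal); beyond that the rate declines
#' as `k_transition_start_point * refilling_rate + refilling_rate * (1 - u)`.
#'
#' @inheritParams release_prob_at
#' @return refill rate, vesicles per ms.
#' @export
refill_rate_at <- function(d, g, kinetics_mode = "standard", extent = 210) {
  if (g$k_transition_end_point == 0) stop("k_transition_end_point is zero")
  if (any(d < 0)) stop("distance must be non-negative")
  d <- .kinetic_distance(d, extent, kinetics_mode)
  m <- g$k_transition_end_point
  u <- pmin(d, m) / m
  ifelse(g$k_transition_start_point > u,
         g$refilling_rate,
         g$k_transition_start_point * g$refilling_rate +
           g$refilling_rate * (1 - u))
}

#' Initialize a ribbon synapse state
#'
#' @param pool_max readily releasable pool capacity (70 vesicles).
#' @return a `ribbon_state` with a full pool.
#' @export
ribbon_state <- function(pool_max = 70) {
  structure(list(pool = pool_max, pool_max = pool_max), class = "ribbon_state")
}

#' Advance a ribbon synapse by one time step
#'
#' Draws `released ~ Binomial(floor(pool), p)` (or the expected value
#' `pool * p` in deterministic mode), decrements the pool, then refills it by
#' `r * dt` capped at the pool capacity.  Uses R's RNG, so `set.seed()`
#' controls reproducibility.
#'
#' @param state a [ribbon_state()].
#' @param p release probability for this step (0..1).
#' @param r refill rate, vesicles per ms.
#' @param dt step, ms.
#' @param deterministic if TRUE, release the expected value instead of a
#'   binomial draw.
#' @return `list(state, released)`.
#' @export
step_ribbon <- function(state, p, r, dt, deterministic = FALSE) {
  stopifnot(inherits(state, "ribbon_state"), p >= 0, p <= 1)
  released <- if (deterministic) state$pool * p
              else rbinom(1L, floor(state$pool), p)
  state$pool <- min(state$pool - released + r * dt, state$pool_max)
  list(state = state, released = released)
}

#' Reset a ribbon synapse pool (light-to-dark transition)
#'
#' @param state a [ribbon_state()].
#' @return the state with a full pool.
#' @export
reset_ribbon <- function(state) {
  state$pool <- state$pool_max
  state
}

#' Double-exponential conductance kernel
#'
#' @param tau_rise,tau_decay rise and decay time constants, ms
#'   (`tau_decay > tau_rise > 0`).
#' @param reversal reversal potential, mV.
#' @param weight peak conductance, nS.
#' @return a `conductance_kernel`.
#' @export
conductance_kernel <- function(tau_rise, tau_decay, reversal, weight) {
  if (!(tau_decay > tau_rise) || tau_rise <= 0)
    stop("requires tau_decay > tau_rise > 0")
  structure(list(tau_rise = tau_rise, tau_decay = tau_decay,
                 reversal = reversal, weight = weight),
            class = "conductance_kernel")
}

# default kernels used throughout: fast AMPA-like bipolar input; slow GABA
bipolar_kernel <- function(weight)
  conductance_kernel(0.89, 1.84, 0, weight)
gaba_kernel <- function(weight, reversal = -75)
  conductance_kernel(3, 30, reversal, weight)

#' Evaluate a conductance kernel at a time since the event
#'
#' `g(t) = weight * N * (exp(-t / tau_decay) - exp(-t / tau_rise))`, with `N`
#' normalizing the peak to `weight`.  Events superpose linearly.
#'
#' @param t_since_event time since the release event, ms (vectorized).
#' @param k a [conductance_kernel()].
#' @return conductance, nS.
#' @export
kernel_conductance <- function(t_since_event, k) {
  stopifnot(inherits(k, "conductance_kernel"), all(t_since_event >= 0))
  tp <- kernel_peak_time(k)
  N <- 1 / (exp(-tp / k$tau_decay) - exp(-tp / k$tau_rise))
  k$weight * N * (exp(-t_since_event / k$tau_decay) -
                    exp(-t_since_event / k$tau_rise))
}

#' Time of the kernel peak
#'
#' Closed form: `tau_rise * tau_decay / (tau_decay - tau_rise) *
#' log(tau_decay / tau_rise)`.
#'
#' @param k a [conductance_kernel()].
#' @return peak time, ms.
#' @export
kernel_peak_time <- function(k) {
  k$tau_rise * k$tau_decay / (k$tau_decay - k$tau_rise) *
    log(k$tau_decay / k$tau_rise)
}

#' GABA release event times from a presynaptic voltage trace
#'
#' While the presynaptic voltage exceeds `threshold` the synapse fires at
#' `rate`; the event phase restarts at each suprathreshold crossing, and
#' events are snapped to the sampling grid.
#'
#' @param v presynaptic voltage trace, mV, sampled at `dt`.
#' @param dt sampling interval, ms.
#' @param threshold activation threshold, mV (-50 mV default).
#' @param rate event rate while active, Hz (200 Hz default).
#' @return event times in ms (possibly empty).
#' @export
gaba_event_times <- function(v, dt, threshold = -50, rate = 200) {
  stopifnot(rate > 0)
  period <- 1000 / rate
  events <- numeric(0)
  active <- FALSE
  timer <- 0
  for (i in seq_along(v)) {
    t <- (i - 1) * dt
    if (v[i] > threshold) {
      if (!active) {
        active <- TRUE
        timer <- 0
        events <- c(events, t)
      } else {
        timer <- timer + dt
        while (timer >= period - 1e-9) {
          timer <- timer - period
          events <- c(events, t)
        }
      }
    } else {
      active <- FALSE
    }
  }
  events
}

#' Sustained-transient index from an averaged PSTH
#'
#' `STI = steady_state / peak`, with the peak taken as the first bin after
#' stimulation start and the steady state as the last bin.  1 indicates a
#' completely sustained input, 0 a completely transient one.
#'
#' @param psth averaged peristimulus time histogram (vesicles per bin).
#' @return the STI, or `NA` if the peak bin is empty.
#' @export
sti_from_psth <- function(psth) {
  if (length(psth) < 2L) stop("PSTH needs at least two bins")
  peak <- psth[1L]
  if (peak == 0) return(NA_real_)
  psth[length(psth)] / peak
}

#' Sustained-transient index of a ribbon synapse
#'
#' Simulates the stochastic vesicle release for 250 ms under full
#' illumination, averages the PSTH (10 ms bins) over `reps` repetitions and
#' returns [sti_from_psth()] of the result.
#'
#' @param p release probability per time step.
#' @param r refill rate, vesicles per ms.
#' @param dt integration step, ms.
#' @param duration simulated time, ms.
#' @param reps number of repetitions averaged (50).
#' @param bin_ms PSTH bin width, ms.
#' @param pool_max vesicle pool capacity.
#' @param seed RNG seed for the release draws.
#' @param deterministic expected-value release (no noise).
#' @return the STI.
#' @export
compute_sti <- function(p, r, dt = 0.025, duration = 250, reps = 50,
                        bin_ms = 10, pool_max = 70, seed = 1L,
                        deterministic = FALSE) {
  stopifnot(p >= 0, p <= 1, r >= 0)
  psth <- ribbon_psth_cpp(p, r, dt, duration, as.integer(reps), bin_ms,
                          pool_max, as.integer(seed), deterministic)
  sti_from_psth(psth)
}

#' Build the STI interpolation table
#'
#' A grid of STI values over release probabilities and refill rates, both
#' log-spaced (51 points per axis over (1.56e-4, 0.25) x (5.12e-5, 1.0) by
#' default), for fast lookup by bilinear interpolation in log space.
#'
#' @param n grid points per axis.
#' @param p_range,r_range axis ranges (release probability, refill rate).
#' @param ... passed to [compute_sti()] (reps, seed, ...).
#' @return an `sti_table`.
#' @export
build_sti_table <- function(n = 51, p_range = c(1.56e-4, 0.25),
                            r_range = c(5.12e-5, 1.0), ...) {
  p_axis <- exp(seq(log(p_range[1]), log(p_range[2]), length.out = n))
  r_axis <- exp(seq(log(r_range[1]), log(r_range[2]), length.out = n))
  vals <- matrix(NA_real_, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      vals[i, j] <- compute_sti(p_axis[i], r_axis[j], ...)
  structure(list(p_axis = p_axis, r_axis = r_axis, sti = vals),
            class = "sti_table")
}

#' Look up an STI value by bilinear interpolation in log-parameter space
#'
#' Queries outside the table range are clamped to the border with a warning.
#'
#' @param p release probability.
#' @param r refill rate.
#' @param table an [build_sti_table()] result.
#' @return interpolated STI.
#' @export
lookup_sti <- function(p, r, table) {
  stopifnot(inherits(table, "sti_table"))
  lp <- log(p); lr <- log(r)
  la <- log(table$p_axis); lb <- log(table$r_axis)
  if (lp < la[1] || lp > la[length(la)] || lr < lb[1] || lr > lb[length(lb)]) {
    warning("query outside STI table range; clamped")
    lp <- min(max(lp, la[1]), la[length(la)])
    lr <- min(max(lr, lb[1]), lb[length(lb)])
  }
  i <- findInterval(lp, la, all.inside = TRUE)
  j <- findInterval(lr, lb, all.inside = TRUE)
  wx <- (lp - la[i]) / (la[i + 1] - la[i])
  wy <- (lr - lb[j]) / (lb[j + 1] - lb[j])
  (1 - wx) * (1 - wy) * table$sti[i, j] +
    wx * (1 - wy) * table$sti[i + 1, j] +
    (1 - wx) * wy * table$sti[i, j + 1] +
    wx * wy * table$sti[i + 1, j + 1]
}
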