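# ---------------------------------------------------------------------------
# Visual stimuli: expanding / collapsing rings, alternating bars, flicker
# noise, and precompilation of per-compartment illumination time series.
# All intensities are gray-scale values in [0, 1]; times in ms; space in um.
# ---------------------------------------------------------------------------

#' Expanding / collapsing ring stimulus specification
#'
#' Concentric square-wave rings (50\% duty cycle by default) drifting
#' radially outward (expanding) or inward (collapsing) at
#' `spatial_period * temporal_frequency`.  The stimulus alternates between an
#' illuminating phase and a dark phase, each lasting `time_c = 1000 /
#' (2 * temporal_frequency)` ms.  The ring pattern extends to the field
#' diagonal so that the square field corners are covered.
#'
#' @param kind `"expanding_rings"` or `"collapsing_rings"`.
#' @param field_size width/height of the square stimulation field, um.
#' @param field_origin bottom-left corner of the field, um.
#' @param center ring center (the simulated cell's soma position), um.
#' @param temporal_frequency stimulus frequency, Hz.
#' @param spatial_period ring spatial period, um per cycle.
#' @param delay stimulation onset delay, ms.
#' @param duration stimulus duration, ms.
#' @param duty illuminated fraction of each spatial cycle.
#' @param profile `"rings"` (drifting square-wave grating) or `"disc"`
#'   (a single expanding/collapsing disc).
#' @param noise optional [flicker_noise_spec()].
#' @return a `stimulus_spec`.
#' @export
ring_stimulus <- function(kind = c("expanding_rings", "collapsing_rings"),
                          field_size = c(315, 315), field_origin = c(0, 0),
                          center = c(135, 125), temporal_frequency = 2,
                          spatial_period = 450, delay = 0, duration = 1500,
                          duty = 0.5, profile = c("rings", "disc"),
                          noise = NULL) {
  kind <- match.arg(kind)
  profile <- match.arg(profile)
  stopifnot(temporal_frequency > 0, spatial_period > 0, all(field_size > 0))
  structure(list(kind = kind, field_size = field_size,
                 field_origin = field_origin, center = center,
                 temporal_frequency = temporal_frequency,
                 spatial_period = spatial_period, delay = delay,
                 duration = duration, duty = duty, profile = profile,
                 time_c = 1000 / (2 * temporal_frequency),
                 max_radius = sqrt(sum(field_size^2)),
                 noise = noise),
            class = "stimulus_spec")
}

#' Alternating moving-bar stimulus specification
#'
#' A bright bar of length `bar_length` (along the motion axis) and width
#' `bar_width` sweeps along x at `velocity`, reversing direction every
#' `(x_perimeter + bar_length) / velocity` seconds so that it fully crosses
#' the travel perimeter, exits, and comes back.
#'
#' @param bar_length bar extent along the motion axis, um.
#' @param bar_width bar extent orthogonal to motion, um.
#' @param velocity bar speed, um per second.
#' @param x_perimeter length of the travel corridor, um.
#' @param center center of the travel corridor, um.
#' @param first_direction +1 (first sweep towards +x) or -1.
#' @param duration stimulus duration, ms.
#' @param field_size,field_origin stimulation field geometry, um.
#' @param noise optional [flicker_noise_spec()].
#' @return a `stimulus_spec`.
#' @export
bar_stimulus <- function(bar_length = 250, bar_width = 600, velocity = 1000,
                         x_perimeter = 500, center = c(135, 125),
                         first_direction = 1, duration = 3000,
                         field_size = c(600, 600),
                         field_origin = center - field_size / 2,
                         noise = NULL) {
  stopifnot(velocity > 0, bar_length > 0, x_perimeter > 0)
  structure(list(kind = "alternating_bar", bar_length = bar_length,
                 bar_width = bar_width, velocity = velocity,
                 x_perimeter = x_perimeter, center = center,
                 first_direction = sign(first_direction), duration = duration,
                 field_size = field_size, field_origin = field_origin,
                 sweep_ms = 1000 * (x_perimeter + bar_length) / velocity,
                 noise = noise),
            class = "stimulus_spec")
}

#' Flickering-spot background noise specification
#'
#' `n_spots` bright discs are placed uniformly at random over the field and
#' resampled at `refresh_rate`; the noise is combined with the base stimulus
#' by taking the pointwise maximum.
#'
#' @param n_spots number of spots per flicker epoch.
#' @param spot_radius spot radius, um.
#' @param refresh_rate flicker rate, Hz.
#' @param rng_seed integer seed; the same seed reproduces the spot sequence.
#' @return a `flicker_noise_spec`.
#' @export
flicker_noise_spec <- function(n_spots = 30, spot_radius = 25,
                               refresh_rate = 15, rng_seed = 1L) {
  stopifnot(n_spots >= 0, refresh_rate > 0, spot_radius > 0)
  structure(list(n_spots = as.integer(n_spots), spot_radius = spot_radius,
                 refresh_rate = refresh_rate, rng_seed = as.integer(rng_seed)),
            class = "flicker_noise_spec")
}

#' Illumination phase of a ring stimulus
#'
#' Expanding rings illuminate while `(t - delay) mod (2 * time_c) < time_c`;
#' collapsing rings use the complementary (strict `>`) comparison, so the
#' exact phase boundary is dark for both.
#'
#' @param t time, ms (vectorized).
#' @param spec a ring `stimulus_spec`.
#' @return `"illuminating"` or `"dark"` per time point.
#' @export
ring_phase <- function(t, spec) {
  stopifnot(inherits(spec, "stimulus_spec"),
            spec$kind %in% c("expanding_rings", "collapsing_rings"))
  ph <- (t - spec$delay) %% (2 * spec$time_c)
  on <- if (spec$kind == "expanding_rings") ph < spec$time_c else ph > spec$time_c
  ifelse(on, "illuminating", "dark")
}

# disc-mode edge radius within the current illuminating phase (NA in dark)
ring_edge_radius <- function(t, spec) {
  v <- spec$spatial_period * spec$temporal_frequency / 1000   # um per ms
  ph <- (t - spec$delay) %% (2 * spec$time_c)
  if (spec$kind == "expanding_rings") {
    ifelse(ph < spec$time_c, v * ph, NA_real_)
  } else {
    ifelse(ph > spec$time_c, v * (spec$time_c - (ph - spec$time_c)), NA_real_)
  }
}

#' Ring stimulus intensity at a point
#'
#' The default profile is a continuous radial square-wave grating drifting
#' outward (expanding) or inward (collapsing) at `spatial_period *
#' temporal_frequency`, so every point is modulated at the temporal
#' frequency and the light-onset front travels in the motion direction.  At
#' the ring center this reduces exactly to the [ring_phase()] alternation:
#' the center is illuminated during the first (expanding) or second
#' (collapsing) half of each cycle.  Expanding and collapsing stimuli are
#' time reversals of one another.  The `"disc"` profile instead grows or
#' shrinks a single disc during the illuminating phase and is dark
#' everywhere otherwise.
#'
#' @param x,y planar position, um (vectorized, equal length).
#' @param t time, ms (scalar).
#' @param spec a ring `stimulus_spec`.
#' @return intensities in \[0, 1\].
#' @export
ring_intensity <- function(x, y, t, spec) {
  rho <- sqrt((x - spec$center[1])^2 + (y - spec$center[2])^2)
  v <- spec$spatial_period * spec$temporal_frequency / 1000   # um per ms
  te <- t - spec$delay
  P <- spec$spatial_period
  out <- if (spec$profile == "disc") {
    re <- ring_edge_radius(t, spec)
    if (is.na(re)) numeric(length(rho)) else as.numeric(rho <= re)
  } else if (spec$kind == "expanding_rings") {
    as.numeric(((v * te - rho) %% P) < spec$duty * P)
  } else {
    as.numeric(((v * te + rho) %% P) >= (1 - spec$duty) * P)
  }
  out[rho > spec$max_radius] <- 0
  out
}

#' Moving-bar stimulus intensity at a point
#'
#' @param x,y planar position, um (vectorized).
#' @param t time, ms (scalar).
#' @param spec a bar `stimulus_spec`.
#' @return intensities in \[0, 1\] (1 inside the bar footprint).
#' @export
bar_intensity <- function(x, y, t, spec) {
  stopifnot(spec$kind == "alternating_bar")
  P <- spec$x_perimeter; L <- spec$bar_length
  x_min <- spec$center[1] - P / 2
  s <- (t / 1000 * spec$velocity) %% (2 * (P + L))
  if (spec$first_direction < 0) s <- (s + (P + L)) %% (2 * (P + L))
  if (s < P + L) {                      # moving +x; leading edge at x_min + s
    lo <- x_min + s - L; hi <- x_min + s
  } else {                              # moving -x
    sp <- s - (P + L)
    lo <- x_min + P - sp; hi <- lo + L
  }
  inside <- x >= lo & x <= hi & abs(y - spec$center[2]) <= spec$bar_width / 2
  as.numeric(inside)
}

#' Current motion direction of an alternating bar
#'
#' @param t time, ms.
#' @param spec a bar `stimulus_spec`.
#' @return +1 or -1 per time point.
#' @export
bar_direction <- function(t, spec) {
  s <- (t / 1000 * spec$velocity) %% (2 * (spec$x_perimeter + spec$bar_length))
  d <- ifelse(s < spec$x_perimeter + spec$bar_length, 1, -1)
  d * spec$first_direction
}

# spot centers of the flicker epoch containing time t (deterministic in seed)
flicker_spots <- function(noise, t, field_origin, field_size) {
  epoch <- floor(t * noise$refresh_rate / 1000)
  if (noise$n_spots == 0L) return(matrix(numeric(0), ncol = 2))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed((noise$rng_seed + epoch * 7919L) %% .Machine$integer.max)
  cbind(field_origin[1] + runif(noise$n_spots) * field_size[1],
        field_origin[2] + runif(noise$n_spots) * field_size[2])
}

#' Overlay flickering-spot noise on a base intensity field
#'
#' The spot layout is resampled every `1000 / refresh_rate` ms; within an
#' epoch it is constant.  The combined intensity is `max(base, spot mask)`,
#' so values stay in \[0, 1\].
#'
#' @param base base intensities at the query points.
#' @param x,y query point coordinates, um.
#' @param t time, ms (scalar).
#' @param noise a [flicker_noise_spec()].
#' @param field_origin,field_size rectangle over which spots are scattered.
#' @return intensities in \[0, 1\].
#' @export
apply_flicker_noise <- function(base, x, y, t, noise, field_origin,
                                field_size) {
  stopifnot(inherits(noise, "flicker_noise_spec"))
  if (noise$n_spots == 0L) return(base)
  sp <- flicker_spots(noise, t, field_origin, field_size)
  mask <- rep(FALSE, length(x))
  for (i in seq_len(nrow(sp)))
    mask <- mask | ((x - sp[i, 1])^2 + (y - sp[i, 2])^2 <=
                      noise$spot_radius^2)
  pmax(base, as.numeric(mask))
}

# intensity of a stimulus spec (plus optional noise) at points, time t
stimulus_field <- function(spec) {
  force(spec)
  function(x, y, t) {
    base <- switch(spec$kind,
      expanding_rings = ,
      collapsing_rings = ring_intensity(x, y, t, spec),
      alternating_bar = bar_intensity(x, y, t, spec),
      stop("unknown stimulus kind: ", spec$kind))
    if (!is.null(spec$noise))
      base <- apply_flicker_noise(base, x, y, t, spec$noise,
                                  spec$field_origin, spec$field_size)
    base
  }
}

#' Precompile a stimulus into a per-position intensity matrix
#'
#' Evaluates the illumination at each query position for every time step, so
#' that repeated simulation runs replay the identical visual input.  Row `i`,
#' column `k` holds the intensity at `positions[i, ]` and time `(k - 1) * dt`.
#'
#' @param spec a `stimulus_spec`, or a function `f(x, y, t)` returning
#'   intensities.
#' @param positions two-column matrix of planar positions, um.
#' @param dt sampling interval, ms.
#' @param duration total duration, ms; the matrix has `round(duration / dt)`
#'   columns covering `[0, duration)`.
#' @return an `intensity_matrix` (numeric matrix with a `dt` attribute).
#' @export
compile_stimulus <- function(spec, positions, dt = 1, duration = NULL) {
  f <- if (inherits(spec, "stimulus_spec")) stimulus_field(spec) else spec
  if (is.null(duration)) {
    if (!inherits(spec, "stimulus_spec"))
      stop("duration must be given when spec is a plain function")
    duration <- spec$duration
  }
  stopifnot(dt > 0)
  positions <- as.matrix(positions)
  n_steps <- round(duration / dt)
  out <- matrix(0, nrow = nrow(positions), ncol = n_steps)
  for (k in seq_len(n_steps))
    out[, k] <- f(positions[, 1], positions[, 2], (k - 1) * dt)
  if (any(out < 0 | out > 1)) stop("stimulus intensities must lie in [0, 1]")
  structure(out, dt = dt, duration = duration, class = "intensity_matrix")
}

#' Measure the radial drift velocity of a ring stimulus
#'
#' Locates the outermost illuminated edge on a dense radial grid at two times
#' within one illuminating phase and differences the edge positions.
#'
#' @param spec a ring `stimulus_spec`.
#' @param t1,t2 probe times, ms (defaults inside the first phase).
#' @return drift speed in um per second (positive outward for expanding).
#' @export
measure_ring_velocity <- function(spec, t1 = spec$time_c * 0.2,
                                  t2 = spec$time_c * 0.6) {
  if (spec$kind == "collapsing_rings") {
    t1 <- spec$time_c + t1; t2 <- spec$time_c + t2
  }
  edge_at <- function(t) {
    rho <- seq(0, spec$spatial_period * spec$duty, by = 0.05)
    inten <- ring_intensity(spec$center[1] + rho, rep(spec$center[2],
                                                      length(rho)), t, spec)
    first_dark <- which(inten == 0)[1]
    rho[first_dark - 1L]
  }
  (edge_at(t2) - edge_at(t1)) / (t2 - t1) * 1000
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("<stimulus_spec: %s, %.0f ms, field %.0fx%.0f um%s>\n",
              x$kind, x$duration, x$field_size[1], x$field_size[2],
              if (!is.null(x$noise)) ", + flicker noise" else ""))
  invisible(x)
}
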