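# ---------------------------------------------------------------------------
# Selectivity and kinetics indices computed from voltage traces:
# CSI (centrifugal selectivity), RTI (rise-time index), DSI (direction
# selectivity), PD activation, and the supporting rise-time / cycle-folding
# machinery.
# ---------------------------------------------------------------------------

#' Centrifugal selectivity index
#'
#' `CSI = (R_exp - R_col) / (R_exp + R_col)` from the response amplitudes to
#' expanding and collapsing rings; positive values indicate centrifugal
#' preference.
#'
#' @param r_exp,r_col response amplitudes, mV (vectorized).
#' @return index in \[-1, 1\], `NA` where both amplitudes are 0.
#' @export
csi <- function(r_exp, r_col) {
  s <- r_exp + r_col
  ifelse(s == 0, NA_real_, (r_exp - r_col) / s)
}

#' Rise-time index
#'
#' `RTI = (rt_col - rt_exp) / (rt_col + rt_exp)`; positive values indicate
#' faster rise during centrifugal (expanding) motion.
#'
#' @param rt_col,rt_exp rise times, ms (vectorized).
#' @return index in \[-1, 1\], `NA` where both rise times are 0.
#' @export
rti <- function(rt_col, rt_exp) {
  s <- rt_col + rt_exp
  ifelse(s == 0, NA_real_, (rt_col - rt_exp) / s)
}

#' Response rise time (20\%-of-peak to peak)
#'
#' Time from the first sample reaching `baseline + 0.2 * (peak - baseline)`
#' to the peak sample; peak ties break to the earliest sample.
#'
#' @param trace voltage trace, mV.
#' @param baseline baseline voltage, mV.
#' @param dt sampling interval, ms.
#' @return rise time, ms, or `NA` for a flat / non-depolarizing trace.
#' @export
rise_time <- function(trace, baseline, dt) {
  peak <- max(trace)
  if (peak <= baseline) return(NA_real_)
  ipk <- which.max(trace)
  thr <- baseline + 0.2 * (peak - baseline)
  i20 <- which(trace >= thr)[1]
  (ipk - i20) * dt
}

#' Direction selectivity index from preferred/null voltage traces
#'
#' `DSI = (R_PD - R_ND) / (R_PD + R_ND)` where each `R` is the area between
#' the trace and the reference voltage (clipped below at 0), integrated by
#' the trapezoid rule.
#'
#' @param trace_pd,trace_nd voltage traces of equal length, mV.
#' @param dt sampling interval, ms.
#' @param reference reference voltage, mV (-60).
#' @return the DSI, or `NA` if both areas are 0.
#' @export
dsi <- function(trace_pd, trace_nd, dt, reference = -60) {
  if (length(trace_pd) != length(trace_nd))
    stop("traces must have the same length")
  r_pd <- trace_area(trace_pd, reference, dt)
  r_nd <- trace_area(trace_nd, reference, dt)
  if (r_pd + r_nd == 0) return(NA_real_)
  (r_pd - r_nd) / (r_pd + r_nd)
}

# trapezoid area of max(V - ref, 0), mV*ms
trace_area <- function(v, ref, dt) {
  x <- pmax(v - ref, 0)
  if (length(x) < 2L) return(0)
  sum((x[-1] + x[-length(x)]) / 2) * dt
}

#' Preferred-direction activation above the spiking threshold
#'
#' Area of the preferred-direction voltage trace above the spiking
#' threshold.  For simulated DSGCs the threshold is 11 mV above the minimum
#' of the trace.
#'
#' @param trace_pd preferred-direction voltage trace, mV.
#' @param spike_threshold threshold, mV; `NULL` uses `min(trace) + 11`.
#' @param dt sampling interval, ms.
#' @return activation area, mV ms.
#' @export
pd_activation <- function(trace_pd, spike_threshold = NULL, dt) {
  if (is.null(spike_threshold)) spike_threshold <- min(trace_pd) + 11
  trace_area(trace_pd, spike_threshold, dt)
}

#' Average a periodic response over stimulus cycles
#'
#' Folds the trace into cycles of `period_ms` and averages, discarding the
#' first `discard` cycles (the response to stimulus appearance).
#'
#' @param trace voltage trace sampled at `dt`.
#' @param dt sampling interval, ms.
#' @param period_ms cycle length, ms.
#' @param discard leading cycles to drop (1).
#' @return the cycle-averaged waveform.
#' @export
fold_cycles <- function(trace, dt, period_ms, discard = 1L) {
  n_cyc <- round(period_ms / dt)
  total <- (length(trace) - 1L) %/% n_cyc
  if (total <= discard) stop("trace shorter than discard + 1 cycles")
  use <- (discard + 1L):total
  folded <- rowMeans(vapply(use, function(k)
    trace[((k - 1L) * n_cyc + 1L):(k * n_cyc)], numeric(n_cyc)))
  folded
}

#' Response metrics of an expanding/collapsing ring pair
#'
#' Cycle-averages both somatic traces (first cycle discarded), measures
#' amplitudes (peak minus baseline) and 20\%-to-peak rise times, and returns
#' the CSI / RTI pair plus the raw maximal voltages used by the genetic
#' objectives.
#'
#' @param v_exp,v_col somatic voltage traces for expanding and collapsing
#'   rings.
#' @param dt sampling interval, ms.
#' @param time_c half stimulation period, ms (cycle length is `2 * time_c`).
#' @param baseline baseline voltage, mV (the resting potential).
#' @return list with csi, rti, amplitudes, rise times and windowed maxima.
#' @export
ring_response_metrics <- function(v_exp, v_col, dt, time_c, baseline) {
  period <- 2 * time_c
  f_exp <- fold_cycles(v_exp, dt, period)
  f_col <- fold_cycles(v_col, dt, period)
  amp_exp <- max(f_exp) - baseline
  amp_col <- max(f_col) - baseline
  rt_exp <- rise_time(f_exp, baseline, dt)
  rt_col <- rise_time(f_col, baseline, dt)
  win <- -(1:round(period / dt))                # drop the first cycle
  list(csi = csi(amp_exp, amp_col), rti = rti(rt_col, rt_exp),
       amp_exp = amp_exp, amp_col = amp_col,
       rt_exp = rt_exp, rt_col = rt_col,
       max_exp = max(v_exp[-seq_len(round(period / dt))]),
       max_col = max(v_col[-seq_len(round(period / dt))]),
       folded_exp = f_exp, folded_col = f_col)
}

#' Population centrifugal-preference summary
#'
#' Computes per-cell CSI and RTI from a table of response amplitudes and
#' rise times (one row per cell) and summarizes the population.
#'
#' @param tab data frame with columns `amp_exp`, `amp_col`, `rt_exp`,
#'   `rt_col`.
#' @return list with per-cell indices and population mean/sd of each.
#' @export
population_cf_indices <- function(tab) {
  stopifnot(all(c("amp_exp", "amp_col", "rt_exp", "rt_col") %in% names(tab)))
  cell_csi <- csi(tab$amp_exp, tab$amp_col)
  cell_rti <- rti(tab$rt_col, tab$rt_exp)
  list(per_cell = data.frame(csi = cell_csi, rti = cell_rti),
       csi_mean = mean(cell_csi, na.rm = TRUE),
       csi_sd = sd(cell_csi, na.rm = TRUE),
       rti_mean = mean(cell_rti, na.rm = TRUE),
       rti_sd = sd(cell_rti, na.rm = TRUE))
}
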