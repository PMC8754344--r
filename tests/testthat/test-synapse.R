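test_that("release probability follows the distance rule", {
  g <- genome_params(release_probability = 0.08,
                     k_transition_start_point = 0,
                     k_transition_end_point = 135)
  # multiplicative gating by the visual intensity
  expect_equal(release_prob_at(50, g, v_intensity = 0), 0)
  # at d = m the slope term saturates
  expect_equal(release_prob_at(135, g, 1), 0.08)
  # kinetics constant beyond the transition endpoint: d = 2m clamps to m
  expect_equal(release_prob_at(270, g, 1), release_prob_at(135, g, 1))
  # cap at 1
  gbig <- genome_params(release_probability = 5,
                        k_transition_start_point = 0.5)
  expect_equal(release_prob_at(135, gbig, 1), 1)
  # reversed kinetics substitute d -> extent - d
  expect_equal(release_prob_at(0, g, 1, "reversed", extent = 210),
               release_prob_at(210, g, 1))
  # fixed kinetics freeze at the somatic value
  expect_equal(release_prob_at(200, g, 1, "fixed"),
               release_prob_at(0, g, 1))
  expect_error(release_prob_at(10, genome_params(k_transition_end_point = 0)))
})

test_that("refill rate has a proximal plateau and a linear decline", {
  g <- genome_params(refilling_rate = 1, k_transition_start_point = 0.5,
                     k_transition_end_point = 100)
  # proximal branch (u < k_tsp): full rate
  expect_equal(refill_rate_at(10, g), 1)
  # u = 0.75: r = 0.5 * 1 + 1 * (1 - 0.75) = 0.75
  expect_equal(refill_rate_at(75, g), 0.75)
  # non-increasing in distance
  r <- refill_rate_at(seq(0, 250, by = 5), g)
  expect_true(all(diff(r) <= 1e-12))
})

test_that("ribbon release is binomial over the integer pool", {
  st <- ribbon_state()
  expect_equal(st$pool, 70)
  # degenerate draws
  set.seed(1)
  expect_equal(step_ribbon(st, p = 0, r = 0, dt = 0.025)$released, 0)
  expect_equal(step_ribbon(st, p = 1, r = 0, dt = 0.025)$released, 70)
  # Monte-Carlo mean at pool = 70, p = 0.1 matches the binomial mean
  set.seed(42)
  rel <- replicate(1e4, step_ribbon(ribbon_state(), 0.1, 0, 0.025)$released)
  se <- sqrt(70 * 0.1 * 0.9 / 1e4)
  expect_lt(abs(mean(rel) - 7), 3 * se)
  # pool bookkeeping: pool + released - refill is conserved below the cap
  set.seed(7)
  st <- ribbon_state(); tot_rel <- 0; tot_ref <- 0
  for (i in 1:400) {
    out <- step_ribbon(st, 0.3, 0.9, 0.025)
    refill <- min(0.9 * 0.025, st$pool_max - (st$pool - out$released))
    tot_rel <- tot_rel + out$released; tot_ref <- tot_ref + refill
    st <- out$state
    expect_equal(st$pool, 70 - tot_rel + tot_ref, tolerance = 1e-9)
    expect_true(st$pool >= 0 && st$pool <= 70)
  }
  expect_equal(reset_ribbon(st)$pool, 70)
})

test_that("ribbon trajectories are reproducible and reset on darkness", {
  # same seed -> bit-identical PSTH from the compiled ribbon simulator
  a <- retsim:::ribbon_psth_cpp(0.05, 0.5, 0.025, 250, 20, 10, 70, 3, FALSE)
  b <- retsim:::ribbon_psth_cpp(0.05, 0.5, 0.025, 250, 20, 10, 70, 3, FALSE)
  expect_identical(a, b)
  # light -> dark reset inside the circuit simulator: a synapse driven by a
  # 1-0-1 intensity pattern releases a fresh full-pool burst after darkness
  m <- cable_morphology(length_um = 20, radius_um = 1)
  cell <- make_cell(discretize(m), passive_props(), c(0, 0), 1L)
  exc <- data.frame(cell = 1L, comp = 2L, x = 0, y = 0, d = 10,
                    pfac = 0.9, refill = 0, weight = 0.01, mult = 1)
  circ <- build_circuit(list(cell), exc_synapses = exc)
  stim <- structure(matrix(rep(c(1, 0, 1), each = 100), nrow = 1),
                    dt = 1, class = "intensity_matrix")
  res <- simulate_circuit(circ, stim = stim, duration = 300,
                          deterministic = TRUE)
  v <- res$v[1, ]
  t <- res$t
  # with no refill the pool empties in the first light phase; the second
  # light phase depolarizes again only because darkness reset the pool
  peak1 <- max(v[t < 100]); peak2 <- max(v[t > 200])
  expect_gt(peak1, -59)
  expect_gt(peak2, -59)
  trough <- max(v[t > 190 & t < 200])
  expect_lt(trough, peak2 - 0.5)
})

test_that("double-exponential kernel peaks at the closed-form time", {
  k <- conductance_kernel(0.89, 1.84, 0, 0.0025)
  expect_equal(kernel_conductance(0, k), 0)
  tp <- kernel_peak_time(k)
  expect_equal(tp, 0.89 * 1.84 / (1.84 - 0.89) * log(1.84 / 0.89))
  expect_equal(kernel_conductance(tp, k), k$weight, tolerance = 1e-12)
  tt <- seq(0, 20, by = 0.01)
  expect_true(all(kernel_conductance(tt, k) <= k$weight + 1e-12))
  # linear superposition of two events
  g2 <- kernel_conductance(tt, k) + kernel_conductance(pmax(tt - 3, 0), k) *
    (tt >= 3)
  expect_equal(g2[tt == 5], kernel_conductance(5, k) +
                 kernel_conductance(2, k))
  expect_error(conductance_kernel(2, 1, 0, 1), "tau_decay > tau_rise")
})

test_that("GABA event trains lock to threshold crossings", {
  dt <- 0.025
  # never suprathreshold
  expect_length(gaba_event_times(rep(-60, 1000), dt), 0L)
  # 20 ms above threshold at 200 Hz: events at 0, 5, 10, 15 ms
  v <- c(rep(-60, 40), rep(-40, 800), rep(-60, 40))
  ev <- gaba_event_times(v, dt)
  expect_equal(ev - ev[1], c(0, 5, 10, 15))
  # two disjoint suprathreshold epochs give two independent trains, each
  # restarting its phase at the crossing
  v2 <- c(rep(-40, 280), rep(-60, 100), rep(-40, 280))
  ev2 <- gaba_event_times(v2, dt)
  expect_equal(ev2, c(0, 5, (280 + 100) * dt + c(0, 5)))
})

test_that("sustained-transient index matches its definition and an oracle", {
  expect_equal(sti_from_psth(c(4, 3, 2, 4)), 1)      # steady == peak
  expect_equal(sti_from_psth(c(10, 1, 0, 0)), 0)     # fully transient
  expect_true(is.na(sti_from_psth(c(0, 1, 2))))      # empty peak bin
  # depleting synapse with negligible refill is transient
  expect_lt(compute_sti(0.2, 1e-4, seed = 5), 0.02)
  # mid-range kinetics agree with an independent high-repetition R oracle
  p <- 0.01; r <- 0.5; dt <- 0.025
  set.seed(99)
  nrep <- 500L; nstep <- 10000L
  pool <- rep(70, nrep); psth <- matrix(0, nrep, 25)
  for (s in seq_len(nstep)) {
    rel <- rbinom(nrep, floor(pool), p)
    pool <- pmin(pool - rel + r * dt, 70)
    b <- (s - 1) %/% 400 + 1
    psth[, b] <- psth[, b] + rel
  }
  oracle <- sti_from_psth(colMeans(psth))
  sti <- compute_sti(p, r, reps = 200, seed = 17)
  expect_equal(sti, oracle, tolerance = 0.08)
})

test_that("STI table interpolates its own nodes and orders its corners", {
  tab <- build_sti_table(n = 5, reps = 20, seed = 3)
  expect_equal(dim(tab$sti), c(5L, 5L))
  expect_true(all(diff(tab$p_axis) > 0) && all(diff(tab$r_axis) > 0))
  # lookup at a grid node returns the stored value
  expect_equal(lookup_sti(tab$p_axis[2], tab$r_axis[3], tab),
               tab$sti[2, 3])
  # between nodes the value lies within the four corner values
  mid_p <- sqrt(tab$p_axis[2] * tab$p_axis[3])
  mid_r <- sqrt(tab$r_axis[2] * tab$r_axis[3])
  corners <- tab$sti[2:3, 2:3]
  v <- lookup_sti(mid_p, mid_r, tab)
  expect_gte(v, min(corners)); expect_lte(v, max(corners))
  # sustained corner (small p, large r) beats transient corner
  expect_gt(tab$sti[1, 5], tab$sti[5, 1])
  expect_warning(lookup_sti(1, 1e-6, tab), "clamped")
})
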