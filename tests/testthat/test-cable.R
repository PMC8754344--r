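test_that("a circuit with no inputs stays at rest", {
  cell <- make_cell(discretize(small_star()), passive_props(), c(0, 0), 1L)
  res <- simulate_circuit(build_circuit(list(cell)), duration = 50)
  expect_true(all(abs(res$v - -60) < 1e-9))
})

test_that("isolated compartment follows the RC closed form", {
  m <- cable_morphology(length_um = 10, radius_um = 1, step = 10)
  # keep only the soma section: one isolated compartment
  m$sections <- m$sections[1]
  cell <- make_cell(discretize(m), passive_props(), c(0, 0), 1L)
  g_ns <- passive_props()$leak_conductance * cell$tree$area_cm2[1] * 1e9
  tau <- 1 * cell$tree$area_cm2[1] * 1e6 / g_ns     # pF / nS = ms
  circ <- build_circuit(list(cell),
                        injections = data.frame(cell = 1, comp = 1,
                                                amp_pa = 5, t0 = 0,
                                                t1 = 1000))
  res <- simulate_circuit(circ, duration = 9 * tau)
  dv <- res$v[1, ncol(res$v)] + 60
  expect_equal(dv, 5 / g_ns, tolerance = 1e-3)      # within 0.1 %
  # input resistance of the isolated compartment is 1 / (g_pas * A)
  rin <- measure_input_resistance(cell, duration = 8 * tau)
  expect_equal(rin, 1e3 / g_ns, tolerance = 1e-3)   # MOhm
})

test_that("sealed uniform cable matches finite-cable theory", {
  pp <- passive_props()
  m <- cable_morphology(length_um = 400, radius_um = 1, soma_radius = 1)
  cell <- make_cell(discretize(m, 2.5), pp, c(0, 0), 1L)
  rin <- measure_input_resistance(cell, duration = 600)
  Rm <- 1 / pp$leak_conductance
  a <- 1e-4; L <- 400e-4                            # cm
  lambda <- sqrt(a * Rm / (2 * pp$axial_resistivity))
  Rinf <- sqrt(Rm * pp$axial_resistivity / 2) / (pi * a^1.5)
  Rcable <- Rinf / tanh(L / lambda)                 # sealed end: coth
  gsoma <- pp$leak_conductance * cell$tree$area_cm2[1]
  expected <- 1 / (1 / Rcable + gsoma) / 1e6        # MOhm, soma in parallel
  expect_equal(rin, expected, tolerance = 0.01)
})

test_that("input resistance scales inversely with leak conductance", {
  m <- small_star()
  r1 <- measure_input_resistance(make_cell(discretize(m), passive_props(),
                                           c(0, 0), 1L))
  r2 <- measure_input_resistance(
    make_cell(discretize(m), passive_props(leak_conductance = 1.2e-4),
              c(0, 0), 1L))
  expect_equal(r1 / r2, 2, tolerance = 0.01)
})

test_that("voltage clamp holds the level and reports Ohmic current", {
  m <- cable_morphology(length_um = 10, radius_um = 1, step = 10)
  m$sections <- m$sections[1]
  cell <- make_cell(discretize(m), passive_props(), c(0, 0), 1L)
  g_ns <- passive_props()$leak_conductance * cell$tree$area_cm2[1] * 1e9
  # clamp at rest: zero current
  i0 <- voltage_clamp(build_circuit(list(cell)), 1, 1, -60, duration = 50)
  expect_true(all(abs(i0[-1]) < 1e-9))
  # clamp 10 mV above rest: steady current 10 * g_pas * A
  i10 <- voltage_clamp(build_circuit(list(cell)), 1, 1, -50, duration = 50)
  expect_equal(i10[length(i10)], 10 * g_ns, tolerance = 1e-9)
})

test_that("implicit scheme is stable at coarse steps and converges in dt", {
  g <- genome_params()
  a1 <- run_single_sac_assay(g, seed = 2, duration = 1000, dt = 0.1,
                             deterministic = TRUE)
  expect_true(all(is.finite(a1$v_exp)))
  expect_lt(max(a1$v_exp), 0)
  a2 <- run_single_sac_assay(g, seed = 2, duration = 1000, dt = 0.025,
                             deterministic = TRUE)
  a3 <- run_single_sac_assay(g, seed = 2, duration = 1000, dt = 0.0125,
                             deterministic = TRUE)
  # refining dt from 0.025 to 0.0125 changes the peak by < 1 %
  pk2 <- max(a2$v_exp) + 60; pk3 <- max(a3$v_exp) + 60
  expect_lt(abs(pk2 - pk3) / pk3, 0.01)
})

test_that("voltage respects the maximum principle with excitatory input", {
  # all synaptic reversals at 0 mV >= rest, no clamps: V never exceeds 0
  a <- run_single_sac_assay(genome_params(), seed = 4, duration = 1000)
  expect_lt(max(a$v_exp), 0)
  expect_lt(max(a$v_col), 0)
  expect_gte(min(a$v_exp), -60 - 1e-9)
})

test_that("simulation results are bit-reproducible under a fixed seed", {
  g <- genome_params()
  a <- run_single_sac_assay(g, seed = 8, duration = 1000)
  b <- run_single_sac_assay(g, seed = 8, duration = 1000)
  expect_identical(a$v_exp, b$v_exp)
  expect_identical(a$v_col, b$v_col)
  c_ <- run_single_sac_assay(g, seed = 9, duration = 1000)
  expect_false(identical(a$v_exp, c_$v_exp))
})
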