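test_that("ring phase follows the modular alternation", {
  ex <- ring_stimulus("expanding_rings")
  co <- ring_stimulus("collapsing_rings")
  expect_equal(ring_phase(100, ex), "illuminating")
  expect_equal(ring_phase(300, ex), "dark")          # 300 mod 500 >= 250
  expect_equal(ring_phase(250, ex), "dark")          # strict boundary
  # collapsing is the complement away from exact boundaries
  t <- setdiff(seq(0, 995, by = 5), seq(0, 1000, by = 250))
  expect_true(all(ring_phase(t, ex) != ring_phase(t, co)))
})

test_that("ring grating drifts at spatial_period * temporal_frequency", {
  ex <- ring_stimulus("expanding_rings", spatial_period = 450,
                      temporal_frequency = 2)
  expect_equal(measure_ring_velocity(ex), 900, tolerance = 1e-6)
  co <- ring_stimulus("collapsing_rings")
  expect_equal(measure_ring_velocity(co), -900, tolerance = 1e-6)
  # spatial periodicity within the pattern extent: intensity at rho equals
  # intensity at rho + period (a wide field keeps both radii inside)
  wide <- ring_stimulus("expanding_rings", field_size = c(700, 700),
                        center = c(350, 350))
  rho <- seq(5, 200, by = 13)
  for (t in c(40, 120, 330)) {
    a <- ring_intensity(wide$center[1] + rho, rep(wide$center[2],
                                                  length(rho)), t, wide)
    b <- ring_intensity(wide$center[1] + rho + 450,
                        rep(wide$center[2], length(rho)), t, wide)
    expect_equal(a, b)
  }
  # the ring center reproduces the phase alternation exactly
  for (t in c(10, 100, 249, 251, 400)) {
    expect_equal(ring_intensity(ex$center[1], ex$center[2], t, ex),
                 as.numeric(ring_phase(t, ex) == "illuminating"))
    expect_equal(ring_intensity(co$center[1], co$center[2], t, co),
                 as.numeric(ring_phase(t, co) == "illuminating"))
  }
})

test_that("expanding and collapsing rings are time reversals", {
  ex <- ring_stimulus("expanding_rings")
  co <- ring_stimulus("collapsing_rings")
  rho <- seq(3, 210, by = 11.7)
  x <- ex$center[1] + rho; y <- rep(ex$center[2], length(rho))
  for (t in seq(13, 487, by = 29))
    expect_equal(ring_intensity(x, y, t, co),
                 ring_intensity(x, y, 500 - t, ex))
})

test_that("alternating bar geometry and direction flips", {
  sp <- bar_stimulus(bar_length = 250, bar_width = 600, velocity = 1000,
                     x_perimeter = 500, center = c(0, 0), duration = 3000)
  # flips every (500 + 250) / 1000 s = 750 ms
  expect_equal(sp$sweep_ms, 750)
  expect_equal(bar_direction(c(10, 740, 760, 1490, 1510), sp),
               c(1, 1, -1, -1, 1))
  # mid-sweep: inside footprint -> 1, ahead of the leading edge -> 0
  # at t = 375 ms the leading edge is at -250 + 375 = 125
  expect_equal(bar_intensity(100, 0, 375, sp), 1)
  expect_equal(bar_intensity(150, 0, 375, sp), 0)    # ahead of leading edge
  expect_equal(bar_intensity(-200, 0, 375, sp), 0)   # behind trailing edge
  expect_equal(bar_intensity(100, 400, 375, sp), 0)  # outside bar width
})

test_that("flicker noise resamples per epoch and stays bounded", {
  no <- flicker_noise_spec(n_spots = 30, spot_radius = 25,
                           refresh_rate = 15, rng_seed = 4L)
  gx <- as.vector(outer(seq(0, 300, by = 20), rep(1, 16)))
  gy <- as.vector(outer(rep(1, 16), seq(0, 300, by = 20)))
  base <- rep(0, length(gx))
  m0 <- apply_flicker_noise(base, gx, gy, 0, no, c(0, 0), c(315, 315))
  m66 <- apply_flicker_noise(base, gx, gy, 66, no, c(0, 0), c(315, 315))
  m67 <- apply_flicker_noise(base, gx, gy, 67, no, c(0, 0), c(315, 315))
  expect_identical(m0, m66)                 # constant within [0, 66.67) ms
  expect_false(identical(m66, m67))         # resampled at 1000/15 ms
  expect_true(all(m67 %in% c(0, 1)))
  # identity with zero spots; clamped with a bright base
  none <- flicker_noise_spec(n_spots = 0)
  expect_identical(apply_flicker_noise(base, gx, gy, 0, none, c(0, 0),
                                       c(315, 315)), base)
  bright <- apply_flicker_noise(rep(1, length(gx)), gx, gy, 0, no, c(0, 0),
                                c(315, 315))
  expect_true(all(bright == 1))
  # illuminated area is at most n_spots * pi * r^2 (overlap only reduces it)
  cell <- 20^2
  expect_lte(sum(m0) * cell, 30 * pi * 25^2 + 30 * 4 * 25 * 20)
})

test_that("stimulus compilation is sized and replayable", {
  ex <- ring_stimulus("expanding_rings", duration = 1500)
  pos <- cbind(c(135, 160, 200), c(125, 125, 140))
  m <- compile_stimulus(ex, pos, dt = 0.025)
  expect_equal(ncol(m), 60000L)             # 1500 / 0.025 steps
  expect_equal(nrow(m), 3L)
  expect_true(all(m >= 0 & m <= 1))
  # constant field
  cf <- compile_stimulus(function(x, y, t) rep(0.5, length(x)), pos,
                         dt = 10, duration = 100)
  expect_true(all(cf == 0.5))
  # deterministic replay, including the seeded flicker noise
  exn <- ring_stimulus("expanding_rings", duration = 200,
                       noise = flicker_noise_spec(rng_seed = 9L))
  a <- compile_stimulus(exn, pos, dt = 5)
  b <- compile_stimulus(exn, pos, dt = 5)
  expect_identical(a, b)
})
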