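# Detector frame, transport physics and the 2D weighting potential.

test_that("geometry invariants: strip layout and coordinate frame", {
  g <- detector_geometry()
  expect_equal(g$n_strips, 51L)
  expect_equal(g$reference_strip, 26L)
  expect_lt(g$electrode_width, g$pitch)
  expect_equal(strip_centers(g, 26), 0)
  expect_equal(strip_centers(g, 27), 12)
  expect_equal(strip_centers(g, 1), (1 - 26) * 12)
  expect_error(detector_geometry(electrode_width = 12, pitch = 12))
  # nearest-electrode mapping, gap positions included
  expect_equal(strip_at_x(g, c(0, 5.9, 6.1, -6.1, 400, -400)),
               c(26L, 26L, 27L, 25L, 51L, 1L))
})

test_that("drift field is uniform, bias/thickness, pointing to -y", {
  f <- drift_field(detector_geometry())
  expect_equal(f$magnitude, 200 / 0.05)    # 200 V over 500 um in V/cm
  expect_equal(f$direction, c(0, -1))
})

test_that("drift speed has the Canali low-field and saturation limits", {
  ph <- transport_physics()
  expect_equal(drift_speed(0, "hole", ph), 0)
  # low-field limit: within 1 percent of mu0 E at E <= 100 V/cm
  for (E in c(1, 10, 100)) {
    expect_equal(drift_speed(E, "electron", ph), ph$mu0_e * E,
                 tolerance = 0.01)
    expect_equal(drift_speed(E, "hole", ph), ph$mu0_h * E, tolerance = 0.01)
  }
  # saturation limit and monotonicity
  E <- 10^seq(0, 7, by = 0.25)
  for (k in c("electron", "hole")) {
    v <- drift_speed(E, k, ph)
    expect_true(all(diff(v) > 0))
    vs <- if (k == "electron") ph$vsat_e else ph$vsat_h
    expect_true(all(v < vs))
    expect_equal(drift_speed(1e9, k, ph), vs, tolerance = 1e-3)
  }
})

test_that("Einstein relation: D = (kT/e) mu0, linear in T, ratio cancels", {
  ph <- transport_physics()
  kT_e <- 1.380649e-23 * 300 / 1.602176634e-19
  expect_equal(diffusion_coefficient("hole", ph), kT_e * 471,
               tolerance = 1e-12)
  expect_equal(diffusion_coefficient("electron", ph) /
                 diffusion_coefficient("hole", ph),
               ph$mu0_e / ph$mu0_h, tolerance = 1e-12)
  # linear in temperature (and vanishing as T -> 0)
  d1 <- diffusion_coefficient("hole", transport_physics(temperature = 100))
  d3 <- diffusion_coefficient("hole", transport_physics(temperature = 300))
  expect_equal(d3 / d1, 3, tolerance = 1e-12)
  expect_lt(diffusion_coefficient("hole",
                                  transport_physics(temperature = 1e-6)),
            1e-7)
})

test_that("weighting map: exact Dirichlet boundaries and value range", {
  m <- coarse_map()
  g <- m$geometry
  # unit potential on the reference electrode, zero on backside and on
  # other electrodes
  expect_equal(weighting_value(m, 26, c(0, 4, -4), c(0, 0, 0)), rep(1, 3))
  expect_equal(weighting_value(m, 26, c(0, 30, -55), c(500, 500, 500)),
               rep(0, 3))
  expect_equal(weighting_value(m, 26, c(12, -12, 24), c(0, 0, 0)), rep(0, 3))
  expect_true(all(m$values >= 0 & m$values <= 1))
  expect_lt(m$residual, 1e-8)
})

test_that("weighting map obeys the discrete maximum principle", {
  m <- coarse_map()
  interior <- m$values[2:(length(m$x) - 1), 2:(length(m$y) - 1)]
  expect_true(all(interior > 0))
  expect_true(all(interior < 1))
})

test_that("weighting value interpolation is translation consistent", {
  m <- coarse_map()
  x <- c(-3.7, 0, 2.2, 5.5)
  y <- c(17, 123.4, 250, 480)
  expect_equal(weighting_value(m, 26, x, y),
               weighting_value(m, 27, x + 12, y), tolerance = 1e-12)
  expect_equal(weighting_value(m, 26, x, y),
               weighting_value(m, 25, x - 12, y), tolerance = 1e-12)
})

test_that("grid refinement converges with observed order >= 1.5", {
  g <- detector_geometry()
  # probe at nodes shared by all three grids (no interpolation error),
  # near the strips where the solution varies fastest.  The linearly
  # interpolated gap profile keeps the boundary data continuous, so the
  # electrode-edge corner does not cap the observable order.
  probe_x <- c(0, 4, 8)
  probe_y <- c(10, 20, 30)
  w <- lapply(c(1, 0.5, 0.25), function(h) {
    m <- solve_weighting_potential(g, grid_spacing = h, x_halfwidth = 24,
                                   gap_bc = "linear")
    weighting_value(m, 26, probe_x, probe_y)
  })
  d1 <- max(abs(w[[2]] - w[[1]]))
  d2 <- max(abs(w[[3]] - w[[2]]))
  expect_lt(d2, d1 / 2^1.5)
})

test_that("solution matches the closed-form strip oracle along x = 0", {
  # electrodes separated by a single linearly interpolated boundary node
  # on a wide grounded domain approximate the analytic zero-gap
  # configuration (effective strip width = pitch); the agreement
  # tolerance shrinks with grid refinement
  g <- detector_geometry(electrode_width = 11)
  y <- seq(10, 490, by = 24)
  err <- sapply(c(2, 1), function(h) {
    m <- solve_weighting_potential(g, grid_spacing = h, x_halfwidth = 300,
                                   gap_bc = "linear",
                                   sidewall_bc = "grounded")
    max(abs(weighting_value(m, 26, rep(0, length(y)), y) -
              strip_weighting_oracle(0, y, w = 12)))
  })
  expect_lte(err[2], err[1])
  expect_lt(err[2], 0.005)
})

test_that("superposition: strip potentials sum below the plate complement", {
  g <- detector_geometry()
  m <- cc_cached("wide_map", {
    solve_weighting_potential(g, grid_spacing = 2, x_halfwidth = 342,
                              sidewall_bc = "grounded")
  })
  y <- 250
  s <- sum(sapply(seq_len(51), function(k) weighting_value(m, k, 0, y)))
  expect_lte(s, 1)
  expect_lt(s, 1 - y / 500 + 0.02)
  # the zero-gap closed form per electrode bounds it from above
  oracle_sum <- sum(sapply(strip_centers(g), function(cx)
    strip_weighting_oracle(0 - cx, y, w = 10)))
  expect_equal(s, oracle_sum, tolerance = 0.25)
})

test_that("weighting value errors outside the wafer", {
  m <- coarse_map()
  expect_error(weighting_value(m, 26, 0, -1), "outside")
  expect_error(weighting_value(m, 26, 0, 501), "outside")
})

test_that("weighting map exports and re-imports identically", {
  m <- coarse_map()
  base <- file.path(tempdir(), "wmap")
  write_weighting_map(m, base)
  m2 <- read_weighting_map(base)
  expect_equal(m2$grid_spacing, m$grid_spacing)
  expect_equal(m2$values, m$values, tolerance = 1e-12)
  expect_equal(weighting_value(m2, 30, 3, 77), weighting_value(m, 30, 3, 77),
               tolerance = 1e-10)
})
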