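# Drift-diffusion stepping, collection, Shockley-Ramo signal induction
# and the event-level simulation.

zero_field <- function() structure(list(magnitude = 0, direction = c(0, -1)),
                                   class = "drift_field")
cold <- function() transport_physics(temperature = 1e-9)  # D ~ 0

test_that("a step with no field and no diffusion leaves carriers in place", {
  p0 <- cbind(c(-3, 0, 4), c(100, 250, 400))
  p1 <- step_carriers(p0, c("hole", "electron", "hole"), zero_field(),
                      cold(), dt = 2e-9)
  expect_equal(p1, p0, tolerance = 1e-6)
})

test_that("drift-only step displaces holes by exactly -v dt", {
  g <- detector_geometry()
  f <- drift_field(g)
  ph <- cold()
  dt <- 2e-9
  v_um <- drift_speed(f$magnitude, "hole", ph) * 1e4 * dt
  p1 <- step_carriers(cbind(0, 250), "hole", f, ph, dt)
  expect_equal(p1[1, 1], 0, tolerance = 1e-4)
  expect_equal(p1[1, 2], 250 - v_um, tolerance = 1e-4)
  # electrons go the other way
  p2 <- step_carriers(cbind(0, 250), "electron", f, ph, dt)
  expect_gt(p2[1, 2], 250)
})

test_that("diffusion-only random walk has variance 2 D N dt", {
  set.seed(401)
  ph <- transport_physics()
  n <- 1e4; N <- 25; dt <- 2e-9
  p <- cbind(rep(0, n), rep(250, n))
  for (i in seq_len(N))
    p <- step_carriers(p, "hole", zero_field(), ph, dt)
  v_expect <- 2 * diffusion_coefficient("hole", ph) * N * dt * 1e8  # um^2
  se_v <- v_expect * sqrt(2 / (n - 1))
  expect_lt(abs(stats::var(p[, 1]) - v_expect), 3 * se_v)
  expect_lt(abs(stats::var(p[, 2]) - v_expect), 3 * se_v)
})

test_that("carriers are transported to their collection boundaries", {
  set.seed(402)
  g <- detector_geometry()
  f <- drift_field(g)
  cfg <- transport_config()

  # drift-only hole from the backside: collection time = thickness / v
  ph0 <- cold()
  t_exact <- 500e-4 / drift_speed(f$magnitude, "hole", ph0)
  out <- transport_to_collection(cbind(0, 500), "hole", g, f, ph0, cfg)
  expect_equal(out$y_end, 0)
  expect_lt(abs(out$time - t_exact), cfg$dt)

  # electrons always end on the backside
  ph <- transport_physics()
  oe <- transport_to_collection(cbind(rep(0, 200), runif(200, 1, 499)),
                                "electron", g, f, ph, cfg)
  expect_true(all(oe$y_end == 500))

  # diffusion spread at collection matches 2 D t_drift
  n <- 1e4
  oh <- transport_to_collection(cbind(rep(0, n), rep(400, n)), "hole",
                                g, f, ph, cfg)
  t_drift <- mean(oh$time)
  v_expect <- 2 * diffusion_coefficient("hole", ph) * t_drift * 1e8
  se_v <- v_expect * sqrt(2 / (n - 1))
  expect_lt(abs(stats::var(oh$x_end) - v_expect), 4 * se_v)
})

test_that("induced current traces integrate to q delta-W (Ramo)", {
  m <- ramo_map()
  # a stationary carrier induces nothing
  flat <- matrix(c(0, 1e-9, 2, 2, 100, 100), ncol = 3,
                 dimnames = list(NULL, c("time", "x", "y")))
  tr0 <- induced_current_trace(flat, m, 26, "hole")
  expect_true(all(tr0$current == 0))
  # trace mode refuses endpoint-only paths
  expect_error(induced_current_trace(flat[1, , drop = FALSE], m, 26, "hole"),
               "record_traces")

  dev <- ramo_deviations(1000)
  expect_lt(mean(abs(dev)), 0.005)
  expect_lt(max(abs(dev)), 0.05)
})

test_that("a collected pair induces one full charge on the landing strip", {
  set.seed(404)
  g <- detector_geometry()
  f <- drift_field(g)
  ph <- transport_physics()
  cfg <- transport_config()
  m <- ramo_map()
  ens <- structure(list(pair_positions = data.frame(x = c(0, 2), y = c(60, 300)),
                        pair_count = 2L), class = "carrier_ensemble")
  paths <- transport_to_collection(ens, geometry = g, field = f,
                                   physics = ph, config = cfg)
  sig <- integrated_pixel_energies(paths, g, map = m, method = "delta_w")
  land <- strip_at_x(g, paths$x_end[paths$kind == "hole"])
  # each pair contributes 3.6 eV to its landing strip, nothing elsewhere
  expected <- tabulate(land, nbins = 51) * 3.6e-3
  expect_equal(sig$energies, expected, tolerance = 0.05 * 3.6e-3 * 2)
})

test_that("landing and delta-W signal computations agree on shared paths", {
  set.seed(405)
  g <- detector_geometry()
  m <- ramo_map()
  ens <- track_to_pairs(generate_electron_track(8, c(-4.8, 20)))
  paths <- transport_to_collection(ens, geometry = g)
  fast <- integrated_pixel_energies(paths, g, method = "landing")
  full <- integrated_pixel_energies(paths, g, map = m, method = "delta_w")
  expect_equal(fast$deposited_energy, full$deposited_energy)
  expect_lt(max(abs(fast$energies - full$energies)), 0.1)
  expect_lt(abs(sum(full$energies) - full$deposited_energy),
            0.02 * full$deposited_energy)
})

test_that("noiseless signals conserve the deposited energy", {
  ds <- small_dataset()
  pair_round <- abs(rowSums(ds$signals) -
                      ds$events$recoil_energy)
  # per-deposit rounding error is below 3.6 eV per deposit (21 deposits)
  expect_true(all(pair_round <= 21 * 3.6e-3 + 1e-9))
})

test_that("worked example: 8 keV at (-4.8, 20) concentrates in the pixel", {
  set.seed(406)
  ev <- simulate_event(list(photon_energy = 60, recoil_energy = 8,
                            origin = c(-4.8, 20)))
  s <- ev$signals$energies
  expect_equal(ev$deposited_energy, 8)
  expect_equal(sum(s), 8, tolerance = 0.05)
  # charge lands in the illuminated strip and its immediate neighbour
  expect_gte(sum(s[25:26]), 0.9 * sum(s))
  expect_true(which.max(s) %in% c(25L, 26L))
  expect_equal(s[c(1:20, 31:51)], rep(0, 41), tolerance = 1e-9)
})

test_that("charge clouds widen with interaction depth", {
  set.seed(407)
  n <- 300
  occupied <- function(y0) {
    sapply(seq_len(n), function(i) {
      ev <- simulate_event(list(photon_energy = 60, recoil_energy = 10,
                                origin = c(runif(1, -6, 6), y0)))
      sum(ev$signals$energies > 0)
    })
  }
  shallow <- occupied(30)
  deep <- occupied(470)
  expect_gt(mean(deep), mean(shallow))
})

test_that("x centroid of signals is an unbiased track-centroid estimator", {
  # low-noise limit: no electronic noise, no threshold; the strip-binned
  # centroid should track the energy-weighted track centroid on average
  set.seed(408)
  g <- detector_geometry()
  n <- 1000
  diffs <- vapply(seq_len(n), function(i) {
    tr <- generate_electron_track(12, c(runif(1, -6, 6), runif(1, 20, 480)))
    cen <- sum(tr$deposits$x * tr$deposits$energy_eV) /
      sum(tr$deposits$energy_eV)
    ens <- track_to_pairs(tr)
    paths <- transport_to_collection(ens$pair_positions, "hole", g)
    s <- integrated_pixel_energies(paths, g)$energies
    sum(strip_centers(g) * s) / sum(s) - cen
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * stats::sd(diffs) / sqrt(n))
})

test_that("dataset simulation is reproducible under a fixed seed", {
  d1 <- simulate_compton_dataset(50, seed = 4242)
  d2 <- simulate_compton_dataset(50, seed = 4242)
  expect_identical(d1$signals, d2$signals)
  expect_identical(d1$events, d2$events)
})
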