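# Spectrum model, interaction classification, Klein-Nishina recoil
# sampling, event origins, electron tracks and the track-table format.

test_that("filtered spectrum: endpoint, attenuation monotone, hardening", {
  sp <- build_filtered_spectrum(kvp = 140)
  expect_true(all(sp$energy_keV <= 140))
  expect_equal(sp$relative_fluence[sp$energy_keV == 140], 0)
  expect_true(all(sp$relative_fluence >= 0))
  expect_equal(sum(sp$relative_fluence), 1)

  # adding a filter never increases any bin's (unnormalised) weight:
  # compare attenuation factors directly through two builds
  base <- build_filtered_spectrum(kvp = 140, filters = list(
    list(material = "aluminum", thickness_mm = 2)))
  more <- build_filtered_spectrum(kvp = 140, filters = list(
    list(material = "aluminum", thickness_mm = 2),
    list(material = "soft_tissue", thickness_mm = 50)))
  # ratio of normalised spectra equals ratio of attenuations up to a
  # constant; check the added filter only suppresses low energies
  ratio <- more$relative_fluence / pmax(base$relative_fluence, 1e-300)
  expect_true(all(diff(ratio[base$relative_fluence > 1e-12]) > -1e-9))

  # beam hardening: mean energy rises with filtration
  unfiltered <- build_filtered_spectrum(kvp = 140, filters = list())
  mean_e <- function(s) sum(s$energy_keV * s$relative_fluence)
  expect_gt(mean_e(sp), mean_e(unfiltered))
})

test_that("unknown filter material raises a helpful error", {
  expect_error(attenuation_table("unobtainium"), "available")
})

test_that("interaction classification follows the cross-section ratios", {
  p <- interaction_probabilities(c(20, 60, 100))
  expect_equal(rowSums(p), rep(1, 3))
  expect_error(interaction_probabilities(1000), "range")

  set.seed(301)
  n <- 1e5
  kind <- classify_interaction(rep(60, n))
  p60 <- interaction_probabilities(60)[1, "compton"]
  se <- sqrt(p60 * (1 - p60) / n)
  expect_lt(abs(mean(kind == "compton") - p60), 3 * se)
})

test_that("Klein-Nishina recoils respect the Compton edge and quadrature mean", {
  set.seed(302)
  tmax_140 <- 140 * (2 * 140 / 511) / (1 + 2 * 140 / 511)
  expect_equal(tmax_140, compton_edge(140), tolerance = 1e-12)
  t140 <- sample_compton_recoil(rep(140, 2e4))
  expect_true(all(t140 >= 0))
  expect_true(all(t140 <= tmax_140))

  # low-energy limit: recoils vanish with the photon energy
  expect_lt(max(sample_compton_recoil(rep(0.5, 1000))), compton_edge(0.5))
  expect_lt(compton_edge(0.5), 2e-3 * 0.5 * 511)  # ~ E * 2E/mc2

  # sampled mean against independent numerical quadrature at 70 keV
  n <- 2e5
  t70 <- sample_compton_recoil(rep(70, n))
  mu_oracle <- kn_mean_recoil_quadrature(70)
  se <- stats::sd(t70) / sqrt(n)
  expect_lt(abs(mean(t70) - mu_oracle), 3 * se)
})

test_that("event origins are uniform over the pixel area", {
  set.seed(303)
  g <- detector_geometry()
  o <- sample_event_origin(g, 1e5)
  expect_true(all(o$X0 >= -6 & o$X0 <= 6))
  expect_true(all(o$Y0 >= 0 & o$Y0 <= 500))
  expect_lt(abs(mean(o$X0) - 0), 3 * (12 / sqrt(12)) / sqrt(1e5))
  expect_lt(abs(mean(o$Y0) - 250), 3 * (500 / sqrt(12)) / sqrt(1e5))
  v <- 500^2 / 12
  se_v <- v * sqrt(2 / (1e5 - 1))   # near-normal sample variance SE
  expect_lt(abs(stats::var(o$Y0) - v), 3 * se_v)
})

test_that("electron tracks conserve energy and respect the range law", {
  set.seed(304)
  cfg <- track_config()
  for (T_keV in c(2, 10, 30, 49)) {
    tr <- generate_electron_track(T_keV, c(0, 250), geometry = NULL,
                                  config = cfg)
    expect_equal(sum(tr$deposits$energy_eV), T_keV * 1000, tolerance = 1e-9)
    r <- sqrt(tr$deposits$x^2 + (tr$deposits$y - 250)^2)
    expect_true(all(r <= csda_range(T_keV, cfg) + 1e-9))
  }
  # 1 keV tracks are sub-micrometre (range law at 1 keV)
  ext <- replicate(200, {
    tr <- generate_electron_track(1, c(0, 250), geometry = NULL, config = cfg)
    max(sqrt(tr$deposits$x^2 + (tr$deposits$y - 250)^2))
  })
  expect_lt(stats::quantile(ext, 0.95), 1)
})

test_that("fluorescence split keeps conservation and flags the track", {
  set.seed(305)
  cfg <- track_config(fluorescence_prob = 1)
  tr <- generate_electron_track(10, c(0, 250), config = cfg)
  expect_true(tr$fluorescence_flag)
  expect_equal(sum(tr$deposits$energy_eV), 10000, tolerance = 1e-9)
  expect_equal(sum(tr$deposits$fluorescence), 1)
  expect_equal(tr$deposits$energy_eV[tr$deposits$fluorescence], 1740)
})

test_that("pair conversion divides deposits by the ionization energy", {
  mk <- function(e_eV) structure(
    list(deposits = data.frame(x = 0, y = 250, energy_eV = e_eV,
                               fluorescence = FALSE),
         total_energy = sum(e_eV) / 1000, fluorescence_flag = FALSE),
    class = "electron_track")
  expect_equal(track_to_pairs(mk(3.6))$pair_count, 1L)
  expect_equal(track_to_pairs(mk(8000))$pair_count, round(8000 / 3.6))
  expect_equal(track_to_pairs(mk(8000))$pair_count, 2222L)
  expect_equal(track_to_pairs(mk(0))$pair_count, 0L)
  # chain rounding loses less than 3.6 eV per deposit
  set.seed(306)
  tr <- generate_electron_track(17.3, c(0, 100))
  pc <- track_to_pairs(tr)$pair_count
  expect_lt(abs(pc * 3.6 - 17300), 3.6 * nrow(tr$deposits))
})

test_that("track tables round-trip and validate", {
  set.seed(307)
  tracks <- lapply(c(5, 12), function(T_keV)
    generate_electron_track(T_keV, c(0, 100)))
  path <- file.path(tempdir(), "tracks.tsv")
  write_track_table(tracks, path)
  back <- read_track_table(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$deposits$x, tracks[[1]]$deposits$x,
               tolerance = 1e-9)
  expect_equal(back[[2]]$deposits$energy_eV, tracks[[2]]$deposits$energy_eV,
               tolerance = 1e-9)
  expect_equal(back[[1]]$total_energy, 5, tolerance = 1e-6)

  # malformed rows are rejected with the offending line number
  bad <- file.path(tempdir(), "bad_tracks.tsv")
  writeLines(c("event_id\tx_um\ty_um\tedep_eV",
               "1\t0\t10\t100", "1\t1\t11\t-5"), bad)
  expect_error(read_track_table(bad), "line 3")

  # handcrafted 7.2 eV track: one track, 2 pairs
  tiny <- file.path(tempdir(), "tiny_tracks.tsv")
  writeLines(c("event_id\tx_um\ty_um\tedep_eV",
               "1\t0\t10\t3.6", "1\t0.1\t10\t2.4", "1\t0.2\t10\t1.2"), tiny)
  tt <- read_track_table(tiny)
  expect_length(tt, 1)
  expect_equal(track_to_pairs(tt[[1]])$pair_count, 2L)
})

test_that("deposited-energy spectrum is concentrated below the Compton edge", {
  ds <- small_dataset()
  e <- ds$events$deposited_keV
  expect_true(all(e <= compton_edge(140) + 0.1))
  expect_gt(mean(e < 35), 0.85)   # bulk of the Compton peak below 35 keV
})
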