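# Independent oracles and shared (cached) heavyweight objects for the
# test suite.  Everything here is computed from first principles,
# separately from the package implementation it checks.

# Closed-form weighting potential of a single strip of width w in the
# plane y = 0 of an infinite slab of thickness d, with the rest of y = 0
# and the whole plane y = d grounded (zero-gap limit).  Harmonic measure
# of the strip seen from (x, y): map the slab to the upper half plane
# with zeta = exp(pi z / d) and read off the subtended angle.
strip_weighting_oracle <- function(x, y, w = 10, d = 500) {
  z <- complex(real = pi * x / d, imaginary = pi * y / d)
  (Arg(exp(z) - exp(pi * (w / 2) / d)) -
      Arg(exp(z) - exp(-pi * (w / 2) / d))) / pi
}

# Klein-Nishina differential cross section versus scattered photon
# energy (unnormalised), written out independently for quadrature
# oracles.  e and ep in keV.
kn_dsigma_dep <- function(e, ep) {
  mec2 <- 511
  ct <- 1 - mec2 * (1 / ep - 1 / e)
  (ep / e)^2 * (ep / e + e / ep - (1 - ct^2))
}

# Mean recoil energy at photon energy e by numerical quadrature.
kn_mean_recoil_quadrature <- function(e, n = 20000) {
  ep_min <- e / (1 + 2 * e / 511)
  ep <- seq(ep_min, e, length.out = n)
  f <- kn_dsigma_dep(e, ep)
  sum((e - ep) * f) / sum(f)
}

# Shared cache: expensive fixtures built once per test run.
.cc_cache <- new.env(parent = emptyenv())

cc_cached <- function(name, expr) {
  if (!exists(name, envir = .cc_cache))
    assign(name, force(expr), envir = .cc_cache)
  get(name, envir = .cc_cache)
}

# Coarse default-geometry weighting map (1 um grid, +/- 5 pitches).
coarse_map <- function() cc_cached("coarse_map", {
  solve_weighting_potential(detector_geometry(), grid_spacing = 1)
})

# Medium map for Ramo trace tests (0.5 um grid).
ramo_map <- function() cc_cached("ramo_map", {
  solve_weighting_potential(detector_geometry(), grid_spacing = 0.5)
})

# Small simulated dataset for unit tests.
small_dataset <- function() cc_cached("small_dataset", {
  simulate_compton_dataset(400, seed = 99)
})

# Shared study run: one simulated event set analysed both ways, used by
# the acceptance-criteria tests (10,000 events: the smallest scale at
# which the histogram-based resolution metrics are stable).
study_run <- function() cc_cached("study_run", {
  ds <- simulate_compton_dataset(10000, seed = 123)
  ideal <- analyze_dataset(ds, noise = FALSE)
  set.seed(124)
  noisy <- analyze_dataset(ds, noise = TRUE)
  list(dataset = ds, ideal = ideal, noisy = noisy)
})

# Ramo path-independence deviations: per-path difference between the
# time-integrated induced-current trace and q [W(end) - W(start)] on the
# central strip, in units of the elementary charge, over random drifted
# and diffused carrier paths.
ramo_deviations <- function(n_paths = 1000) cc_cached("ramo_dev", {
  set.seed(403)
  g <- detector_geometry()
  f <- drift_field(g)
  ph <- transport_physics()
  cfg <- transport_config()
  m <- ramo_map()
  e_C <- 1.602176634e-19
  starts <- cbind(runif(n_paths, -6, 6), runif(n_paths, 5, 495))
  kinds <- rep(c("hole", "electron"), length.out = n_paths)
  paths <- transport_to_collection(starts, kinds, g, f, ph, cfg,
                                   record_traces = TRUE)
  traces <- attr(paths, "traces")
  vapply(seq_len(n_paths), function(i) {
    k <- kinds[i]
    tr <- induced_current_trace(traces[[i]], m, 26, k)
    q <- if (k == "hole") e_C else -e_C
    dW <- weighting_value(m, 26, paths$x_end[i], paths$y_end[i]) -
      weighting_value(m, 26, paths$x0[i], paths$y0[i])
    (sum(tr$current * tr$dt) - q * dW) / e_C
  }, numeric(1))
})

# Gaussian closed form: 5 percent MTF crossing implied by a FWHM.
gaussian_mtf5_from_fwhm <- function(fwhm_um) {
  sigma_cm <- fwhm_um / (2 * sqrt(2 * log(2))) * 1e-4
  sqrt(log(20) / (2 * pi^2 * sigma_cm^2))
}
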