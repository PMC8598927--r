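# Per-event physics input: Compton recoil energies sampled from the
# Klein-Nishina electron spectrum, interaction origins inside the
# illuminated pixel, and a condensed-history electron-track generator.
#
# The track generator is a deliberately simple stand-in for a full
# coupled electron-photon Monte Carlo: it reproduces the energy-dependent
# track-extent scale (CSDA-range power law with a detour factor and
# small-angle scattering) that drives the position estimator's error,
# without condensed-history transport fidelity.  Exact externally
# computed tracks can be injected through \code{read_track_table}.

.mec2 <- 511.0  # electron rest energy, keV

#' Compton edge
#'
#' Maximum recoil-electron energy for a photon of energy E:
#' T_max = E 2k / (1 + 2k) with k = E / 511 keV.
#'
#' @param photon_energy photon energy in keV (vectorised).
#' @return maximum recoil energy in keV.
#' @export
compton_edge <- function(photon_energy) {
  kappa <- photon_energy / .mec2
  photon_energy * 2 * kappa / (1 + 2 * kappa)
}

# Klein-Nishina differential cross section versus scattered photon energy
# ep, un-normalised.  cos(theta) follows from the Compton relation.
.kn_density <- function(e, ep) {
  r <- ep / e
  ct <- 1 - .mec2 * (1 / ep - 1 / e)
  r^2 * (1 / r + r - (1 - ct^2))
}

#' Sample Compton recoil-electron energies
#'
#' Draws recoil energies from the Klein-Nishina electron-energy
#' distribution by rejection sampling on the scattered-photon energy
#' (the density is bounded by its forward-scatter value 2).  Recoil
#' energies are bounded by the Compton edge by construction.
#'
#' @param photon_energy photon energies in keV (one draw per entry).
#' @return recoil energies T in keV, 0 <= T <= \code{compton_edge}.
#' @export
sample_compton_recoil <- function(photon_energy) {
  n <- length(photon_energy)
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    e <- photon_energy[todo]
    ep_min <- e / (1 + 2 * e / .mec2)
    ep <- ep_min + (e - ep_min) * stats::runif(length(todo))
    acc <- stats::runif(length(todo)) * 2 <= .kn_density(e, ep)
    out[todo[acc]] <- e[acc] - ep[acc]
    todo <- todo[!acc]
  }
  out
}

#' Sample interaction origins inside a pixel
#'
#' Uniform over the pixel's pitch-by-thickness area, in the detector
#' frame (x relative to the centre of the reference strip).
#'
#' @param geometry a \code{\link{detector_geometry}}.
#' @param n number of events.
#' @param pixel strip index of the illuminated pixel (default the central
#'   reference strip).
#' @return data frame with columns \code{X0}, \code{Y0} in micrometres.
#' @export
sample_event_origin <- function(geometry, n, pixel = geometry$reference_strip) {
  stopifnot(pixel >= 1L, pixel <= geometry$n_strips)
  cx <- strip_centers(geometry, pixel)
  data.frame(
    X0 = cx + stats::runif(n, -geometry$pitch / 2, geometry$pitch / 2),
    Y0 = stats::runif(n, 0, geometry$thickness))
}

#' Electron-track generator configuration
#'
#' @param n_deposits number of equal-energy sub-deposits per track.
#' @param range_coeff,range_exp CSDA-range power law R(T) = coeff * T^exp
#'   in micrometres with T in keV (silicon, 1-50 keV regime).
#' @param detour_factor ratio of realised path length to CSDA range.
#' @param scatter_sigma per-step direction change (radians, Gaussian).
#' @param fluorescence_prob probability that a track splits off a
#'   displaced Si K fluorescence deposit (K-shell fraction times
#'   fluorescence yield).
#' @param fluorescence_energy energy of the fluorescence deposit, keV.
#' @param fluorescence_mean_range mean of the exponential displacement of
#'   the fluorescence deposit, micrometres.
#' @param w_ionization electron-hole pair creation energy, eV.
#' @return list of class \code{track_config}.
#' @export
track_config <- function(n_deposits = 20L, range_coeff = 0.0171,
                         range_exp = 1.75, detour_factor = 0.7,
                         scatter_sigma = 0.6, fluorescence_prob = 0.007,
                         fluorescence_energy = 1.74,
                         fluorescence_mean_range = 4,
                         w_ionization = 3.6) {
  stopifnot(n_deposits >= 1L, range_coeff > 0, range_exp > 0,
            detour_factor > 0, detour_factor <= 1,
            fluorescence_prob >= 0, fluorescence_prob <= 1,
            w_ionization > 0)
  structure(list(n_deposits = as.integer(n_deposits),
                 range_coeff = range_coeff, range_exp = range_exp,
                 detour_factor = detour_factor, scatter_sigma = scatter_sigma,
                 fluorescence_prob = fluorescence_prob,
                 fluorescence_energy = fluorescence_energy,
                 fluorescence_mean_range = fluorescence_mean_range,
                 w_ionization = w_ionization),
            class = "track_config")
}

#' CSDA range power law
#'
#' @param recoil_energy electron energy in keV.
#' @param config a \code{\link{track_config}}.
#' @return range in micrometres.
#' @export
csda_range <- function(recoil_energy, config = track_config()) {
  config$range_coeff * recoil_energy^config$range_exp
}

# Vectorised generator: one row per deposit, columns event (index into the
# inputs), x, y, energy_eV, fluorescence.  Deposits are clipped to the
# wafer; escape from mid-wafer interaction points is negligible.
.generate_tracks <- function(recoil_energy, x0, y0, geometry,
                             config = track_config()) {
  n <- length(recoil_energy)
  stopifnot(length(x0) == n, length(y0) == n, all(recoil_energy > 0))
  m <- config$n_deposits

  fl <- stats::runif(n) < config$fluorescence_prob &
    recoil_energy > 2 * config$fluorescence_energy
  e_track <- recoil_energy - ifelse(fl, config$fluorescence_energy, 0)

  # Random-walk path: m straight steps of equal length whose total is the
  # detour-scaled CSDA range of the track energy.
  step_len <- config$detour_factor * csda_range(e_track, config) / m
  theta0 <- stats::runif(n, 0, 2 * pi)
  dtheta <- matrix(stats::rnorm(n * m, sd = config$scatter_sigma), n, m)
  dtheta[, 1] <- 0
  theta <- if (m == 1L) matrix(theta0, n, 1L)
           else theta0 + t(apply(dtheta, 1, cumsum))
  dx <- step_len * cos(theta)
  dy <- step_len * sin(theta)
  px <- x0 + t(apply(dx, 1, cumsum))
  py <- y0 + t(apply(dy, 1, cumsum))

  dep <- data.frame(
    event = rep(seq_len(n), m),
    x = as.vector(px), y = as.vector(py),
    energy_eV = rep(e_track * 1000 / m, m),
    fluorescence = FALSE)

  if (any(fl)) {
    idx <- which(fl)
    r <- stats::rexp(length(idx), rate = 1 / config$fluorescence_mean_range)
    phi <- stats::runif(length(idx), 0, 2 * pi)
    dep <- rbind(dep, data.frame(
      event = idx,
      x = x0[idx] + r * cos(phi), y = y0[idx] + r * sin(phi),
      energy_eV = config$fluorescence_energy * 1000,
      fluorescence = TRUE))
  }
  if (!is.null(geometry)) {
    dep$x <- pmin(pmax(dep$x, -geometry$x_halfwidth), geometry$x_halfwidth)
    dep$y <- pmin(pmax(dep$y, 0), geometry$thickness)
  }
  dep[order(dep$event), , drop = FALSE]
}

#' Generate a recoil-electron track
#'
#' Condensed-history toy model: the recoil energy is deposited in
#' \code{n_deposits} equal parts along a random-walk path whose total
#' length is the detour-scaled CSDA range R(T); with a small probability
#' a 1.74 keV Si K fluorescence deposit is split off at an exponentially
#' distributed displacement.  Total deposited energy equals the recoil
#' energy exactly; deposits are clipped to the wafer.
#'
#' @param recoil_energy recoil-electron energy in keV (> 0).
#' @param origin interaction position c(x, y) in micrometres.
#' @param geometry a \code{\link{detector_geometry}} (used for clipping);
#'   \code{NULL} disables clipping.
#' @param config a \code{\link{track_config}}.
#' @return object of class \code{electron_track}: list with
#'   \code{deposits} (data frame x, y, energy_eV, fluorescence),
#'   \code{total_energy} (keV) and \code{fluorescence_flag}.
#' @export
generate_electron_track <- function(recoil_energy, origin,
                                    geometry = detector_geometry(),
                                    config = track_config()) {
  dep <- .generate_tracks(recoil_energy, origin[1], origin[2], geometry, config)
  structure(list(deposits = dep[, c("x", "y", "energy_eV", "fluorescence")],
                 total_energy = recoil_energy,
                 fluorescence_flag = any(dep$fluorescence)),
            class = "electron_track")
}

#' Convert an electron track to electron-hole pairs
#'
#' Each deposit contributes round(E_dep / w) pairs at the deposit
#' position (w = 3.6 eV for silicon); electron and hole of a pair start
#' at the same point.  No Fano-factor fluctuation is applied.
#'
#' @param track an \code{electron_track}.
#' @param w_ionization pair creation energy in eV.
#' @return object of class \code{carrier_ensemble}: list with
#'   \code{pair_positions} (data frame x, y, one row per pair) and
#'   \code{pair_count}.
#' @export
track_to_pairs <- function(track, w_ionization = 3.6) {
  dep <- track$deposits
  if (is.null(dep) || nrow(dep) == 0) stop("empty electron track")
  np <- as.integer(round(dep$energy_eV / w_ionization))
  keep <- np > 0
  pos <- data.frame(x = rep(dep$x[keep], np[keep]),
                    y = rep(dep$y[keep], np[keep]))
  structure(list(pair_positions = pos, pair_count = sum(np)),
            class = "carrier_ensemble")
}

#' Write / read electron-track tables
#'
#' Delimited text interchange format for externally generated tracks:
#' tab-separated columns \code{event_id}, \code{x_um}, \code{y_um},
#' \code{edep_eV} with a mandatory header line.
#'
#' @param tracks list of \code{electron_track} objects.
#' @param path file path.
#' @return \code{write_track_table}: \code{path}, invisibly.
#' @export
write_track_table <- function(tracks, path) {
  if (inherits(tracks, "electron_track")) tracks <- list(tracks)
  rows <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    d <- tracks[[i]]$deposits
    data.frame(event_id = i, x_um = d$x, y_um = d$y, edep_eV = d$energy_eV)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_track_table
#' @return \code{read_track_table}: list of \code{electron_track}
#'   objects grouped by \code{event_id}, with conservation recomputed.
#' @export
read_track_table <- function(path) {
  tab <- utils::read.delim(path)
  need <- c("event_id", "x_um", "y_um", "edep_eV")
  if (!all(need %in% names(tab)))
    stop("track table must have columns ", paste(need, collapse = ", "))
  bad <- which(!is.finite(tab$edep_eV) | tab$edep_eV <= 0)
  if (length(bad))
    stop(sprintf("non-positive deposit energy at line %d of %s",
                 bad[1] + 1L, path))
  lapply(split(tab, tab$event_id), function(d) {
    structure(list(deposits = data.frame(x = d$x_um, y = d$y_um,
                                         energy_eV = d$edep_eV,
                                         fluorescence = FALSE),
                   total_energy = sum(d$edep_eV) / 1000,
                   fluorescence_flag = FALSE),
              class = "electron_track")
  })
}
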