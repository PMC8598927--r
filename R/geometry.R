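# Detector geometry and carrier transport physics for an edge-on silicon
# strip detector.  All lengths are in micrometres unless a unit suffix says
# otherwise; fields are V/cm, mobilities cm^2/(V s), velocities cm/s.

#' Detector geometry
#'
#' Describes the simulated edge-on silicon sensor: a wafer of given
#' thickness read out by a row of strip electrodes on the front surface
#' (y = 0) and a single full-area electrode on the backside
#' (y = thickness).  The coordinate origin is the centre of the middle
#' strip in x and the strip-side surface in y; strip k is centred at
#' (k - reference_strip) * pitch.  The bias is applied to the backside so
#' the electric field points in -y, holes drift to the strips and
#' electrons to the backside.
#'
#' @param n_strips number of strip electrodes (odd, so a central strip
#'   exists; default 51).
#' @param pitch strip-to-strip pitch in micrometres.
#' @param electrode_width metallised electrode width in micrometres; must
#'   be smaller than the pitch, the remainder is an insulating gap.
#' @param thickness wafer thickness in micrometres.
#' @param bias_voltage backside potential in volts.
#' @param resistivity_kohm_cm substrate resistivity, metadata only.
#' @return an object of class \code{detector_geometry}.
#' @export
detector_geometry <- function(n_strips = 51L, pitch = 12, electrode_width = 10,
                              thickness = 500, bias_voltage = 200,
                              resistivity_kohm_cm = 15) {
  n_strips <- as.integer(n_strips)
  stopifnot(n_strips >= 1L, n_strips %% 2L == 1L,
            pitch > 0, electrode_width > 0, electrode_width < pitch,
            thickness > 0, bias_voltage > 0)
  g <- list(
    n_strips = n_strips,
    pitch = pitch,
    electrode_width = electrode_width,
    gap = pitch - electrode_width,
    thickness = thickness,
    bias_voltage = bias_voltage,
    resistivity_kohm_cm = resistivity_kohm_cm,
    reference_strip = (n_strips + 1L) %/% 2L,
    x_halfwidth = n_strips * pitch / 2
  )
  class(g) <- "detector_geometry"
  g
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf(
    "detector_geometry: %d strips, pitch %g um (electrode %g um), wafer %g um, bias %g V\n",
    x$n_strips, x$pitch, x$electrode_width, x$thickness, x$bias_voltage))
  invisible(x)
}

#' Strip centre positions
#'
#' @param geometry a \code{\link{detector_geometry}}.
#' @param strips strip indices (default all).
#' @return x positions of the strip centres in micrometres.
#' @export
strip_centers <- function(geometry, strips = seq_len(geometry$n_strips)) {
  stopifnot(all(strips >= 1L), all(strips <= geometry$n_strips))
  (strips - geometry$reference_strip) * geometry$pitch
}

#' Strip nearest to an x position
#'
#' Maps an x coordinate to the index of the nearest strip electrode.  A
#' position inside a gap is attributed to the strip whose electrode edge
#' is closest, which for centred electrodes is the strip with the nearest
#' centre.  Positions beyond the outermost strips clamp to strips 1 / n.
#'
#' @param geometry a \code{\link{detector_geometry}}.
#' @param x x positions in micrometres.
#' @return integer strip indices.
#' @export
strip_at_x <- function(geometry, x) {
  k <- as.integer(round(x / geometry$pitch)) + geometry$reference_strip
  pmin(pmax(k, 1L), geometry$n_strips)
}

#' Uniform drift field
#'
#' The pitch is small compared with the wafer thickness, so field-line
#' bending near the strips is neglected and the field is taken uniform,
#' pointing in -y with magnitude bias / thickness.
#'
#' @param geometry a \code{\link{detector_geometry}}.
#' @return list with \code{magnitude} (V/cm) and unit \code{direction}.
#' @export
drift_field <- function(geometry) {
  structure(list(
    magnitude = geometry$bias_voltage / (geometry$thickness * 1e-4),
    direction = c(0, -1)
  ), class = "drift_field")
}

# Physical constants (SI).
.kc <- list(boltzmann = 1.380649e-23, electron_charge = 1.602176634e-19)

#' Carrier transport physics for silicon
#'
#' Bundles the mobility model parameters used for drift and diffusion.
#' Drift uses the Canali field-dependent mobility
#' v = mu0 E / (1 + (mu0 E / v_sat)^beta)^(1/beta); diffusion uses the
#' constant low-field mobility through the Einstein relation
#' D = (kT/e) mu0.  Defaults are the standard 300 K silicon parameter
#' set (Jacoboni/Canali).
#'
#' @param temperature lattice temperature in kelvin.
#' @param mu0_e,mu0_h low-field mobilities, cm^2/(V s).
#' @param vsat_e,vsat_h saturation velocities, cm/s.
#' @param beta_e,beta_h Canali exponents.
#' @return an object of class \code{transport_physics}.
#' @export
transport_physics <- function(temperature = 300,
                              mu0_e = 1417, mu0_h = 471,
                              vsat_e = 1.07e7, vsat_h = 8.37e6,
                              beta_e = 1.109, beta_h = 1.213) {
  stopifnot(temperature > 0, mu0_e > 0, mu0_h > 0,
            vsat_e > 0, vsat_h > 0, beta_e > 0, beta_h > 0)
  p <- list(temperature = temperature,
            mu0_e = mu0_e, mu0_h = mu0_h,
            vsat_e = vsat_e, vsat_h = vsat_h,
            beta_e = beta_e, beta_h = beta_h,
            boltzmann_k = .kc$boltzmann,
            electron_charge_e = .kc$electron_charge,
            thermal_voltage = .kc$boltzmann * temperature / .kc$electron_charge)
  class(p) <- "transport_physics"
  p
}

.carrier_param <- function(physics, carrier, what) {
  carrier <- match.arg(carrier, c("electron", "hole"))
  suf <- if (carrier == "electron") "e" else "h"
  physics[[paste0(what, "_", suf)]]
}

#' Field-dependent drift speed
#'
#' Canali-form saturating drift speed.  Monotone increasing in the field
#' magnitude, linear (mu0 E) at low field and bounded by the saturation
#' velocity.
#'
#' @param field_magnitude electric field magnitude in V/cm (>= 0),
#'   vectorised.
#' @param carrier \code{"electron"} or \code{"hole"}.
#' @param physics a \code{\link{transport_physics}}.
#' @return drift speed in cm/s.
#' @export
drift_speed <- function(field_magnitude, carrier = c("electron", "hole"),
                        physics = transport_physics()) {
  carrier <- match.arg(carrier)
  stopifnot(all(field_magnitude >= 0))
  mu0 <- .carrier_param(physics, carrier, "mu0")
  vsat <- .carrier_param(physics, carrier, "vsat")
  beta <- .carrier_param(physics, carrier, "beta")
  v0 <- mu0 * field_magnitude
  v0 / (1 + (v0 / vsat)^beta)^(1 / beta)
}

#' Diffusion coefficient from the Einstein relation
#'
#' D = (kT/e) mu0 with the carrier's constant low-field mobility.
#'
#' @inheritParams drift_speed
#' @return diffusion coefficient in cm^2/s.
#' @export
diffusion_coefficient <- function(carrier = c("electron", "hole"),
                                  physics = transport_physics()) {
  carrier <- match.arg(carrier)
  physics$thermal_voltage * .carrier_param(physics, carrier, "mu0")
}
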