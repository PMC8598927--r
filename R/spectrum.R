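# Filtered x-ray tube spectrum and interaction-type classification.
#
# The tube model is a Kramers-shape bremsstrahlung continuum (no
# characteristic lines) hardened by exponential attenuation through the
# configured filter stack.  The attenuation and silicon cross-section
# tables shipped with the package are approximate fixtures: absolute
# spectrum-dependent quantities (e.g. the Compton fraction of primaries)
# are reproducible only approximately, and a measured spectrum can be
# substituted through \code{read_spectrum_table}.

.material_density <- c(aluminum = 2.699, beryllium = 1.848,
                       soft_tissue = 1.06)

.extdata <- function(name) {
  path <- system.file("extdata", name, package = "chargecloud")
  if (path == "") stop("packaged fixture not found: ", name)
  path
}

#' Mass attenuation table for a filter material
#'
#' @param material one of \code{"aluminum"}, \code{"beryllium"},
#'   \code{"soft_tissue"}.
#' @return data frame with \code{energy_keV}, \code{mu_rho_cm2_g} and a
#'   \code{density} attribute (g/cm^3).
#' @export
attenuation_table <- function(material) {
  if (!material %in% names(.material_density))
    stop("unknown material '", material, "'; available: ",
         paste(names(.material_density), collapse = ", "))
  tab <- utils::read.delim(.extdata(paste0("attenuation_", material, ".tsv")),
                           comment.char = "#")
  attr(tab, "density") <- unname(.material_density[[material]])
  tab
}

# Log-log interpolation of mu/rho, constant extrapolation at the ends.
.mu_rho <- function(tab, energy_keV) {
  exp(stats::approx(log(tab$energy_keV), log(tab$mu_rho_cm2_g),
                    xout = log(pmax(energy_keV, min(tab$energy_keV))),
                    rule = 2)$y)
}

#' Build a filtered bremsstrahlung spectrum
#'
#' Kramers continuum N(E) proportional to (kvp - E)/E on a 0.5 keV grid,
#' attenuated by exp(-sum_i (mu/rho)_i rho_i t_i) over the filter stack.
#' Weights are zero above the tube potential.
#'
#' @param kvp tube potential in kV.
#' @param filters list of \code{list(material =, thickness_mm =)} entries;
#'   the default is the 140 kVp study beam: 8.48 mm aluminum, 0.8 mm
#'   beryllium and 300 mm soft tissue.
#' @param bin_width energy grid step in keV.
#' @param e_min lowest tabulated energy in keV.
#' @return object of class \code{xray_spectrum}: a data frame with
#'   \code{energy_keV} and \code{relative_fluence} (normalised to unit
#'   sum).
#' @export
build_filtered_spectrum <- function(kvp = 140,
                                    filters = list(
                                      list(material = "aluminum", thickness_mm = 8.48),
                                      list(material = "beryllium", thickness_mm = 0.8),
                                      list(material = "soft_tissue", thickness_mm = 300)),
                                    bin_width = 0.5, e_min = 0.5) {
  stopifnot(kvp > 0, bin_width > 0, e_min > 0)
  energy <- seq(e_min, kvp, by = bin_width)
  w <- pmax(kvp - energy, 0) / energy
  for (f in filters) {
    tab <- attenuation_table(f$material)
    t_cm <- f$thickness_mm / 10
    w <- w * exp(-.mu_rho(tab, energy) * attr(tab, "density") * t_cm)
  }
  if (!any(w > 0)) stop("filtered spectrum has no surviving fluence")
  spec <- data.frame(energy_keV = energy, relative_fluence = w / sum(w))
  class(spec) <- c("xray_spectrum", "data.frame")
  spec
}

#' Read a spectrum from a delimited table
#'
#' Columns \code{energy_keV} and \code{relative_fluence}, header
#' mandatory; lets a measured or externally modelled spectrum replace the
#' built-in tube model.
#'
#' @param path file path.
#' @return an \code{xray_spectrum}.
#' @export
read_spectrum_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#")
  need <- c("energy_keV", "relative_fluence")
  if (!all(need %in% names(tab)))
    stop("spectrum table must have columns ", paste(need, collapse = ", "))
  if (any(tab$relative_fluence < 0)) stop("negative fluence weight")
  tab$relative_fluence <- tab$relative_fluence / sum(tab$relative_fluence)
  class(tab) <- c("xray_spectrum", "data.frame")
  tab
}

#' Sample photon energies from a spectrum
#'
#' @param spectrum an \code{xray_spectrum}.
#' @param n number of draws.
#' @return photon energies in keV.
#' @export
sample_spectrum <- function(spectrum, n) {
  sample(spectrum$energy_keV, n, replace = TRUE,
         prob = spectrum$relative_fluence)
}

#' Silicon partial interaction coefficients
#'
#' @return data frame with photoelectric, incoherent and coherent mass
#'   interaction coefficients of silicon versus energy (approximate
#'   fixture).
#' @export
si_cross_sections <- function() {
  utils::read.delim(.extdata("si_cross_sections.tsv"), comment.char = "#")
}

#' Interaction-type probabilities in silicon
#'
#' Relative probabilities of photoelectric, Compton (incoherent) and
#' Rayleigh (coherent) interactions at the given photon energies,
#' proportional to the partial cross sections (log-log interpolated).
#'
#' @param photon_energy photon energies in keV (vectorised).
#' @param tables cross-section table, default the packaged silicon
#'   fixture.
#' @return matrix with columns \code{photoelectric}, \code{compton},
#'   \code{rayleigh}; rows sum to 1.
#' @export
interaction_probabilities <- function(photon_energy, tables = si_cross_sections()) {
  rng <- range(tables$energy_keV)
  if (any(photon_energy < rng[1] | photon_energy > rng[2]))
    stop(sprintf("photon energy outside the cross-section table range [%g, %g] keV",
                 rng[1], rng[2]))
  li <- function(col)
    exp(stats::approx(log(tables$energy_keV), log(tables[[col]]),
                      xout = log(photon_energy))$y)
  p <- cbind(photoelectric = li("photoelectric"),
             compton = li("incoherent"),
             rayleigh = li("coherent"))
  p / rowSums(p)
}

#' Classify primary interactions by type
#'
#' Draws an interaction type per photon with probabilities proportional
#' to the silicon partial cross sections at that photon's energy.
#'
#' @inheritParams interaction_probabilities
#' @return factor with levels \code{photoelectric}, \code{compton},
#'   \code{rayleigh}.
#' @export
classify_interaction <- function(photon_energy, tables = si_cross_sections()) {
  p <- interaction_probabilities(photon_energy, tables)
  u <- stats::runif(length(photon_energy))
  kind <- ifelse(u < p[, 1], "photoelectric",
                 ifelse(u < p[, 1] + p[, 2], "compton", "rayleigh"))
  factor(kind, levels = c("photoelectric", "compton", "rayleigh"))
}
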