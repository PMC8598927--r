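# Electronic-noise and lowest-threshold readout model.
#
# Noise is applied to the integrated per-strip energy (the readout chain
# itself is not simulated): independent Gaussian perturbations per strip,
# no inter-strip correlation.  The lowest threshold zeroes sub-threshold
# strips before the charge-cloud fit; an event is registered if at least
# one strip survives.

#' Readout configuration
#'
#' @param noise_sigma electronic noise standard deviation per strip, keV.
#' @param threshold lowest threshold, keV (default 4 sigma = 0.88 keV).
#' @param sampling_interval comparator sampling interval in seconds,
#'   used only by the analytic noise-count-rate estimate.
#' @return list of class \code{readout_config}.
#' @export
readout_config <- function(noise_sigma = 0.22, threshold = 4 * noise_sigma,
                           sampling_interval = 10e-9) {
  stopifnot(noise_sigma >= 0, threshold >= 0, sampling_interval > 0)
  structure(list(noise_sigma = noise_sigma, threshold = threshold,
                 sampling_interval = sampling_interval),
            class = "readout_config")
}

#' Add electronic noise to pixel signals
#'
#' Independent Gaussian noise per strip; no correlation between strips.
#' Accepts a single signal vector, a \code{pixel_signals} object or an
#' events-by-strips matrix.
#'
#' @param signals numeric vector, matrix or \code{pixel_signals}.
#' @param config a \code{\link{readout_config}}.
#' @return same shape as the input, with noise added to the strip
#'   energies (a \code{pixel_signals}' backside entry is untouched).
#' @export
add_electronic_noise <- function(signals, config = readout_config()) {
  if (config$noise_sigma == 0) return(signals)
  if (inherits(signals, "pixel_signals")) {
    signals$energies <- signals$energies +
      stats::rnorm(length(signals$energies), sd = config$noise_sigma)
    return(signals)
  }
  signals + stats::rnorm(length(signals), sd = config$noise_sigma)
}

#' Apply the lowest threshold
#'
#' Strips below the threshold are set to zero; an event is registered if
#' at least one strip is at or above the threshold.  Idempotent.
#'
#' @param signals numeric vector or events-by-strips matrix.
#' @param config a \code{\link{readout_config}}.
#' @return list with \code{signals} (thresholded, same shape) and
#'   \code{registered} (logical, per event).
#' @export
apply_lowest_threshold <- function(signals, config = readout_config()) {
  if (inherits(signals, "pixel_signals")) {
    r <- apply_lowest_threshold(signals$energies, config)
    signals$energies <- r$signals
    return(list(signals = signals, registered = r$registered))
  }
  s <- as.matrix(signals)
  keep <- s >= config$threshold
  out <- ifelse(keep, s, 0)
  registered <- apply(keep, 1, any)
  if (is.vector(signals) || is.null(dim(signals))) {
    out <- as.vector(out); registered <- any(keep)
  }
  list(signals = out, registered = registered)
}

#' Expected interval between noise counts
#'
#' For a comparator sampled every \code{sampling_interval} against a
#' threshold on a Gaussian noise amplitude, the expected time between
#' noise counts is sampling_interval / P(exceedance).  The default
#' counts two-sided exceedance |N(0, sigma)| > threshold; at the 4 sigma
#' threshold and 10 ns sampling this gives about 158 us (the one-sided
#' convention, available via \code{sides = 1}, gives twice that).
#'
#' @param config a \code{\link{readout_config}}.
#' @param sides 2 (two-sided, default) or 1.
#' @return expected interval in seconds (Inf when sigma is 0).
#' @export
expected_noise_count_interval <- function(config = readout_config(),
                                          sides = 2) {
  stopifnot(sides %in% c(1, 2), config$threshold > 0)
  if (config$noise_sigma == 0) return(Inf)
  p <- sides * stats::pnorm(-config$threshold / config$noise_sigma)
  config$sampling_interval / p
}
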