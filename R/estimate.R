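# Subpixel interaction-position estimation.
#
# Per event, a Gaussian f(x) = a exp(-(x - b)^2 / (2 c^2)) is fitted to
# the 51 (strip centre, strip energy) points, assuming each strip's
# signal was deposited at the strip's x centre.  b estimates the
# interaction x; the width c grows with charge diffusion and therefore
# with interaction depth.  A power-law calibration c_fit(y) =
# alpha y^beta + gamma, fitted on the (c, true depth) scatter of the
# dataset, is inverted to estimate the depth: widths below c_fit(0) or
# above c_fit(thickness) map to the mean true depth of such events.

#' Fit a Gaussian to a charge cloud
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' a exp(-(x - b)^2 / (2 c^2)) to the per-strip energies at the strip
#' centres, including zero strips.  With noise and a threshold present,
#' b can be bound-constrained (any real signal lies within a few strips
#' of the illuminated pixel, so far-out maxima are noise); without
#' noise no limits are used.
#'
#' A single-strip event is degenerate: b is the strip centre and c is
#' reported at a small positive floor (the cloud is narrower than the
#' strip resolves).  Two-strip events are also weakly determined - an
#' exact interpolant exists for an interval of widths, so the optimiser
#' settles at the narrow end of that interval; such events typically
#' fall below the calibration's lower width bound and take the
#' boundary-mean depth arm of the estimator.
#'
#' @param signals numeric vector of per-strip energies (keV), or a
#'   \code{pixel_signals}.
#' @param geometry a \code{\link{detector_geometry}}.
#' @param b_limits optional c(lo, hi) bounds on b in micrometres.
#' @param c_floor lower bound / degenerate value for c, micrometres.
#' @param max_iter,ftol optimiser controls.
#' @return list of class \code{gaussian_fit}: \code{a} (keV), \code{b}
#'   (um), \code{c} (um), \code{converged}, \code{degenerate},
#'   \code{n_nonzero_pixels}.
#' @export
fit_charge_cloud_gaussian <- function(signals, geometry = detector_geometry(),
                                      b_limits = NULL, c_floor = 0.1,
                                      max_iter = 200L, ftol = 1e-10) {
  if (inherits(signals, "pixel_signals")) signals <- signals$energies
  stopifnot(length(signals) == geometry$n_strips)
  xs <- strip_centers(geometry)
  nz <- which(signals > 0)
  if (!length(nz))
    stop("all strip signals are zero; check the registered flag before fitting")
  mk <- function(a, b, c, converged, degenerate = FALSE)
    structure(list(a = a, b = b, c = c, converged = converged,
                   degenerate = degenerate, n_nonzero_pixels = length(nz)),
              class = "gaussian_fit")
  clamp_b <- function(b)
    if (is.null(b_limits)) b else min(max(b, b_limits[1]), b_limits[2])
  if (length(nz) == 1L)
    return(mk(signals[nz], clamp_b(xs[nz]), c_floor, TRUE, TRUE))

  w <- signals / sum(signals)
  b0 <- clamp_b(sum(w * xs))
  c0 <- max(sqrt(max(sum(w * (xs - b0)^2), 0)), 1)
  a0 <- max(signals)
  lower <- c(0, if (is.null(b_limits)) -Inf else b_limits[1], c_floor)
  upper <- c(Inf, if (is.null(b_limits)) Inf else b_limits[2], Inf)

  resid <- function(p) p[1] * exp(-(xs - p[2])^2 / (2 * p[3]^2)) - signals
  jac <- function(p) {
    g <- exp(-(xs - p[2])^2 / (2 * p[3]^2))
    cbind(g,
          p[1] * g * (xs - p[2]) / p[3]^2,
          p[1] * g * (xs - p[2])^2 / p[3]^3)
  }
  fit <- try(suppressWarnings(minpack.lm::nls.lm(
    par = c(a0, b0, c0), lower = lower, upper = upper,
    fn = resid, jac = jac,
    control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = ftol,
                                         ptol = ftol))), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(mk(a0, b0, c0, FALSE))
  p <- fit$par
  mk(p[1], p[2], abs(p[3]), fit$info %in% 1:4)
}

#' Fit charge clouds for a whole dataset
#'
#' @param signals events-by-strips matrix of energies (keV).
#' @inheritParams fit_charge_cloud_gaussian
#' @return data frame with columns \code{a}, \code{b}, \code{c},
#'   \code{converged}, \code{degenerate}, \code{n_nonzero_pixels}; rows
#'   with an all-zero signal vector are NA.
#' @export
fit_charge_clouds <- function(signals, geometry = detector_geometry(),
                              b_limits = NULL, c_floor = 0.1) {
  n <- nrow(signals)
  out <- data.frame(a = rep(NA_real_, n), b = NA_real_, c = NA_real_,
                    converged = NA, degenerate = NA,
                    n_nonzero_pixels = NA_integer_)
  for (i in seq_len(n)) {
    if (!any(signals[i, ] > 0)) next
    f <- fit_charge_cloud_gaussian(signals[i, ], geometry, b_limits, c_floor)
    out[i, ] <- list(f$a, f$b, f$c, f$converged, f$degenerate,
                     f$n_nonzero_pixels)
  }
  out
}

#' Calibrate the width-depth relation
#'
#' Least-squares fit of c = alpha y^beta + gamma (alpha, beta, gamma > 0,
#' hence monotone increasing) to the (width, true depth) scatter of a
#' simulated dataset.  Widths below the exclusion cutoff - degenerate
#' near-single-strip fits - are excluded from the curve fit.  The mean
#' true depth of events whose width falls below c_fit(0) or above
#' c_fit(thickness) is recorded for the out-of-range arms of the
#' position estimator.
#'
#' @param widths fitted Gaussian widths c, micrometres.
#' @param depths true interaction depths y, micrometres.
#' @param exclusion_cutoff width cutoff in micrometres (4 for the
#'   noiseless analysis, 6.6 with noise and threshold).
#' @param thickness wafer thickness, micrometres.
#' @param min_samples minimum retained samples.
#' @return object of class \code{calibration_curve} with fields
#'   \code{alpha}, \code{beta}, \code{gamma}, \code{c_at_0},
#'   \code{c_at_max}, \code{mean_y_below}, \code{mean_y_above},
#'   \code{exclusion_cutoff}, \code{thickness}, \code{n_fit}.
#' @export
calibrate_width_curve <- function(widths, depths, exclusion_cutoff = 4,
                                  thickness = 500, min_samples = 100L) {
  ok <- is.finite(widths) & is.finite(depths)
  widths <- widths[ok]; depths <- depths[ok]
  keep <- widths >= exclusion_cutoff
  if (sum(keep) < min_samples)
    stop(sprintf("only %d samples above the %g um exclusion cutoff (need >= %d)",
                 sum(keep), exclusion_cutoff, min_samples))
  cw <- widths[keep]; y <- depths[keep]

  gamma0 <- max(min(cw) * 0.9, 1e-3)
  beta0 <- 0.5
  alpha0 <- max((stats::quantile(cw, 0.95) - gamma0) / thickness^beta0, 1e-6)
  resid <- function(p) p[1] * y^p[2] + p[3] - cw
  fit <- minpack.lm::nls.lm(
    par = c(alpha0, beta0, gamma0),
    lower = c(1e-9, 0.05, 1e-9), upper = c(Inf, 5, Inf),
    fn = resid,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- fit$par
  cfit <- function(yy) p[1] * yy^p[2] + p[3]

  below <- widths < cfit(0)
  above <- widths > cfit(thickness)
  structure(list(alpha = p[1], beta = p[2], gamma = p[3],
                 c_at_0 = cfit(0), c_at_max = cfit(thickness),
                 mean_y_below = if (any(below)) mean(depths[below]) else 0,
                 mean_y_above = if (any(above)) mean(depths[above]) else thickness,
                 exclusion_cutoff = exclusion_cutoff,
                 thickness = thickness, n_fit = sum(keep)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "calibration_curve: c(y) = %.4g y^%.3f + %.3f um (n = %d, cutoff %g um)\n",
    x$alpha, x$beta, x$gamma, x$n_fit, x$exclusion_cutoff))
  cat(sprintf("  c(0) = %.3f, c(%g) = %.3f; ybar below = %.1f, above = %.1f um\n",
              x$c_at_0, x$thickness, x$c_at_max, x$mean_y_below,
              x$mean_y_above))
  invisible(x)
}

#' Calibration curve value
#'
#' @param calibration a \code{calibration_curve}.
#' @param depth depths y in micrometres.
#' @return calibrated width c_fit(y) in micrometres.
#' @export
width_at_depth <- function(calibration, depth) {
  calibration$alpha * depth^calibration$beta + calibration$gamma
}

#' Estimate interaction positions
#'
#' The estimator: Xe = b; for the depth, widths below c_fit(0) map to
#' the mean depth of such events, widths above c_fit(thickness) to the
#' corresponding upper mean, and anything in between inverts the
#' monotone power law in closed form, clamped to [0, thickness].
#'
#' @param fits a \code{gaussian_fit}, or a data frame from
#'   \code{\link{fit_charge_clouds}} (columns b, c).
#' @param calibration a \code{calibration_curve}.
#' @return data frame with columns \code{Xe}, \code{Ye} (um) and
#'   \code{branch} (factor: below / invert / above).
#' @export
estimate_position <- function(fits, calibration) {
  if (inherits(fits, "gaussian_fit")) fits <- data.frame(b = fits$b, c = fits$c)
  b <- fits$b; cw <- fits$c
  ye <- rep(NA_real_, length(b))
  branch <- rep(NA_character_, length(b))
  below <- !is.na(cw) & cw < calibration$c_at_0
  above <- !is.na(cw) & cw > calibration$c_at_max
  mid <- !is.na(cw) & !below & !above
  ye[below] <- calibration$mean_y_below
  ye[above] <- calibration$mean_y_above
  ye[mid] <- ((cw[mid] - calibration$gamma) / calibration$alpha)^
    (1 / calibration$beta)
  ye <- pmin(pmax(ye, 0), calibration$thickness)
  branch[below] <- "below"; branch[above] <- "above"; branch[mid] <- "invert"
  data.frame(Xe = b, Ye = ye,
             branch = factor(branch, levels = c("below", "invert", "above")))
}

#' Persist / load a calibration curve as JSON
#'
#' @param calibration a \code{calibration_curve}.
#' @param path file path.
#' @return \code{write_calibration}: \code{path} invisibly;
#'   \code{read_calibration}: the restored \code{calibration_curve}.
#' @export
write_calibration <- function(calibration, path) {
  jsonlite::write_json(unclass(calibration), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "calibration_curve")
}
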