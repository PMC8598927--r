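# Study orchestration: simulate -> (noise/threshold) -> fit -> calibrate
# -> estimate -> resolution metrics, with file outputs and seeds.
#
# Both analysis variants run on the same simulated noiseless signals, as
# one physical dataset processed two ways: the ideal analysis fits all
# strips with no constraints (4 um calibration cutoff), the noisy
# analysis adds per-strip Gaussian noise, applies the lowest threshold,
# constrains the fitted centre to the five-strip window around the
# illuminated pixel and uses the 6.6 um calibration cutoff.  Metrics for
# the noisy analysis are computed over registered events only.

#' Analyse a simulated dataset
#'
#' Runs charge-cloud fits, width-depth calibration, position estimation
#' and resolution metrics on a \code{compton_dataset}, either as the
#' ideal (noiseless, thresholdless) analysis or with the electronic
#' noise and lowest-threshold readout applied first.
#'
#' @param dataset a \code{compton_dataset}.
#' @param noise if TRUE, apply \code{readout} noise + threshold and the
#'   b-limits; if FALSE run the ideal analysis.
#' @param readout a \code{\link{readout_config}} (noisy analysis).
#' @param exclusion_cutoff calibration width cutoff in micrometres;
#'   default 4 (ideal) or 6.6 (noisy).
#' @param b_limit_strips half-width of the allowed fitted-centre window,
#'   in strips around the illuminated pixel (noisy analysis; 2.5 strips
#'   = +/- 30 um at 12 um pitch).
#' @param bin_width_x,bin_width_y PSF histogram bin widths, micrometres.
#' @param zero_pad_factor MTF padding factor.
#' @param calibration optionally reuse an existing
#'   \code{calibration_curve} instead of calibrating on this dataset
#'   (split-sample operation).
#' @return list of class \code{study_analysis}: \code{fits},
#'   \code{calibration}, \code{estimates} (with event_id and truth),
#'   \code{registered}, \code{stats}, \code{psf_x}, \code{psf_y},
#'   \code{mtf_x}, \code{mtf_y}, \code{noise}.
#' @export
analyze_dataset <- function(dataset, noise = FALSE,
                            readout = readout_config(),
                            exclusion_cutoff = if (noise) 6.6 else 4,
                            b_limit_strips = 2.5,
                            bin_width_x = 0.2, bin_width_y = 5,
                            zero_pad_factor = 8,
                            calibration = NULL) {
  geometry <- dataset$geometry
  signals <- dataset$signals
  events <- dataset$events
  b_limits <- NULL
  registered <- rep(TRUE, nrow(signals))
  if (noise) {
    signals <- add_electronic_noise(signals, readout)
    thr <- apply_lowest_threshold(signals, readout)
    signals <- thr$signals
    registered <- thr$registered
    b_limits <- c(-1, 1) * b_limit_strips * geometry$pitch +
      strip_centers(geometry, geometry$reference_strip)
  }

  fits <- fit_charge_clouds(signals, geometry, b_limits = b_limits)
  use <- registered & !is.na(fits$c)
  if (is.null(calibration))
    calibration <- calibrate_width_curve(fits$c[use], events$Y0[use],
                                         exclusion_cutoff = exclusion_cutoff,
                                         thickness = geometry$thickness)
  est <- estimate_position(fits[use, ], calibration)
  est <- cbind(event_id = events$event_id[use], est,
               events[use, c("X0", "Y0")],
               b = fits$b[use], c = fits$c[use],
               converged = fits$converged[use])

  stats <- position_error_stats(est, est)
  psf_x <- psf_from_errors(est$Xe - est$X0, bin_width_x)
  psf_y <- psf_from_errors(est$Ye - est$Y0, bin_width_y)
  structure(list(fits = fits, calibration = calibration, estimates = est,
                 registered = registered, stats = stats,
                 psf_x = psf_x, psf_y = psf_y,
                 mtf_x = mtf_from_psf(psf_x, zero_pad_factor),
                 mtf_y = mtf_from_psf(psf_y, zero_pad_factor),
                 noise = noise),
            class = "study_analysis")
}

#' @export
print.study_analysis <- function(x, ...) {
  cat(sprintf("study_analysis (%s): %d/%d events registered\n",
              if (x$noise) "noise + threshold" else "ideal",
              sum(x$registered), length(x$registered)))
  print(x$stats)
  cat(sprintf("  FWHM x %.3f um, y %.2f um; MTF 5%% crossing x %.4g, y %.4g lp/cm\n",
              x$psf_x$fwhm, x$psf_y$fwhm,
              x$mtf_x$resolution_at_5pct, x$mtf_y$resolution_at_5pct))
  invisible(x)
}

#' Study configuration
#'
#' Bundles all sub-configurations of a full simulation study.  Defaults
#' reproduce the reference study conditions: 100,000 Compton
#' interactions in the central pixel of a 51-strip, 12 um pitch, 500 um
#' wafer at 200 V, 140 kVp heavily filtered spectrum, 2 ns transport
#' step, 0.22 keV noise with a 0.88 keV lowest threshold.
#'
#' @param n_events number of Compton events.
#' @param seed master RNG seed.
#' @param geometry,physics,track,transport,readout component configs.
#' @param spectrum_kvp,spectrum_filters tube model parameters.
#' @param noise_enabled run the noisy analysis pass.
#' @param output_dir where \code{\link{run_full_study}} writes its
#'   artifacts (NULL: no files).
#' @return list of class \code{study_config}.
#' @export
study_config <- function(n_events = 100000L, seed = 1L,
                         geometry = detector_geometry(),
                         physics = transport_physics(),
                         track = track_config(),
                         transport = transport_config(),
                         readout = readout_config(),
                         spectrum_kvp = 140,
                         spectrum_filters = NULL,
                         noise_enabled = TRUE,
                         output_dir = NULL) {
  n_events <- as.integer(n_events)
  if (is.na(n_events) || n_events <= 0L)
    stop("n_events must be a positive integer")
  stopifnot(inherits(geometry, "detector_geometry"),
            inherits(physics, "transport_physics"),
            inherits(track, "track_config"),
            inherits(transport, "transport_config"),
            inherits(readout, "readout_config"))
  structure(list(n_events = n_events, seed = as.integer(seed),
                 geometry = geometry, physics = physics, track = track,
                 transport = transport, readout = readout,
                 spectrum_kvp = spectrum_kvp,
                 spectrum_filters = spectrum_filters,
                 noise_enabled = isTRUE(noise_enabled),
                 output_dir = output_dir),
            class = "study_config")
}

#' Run a full simulation study
#'
#' Simulates the event set once, runs the ideal analysis and (optionally)
#' the noisy analysis on the same signals, and writes the event table,
#' calibrations, estimate tables, summary statistics and PSF/MTF curves
#' to \code{output_dir} when one is configured.  Re-running with the
#' same configuration and seed reproduces the results exactly.
#'
#' @param config a \code{\link{study_config}}.
#' @return list of class \code{study_report}: \code{dataset},
#'   \code{ideal}, \code{noisy} (a \code{study_analysis} or NULL),
#'   \code{summary} (named numeric vector of the headline metrics),
#'   \code{config}.
#' @export
run_full_study <- function(config = study_config()) {
  spectrum <- if (is.null(config$spectrum_filters))
    build_filtered_spectrum(kvp = config$spectrum_kvp)
  else build_filtered_spectrum(kvp = config$spectrum_kvp,
                               filters = config$spectrum_filters)
  dataset <- simulate_compton_dataset(
    config$n_events, geometry = config$geometry, physics = config$physics,
    spectrum = spectrum, track_cfg = config$track,
    config = config$transport, seed = config$seed)
  ideal <- analyze_dataset(dataset, noise = FALSE)
  noisy <- if (config$noise_enabled)
    analyze_dataset(dataset, noise = TRUE, readout = config$readout)
  else NULL

  summarise <- function(a, tag) {
    v <- c(a$stats$mae_x, a$stats$rms_x, a$stats$mae_y, a$stats$rms_y,
           a$psf_x$fwhm, a$psf_y$fwhm,
           a$mtf_x$resolution_at_5pct, a$mtf_y$resolution_at_5pct)
    names(v) <- paste0(tag, c("_mae_x_um", "_rms_x_um", "_mae_y_um",
                              "_rms_y_um", "_fwhm_x_um", "_fwhm_y_um",
                              "_mtf5_x_lp_cm", "_mtf5_y_lp_cm"))
    v
  }
  summary <- summarise(ideal, "ideal")
  if (!is.null(noisy)) summary <- c(summary, summarise(noisy, "noise"))

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    pth <- function(f) file.path(config$output_dir, f)
    write_event_table(dataset, pth("events.tsv"))
    write_calibration(ideal$calibration, pth("calibration_ideal.json"))
    utils::write.table(ideal$estimates, pth("estimates_ideal.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(noisy)) {
      write_calibration(noisy$calibration, pth("calibration_noise.json"))
      utils::write.table(noisy$estimates, pth("estimates_noise.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    for (nm in c("ideal", if (!is.null(noisy)) "noise")) {
      a <- if (nm == "ideal") ideal else noisy
      for (ax in c("x", "y")) {
        p <- a[[paste0("psf_", ax)]]
        utils::write.table(
          data.frame(center_um = p$bin_centers, density_per_um = p$density),
          pth(sprintf("psf_%s_%s.tsv", nm, ax)),
          sep = "\t", row.names = FALSE, quote = FALSE)
        m <- a[[paste0("mtf_", ax)]]
        utils::write.table(
          data.frame(frequency_lp_cm = m$frequency_lp_cm, mtf = m$mtf),
          pth(sprintf("mtf_%s_%s.tsv", nm, ax)),
          sep = "\t", row.names = FALSE, quote = FALSE)
      }
    }
    jsonlite::write_json(
      list(seed = config$seed, n_events = config$n_events,
           interaction_counts = as.list(dataset$interaction_counts),
           summary = as.list(summary)),
      pth("report.json"), auto_unbox = TRUE, digits = NA)
  }
  structure(list(dataset = dataset, ideal = ideal, noisy = noisy,
                 summary = summary, config = config),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study_report: %d events (seed %d)\n",
              x$config$n_events, x$config$seed))
  print(round(x$summary, 3))
  invisible(x)
}

#' Write / read an event table
#'
#' Delimited text export of a simulated dataset: one row per event with
#' the ground truth and the 51 per-strip energies
#' (columns \code{s_01..s_51}, keV).
#'
#' @param dataset a \code{compton_dataset}.
#' @param path file path.
#' @return \code{write_event_table}: \code{path} invisibly.
#' @export
write_event_table <- function(dataset, path) {
  s <- as.data.frame(dataset$signals)
  names(s) <- sprintf("s_%02d", seq_len(ncol(s)))
  tab <- cbind(dataset$events[, c("event_id", "photon_energy",
                                  "recoil_energy", "X0", "Y0",
                                  "deposited_keV")], s)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @param geometry geometry to attach (must match the written table).
#' @return \code{read_event_table}: a \code{compton_dataset} (without
#'   interaction counts).
#' @export
read_event_table <- function(path, geometry = detector_geometry()) {
  tab <- utils::read.delim(path)
  sc <- grep("^s_", names(tab))
  if (length(sc) != geometry$n_strips)
    stop("event table has ", length(sc), " signal columns, expected ",
         geometry$n_strips)
  structure(list(events = tab[, setdiff(names(tab), names(tab)[sc])],
                 signals = unname(as.matrix(tab[, sc])),
                 interaction_counts = NULL, geometry = geometry),
            class = "compton_dataset")
}

#' Deterministic fixture dataset
#'
#' A small reproducible event set for tests and examples.  The first
#' event is a handcrafted worked example - an 8 keV recoil at
#' (-4.8, 20) um in the illuminated pixel - and the remaining events are
#' drawn from the full simulation chain.
#'
#' @param n_events total number of events (at most 10,000).
#' @param seed RNG seed.
#' @return a \code{compton_dataset}.
#' @export
generate_fixture_dataset <- function(n_events = 200L, seed = 20211118L) {
  stopifnot(n_events >= 1, n_events <= 10000)
  geometry <- detector_geometry()
  set.seed(seed)
  ds <- simulate_compton_dataset(n_events, geometry = geometry)
  # worked-example event: 8 keV at X0 = -4.8 um, Y0 = 20 um
  ev <- simulate_event(list(photon_energy = 60, recoil_energy = 8,
                            origin = c(-4.8, 20)), geometry = geometry)
  ds$signals[1, ] <- ev$signals$energies
  ds$events[1, c("photon_energy", "recoil_energy", "X0", "Y0",
                 "deposited_keV")] <-
    list(60, 8, -4.8, 20, ev$signals$deposited_energy)
  ds$events$fluorescence[1] <- FALSE
  ds
}
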