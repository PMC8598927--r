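# Drift-diffusion transport of electron-hole pairs and Shockley-Ramo
# signal induction.
#
# Holes drift along the field (-y) to the strip electrodes, electrons
# against it to the backside.  The canonical signal computation is the
# endpoint form of the Ramo theorem: the charge induced on strip k by a
# carrier of charge q moving from its creation point to its collection
# point is q [W_k(end) - W_k(start)].  When both carriers of a pair are
# fully collected the pair algebra telescopes to one full charge on the
# strip where the hole lands and nothing elsewhere, so the default fast
# mode transports holes only and bins their landing positions; the
# explicit delta-W mode (both carriers, interpolated weighting map) and
# the time-resolved trace mode are retained as validation routes.

#' Transport configuration
#'
#' @param dt time step in seconds (default 2 ns).
#' @param max_steps per-carrier step cap; exceeding it signals a
#'   physics/configuration bug.
#' @param carrier_mode \code{"fast"} (holes only, landing histogram) or
#'   \code{"endpoint"} (both carriers, delta-W via the weighting map).
#' @return list of class \code{transport_config}.
#' @export
transport_config <- function(dt = 2e-9, max_steps = 100000L,
                             carrier_mode = c("fast", "endpoint")) {
  stopifnot(dt > 0, max_steps > 0)
  structure(list(dt = dt, max_steps = as.integer(max_steps),
                 carrier_mode = match.arg(carrier_mode)),
            class = "transport_config")
}

# Gaussian step standard deviation sqrt(2 D dt), in micrometres.
.step_sigma_um <- function(physics, carrier, dt)
  sqrt(2 * diffusion_coefficient(carrier, physics) * dt) * 1e4

# Signed drift displacement per step, micrometres (negative = towards the
# strips).
.drift_step_um <- function(physics, carrier, field, dt) {
  v <- drift_speed(field$magnitude, carrier, physics) * 1e4 * dt
  if (carrier == "hole") -v else v
}

#' Advance carriers by one drift-diffusion step
#'
#' Each coordinate advances by the field-dependent drift displacement
#' (holes along -y, electrons along +y) plus an independent Gaussian
#' diffusion step of variance 2 D dt sampled separately in x and in y.
#' No boundary handling is applied; see
#' \code{\link{transport_to_collection}} for stepping to collection.
#'
#' @param positions n-by-2 matrix (or data frame) of (x, y) in
#'   micrometres.
#' @param kinds character vector, \code{"electron"} or \code{"hole"},
#'   recycled.
#' @param field a \code{\link{drift_field}}.
#' @param physics a \code{\link{transport_physics}}.
#' @param dt time step in seconds.
#' @return updated n-by-2 matrix.
#' @export
step_carriers <- function(positions, kinds, field, physics, dt) {
  p <- as.matrix(positions)
  n <- nrow(p)
  kinds <- rep_len(kinds, n)
  out <- p
  for (k in c("electron", "hole")) {
    sel <- kinds == k
    if (!any(sel)) next
    ns <- sum(sel)
    sig <- .step_sigma_um(physics, k, dt)
    out[sel, 1] <- p[sel, 1] + stats::rnorm(ns, sd = sig)
    out[sel, 2] <- p[sel, 2] + .drift_step_um(physics, k, field, dt) +
      stats::rnorm(ns, sd = sig)
  }
  out
}

# Pure-R stepping of a few carriers with full trajectory recording;
# mirrors the compiled endpoint kernel (same model, different RNG call
# order).
.transport_traced <- function(x0, y0, kind, geometry, field, physics, config) {
  dirn <- if (kind == "hole") -1 else 1
  drift <- abs(.drift_step_um(physics, kind, field, config$dt)) * dirn
  sig <- .step_sigma_um(physics, kind, config$dt)
  ycross <- if (dirn < 0) 0 else geometry$thickness
  xh <- geometry$x_halfwidth
  traj <- list(c(0, x0, y0))
  x <- x0; y <- y0; t <- 0; steps <- 0
  while (if (dirn < 0) y > 0 else y < geometry$thickness) {
    steps <- steps + 1
    if (steps > config$max_steps) stop("carrier exceeded max_steps")
    xn <- x + stats::rnorm(1, sd = sig)
    yn <- y + drift + stats::rnorm(1, sd = sig)
    crossed <- if (dirn < 0) yn <= ycross else yn >= ycross
    if (crossed) {
      frac <- (y - ycross) / (y - yn)
      x <- x + frac * (xn - x); y <- ycross; t <- t + frac * config$dt
    } else {
      yn <- min(max(yn, 0), geometry$thickness)
      x <- xn; y <- yn; t <- t + config$dt
    }
    if (x < -xh) x <- -2 * xh - x
    if (x > xh) x <- 2 * xh - x
    traj[[length(traj) + 1]] <- c(t, x, y)
    if (crossed) break
  }
  m <- do.call(rbind, traj)
  colnames(m) <- c("time", "x", "y")
  m
}

#' Transport carriers to their collection electrodes
#'
#' Steps every carrier with the drift-diffusion model until its y
#' coordinate crosses its collection boundary (strip plane for holes,
#' backside for electrons); the final partial step is linearly
#' interpolated onto the boundary and the side walls reflect.
#'
#' @param positions n-by-2 matrix or data frame of starting (x, y), or a
#'   \code{carrier_ensemble} (whose pair positions are duplicated into
#'   one electron and one hole each).
#' @param kinds \code{"electron"}/\code{"hole"} per carrier (ignored for
#'   ensembles).
#' @param geometry a \code{\link{detector_geometry}}.
#' @param field a \code{\link{drift_field}}.
#' @param physics a \code{\link{transport_physics}}.
#' @param config a \code{\link{transport_config}}.
#' @param record_traces if TRUE, slower pure-R stepping is used and the
#'   full trajectories are attached as the \code{"traces"} attribute
#'   (list of time/x/y matrices).
#' @return data frame with columns \code{kind}, \code{x0}, \code{y0},
#'   \code{x_end}, \code{y_end}, \code{time} (seconds).
#' @export
transport_to_collection <- function(positions, kinds = "hole",
                                    geometry = detector_geometry(),
                                    field = drift_field(geometry),
                                    physics = transport_physics(),
                                    config = transport_config(),
                                    record_traces = FALSE) {
  if (inherits(positions, "carrier_ensemble")) {
    pp <- as.matrix(positions$pair_positions)
    positions <- rbind(pp, pp)
    kinds <- rep(c("hole", "electron"), each = nrow(pp))
  }
  p <- as.matrix(positions)
  n <- nrow(p)
  kinds <- rep_len(kinds, n)
  out <- data.frame(kind = kinds, x0 = p[, 1], y0 = p[, 2],
                    x_end = NA_real_, y_end = NA_real_, time = NA_real_)
  if (record_traces) {
    traces <- vector("list", n)
    for (i in seq_len(n)) {
      m <- .transport_traced(p[i, 1], p[i, 2], kinds[i], geometry, field,
                             physics, config)
      traces[[i]] <- m
      last <- m[nrow(m), ]
      out$x_end[i] <- last[["x"]]; out$y_end[i] <- last[["y"]]
      out$time[i] <- last[["time"]]
    }
    attr(out, "traces") <- traces
    return(out)
  }
  for (k in c("electron", "hole")) {
    sel <- kinds == k
    if (!any(sel)) next
    dirn <- if (k == "hole") -1L else 1L
    res <- .cc_transport_endpoints(
      p[sel, 1], p[sel, 2],
      abs(.drift_step_um(physics, k, field, config$dt)), dirn,
      .step_sigma_um(physics, k, config$dt), config$dt,
      geometry$thickness, geometry$x_halfwidth, config$max_steps)
    out$x_end[sel] <- res[, 1]
    out$y_end[sel] <- if (dirn < 0) 0 else geometry$thickness
    out$time[sel] <- res[, 2]
  }
  out
}

#' Induced current trace on one strip
#'
#' Shockley-Ramo current i(t) = q Ew(x, y) . v(t) along a recorded
#' trajectory, with the weighting field Ew = -grad W interpolated from
#' the solved map.  Each stored step is subdivided for the quadrature so
#' that the time integral reproduces q [W(end) - W(start)] to within the
#' interpolation error.
#'
#' @param trace a time/x/y matrix from
#'   \code{\link{transport_to_collection}} with
#'   \code{record_traces = TRUE}.
#' @param map a \code{weighting_map}.
#' @param strip strip index.
#' @param kind \code{"electron"} or \code{"hole"} (sets the sign of q).
#' @param n_sub minimum quadrature subdivisions per stored step; steps
#'   are additionally subdivided to at most \code{sub_length} um so that
#'   the drift step (tens of um per 2 ns) resolves the steep weighting
#'   field near the electrodes.
#' @param sub_length maximum sub-segment length in micrometres.
#' @return data frame with \code{time} (s), \code{current} (A) and
#'   \code{dt} (s) per sample.
#' @export
induced_current_trace <- function(trace, map, strip,
                                  kind = c("hole", "electron"), n_sub = 4L,
                                  sub_length = 0.25) {
  kind <- match.arg(kind)
  if (is.null(trace) || nrow(trace) < 2)
    stop("trajectory absent; transport with record_traces = TRUE for trace mode")
  q <- if (kind == "hole") .kc$electron_charge else -.kc$electron_charge
  t0 <- trace[-nrow(trace), "time"]; t1 <- trace[-1, "time"]
  x0 <- trace[-nrow(trace), "x"]; x1 <- trace[-1, "x"]
  y0 <- trace[-nrow(trace), "y"]; y1 <- trace[-1, "y"]
  keep <- t1 > t0
  t0 <- t0[keep]; t1 <- t1[keep]; x0 <- x0[keep]; x1 <- x1[keep]
  y0 <- y0[keep]; y1 <- y1[keep]
  if (!length(t0))
    return(data.frame(time = numeric(), current = numeric(), dt = numeric()))
  # velocity is constant within a step; midpoint quadrature on
  # sub-segments short enough to follow the weighting-field variation
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  ns <- pmax(as.integer(n_sub), as.integer(ceiling(len / sub_length)))
  seg <- rep(seq_along(t0), ns)
  frac <- (unlist(lapply(ns, seq_len)) - 0.5) / ns[seg]
  tm <- t0[seg] + frac * (t1 - t0)[seg]
  xm <- x0[seg] + frac * (x1 - x0)[seg]
  ym <- y0[seg] + frac * (y1 - y0)[seg]
  vx <- ((x1 - x0) / (t1 - t0))[seg]   # um/s
  vy <- ((y1 - y0) / (t1 - t0))[seg]
  g <- weighting_gradient(map, strip, xm, ym)
  # current flowing into the electrode: i = q dW/dt = -q Ew . v, so the
  # time integral equals the collected charge q [W(end) - W(start)]
  data.frame(time = tm,
             current = -q * (g$Ex * vx + g$Ey * vy),
             dt = ((t1 - t0) / ns)[seg])
}

# Snap a strip-plane landing point into the nearest electrode so that the
# weighting potential there is exactly 0 or 1; field lines terminate on
# electrodes, a uniform-field carrier landing in a gap is attributed to
# the nearest electrode edge.
.snap_to_electrode <- function(geometry, x) {
  k <- strip_at_x(geometry, x)
  cx <- strip_centers(geometry, k)
  half <- geometry$electrode_width / 2 * 0.999
  pmin(pmax(x, cx - half), cx + half)
}

#' Integrate per-strip induced energies for one event
#'
#' Converts collected carrier paths into the per-strip induced signal in
#' keV (one pair's full charge carries the pair creation energy, 3.6 eV).
#' The default \code{"landing"} method bins hole landing positions into
#' strips, which the pair algebra of the endpoint Ramo form makes exact
#' under full collection; \code{"delta_w"} evaluates
#' q [W_k(end) - W_k(start)] per carrier and strip on the weighting map
#' (requires \code{map}).  Hole landings in an inter-electrode gap are
#' snapped to the nearest electrode edge.
#'
#' @param paths data frame from \code{\link{transport_to_collection}}.
#' @param geometry a \code{\link{detector_geometry}}.
#' @param map a \code{weighting_map} (delta-W method only).
#' @param method \code{"landing"} or \code{"delta_w"}.
#' @param w_ionization pair energy in eV.
#' @return object of class \code{pixel_signals}: list with
#'   \code{energies} (keV per strip), \code{backside_energy} (keV not
#'   attributed to any strip) and \code{deposited_energy} (keV).
#' @export
integrated_pixel_energies <- function(paths, geometry, map = NULL,
                                      method = c("landing", "delta_w"),
                                      w_ionization = 3.6) {
  method <- match.arg(method)
  holes <- paths[paths$kind == "hole", , drop = FALSE]
  pair_kev <- w_ionization / 1000
  deposited <- nrow(holes) * pair_kev
  if (method == "landing") {
    strips <- strip_at_x(geometry, holes$x_end)
    e <- tabulate(strips, nbins = geometry$n_strips) * pair_kev
  } else {
    if (is.null(map)) stop("delta_w method needs a solved weighting map")
    e <- numeric(geometry$n_strips)
    xe <- ifelse(paths$kind == "hole",
                 .snap_to_electrode(geometry, paths$x_end), paths$x_end)
    q <- ifelse(paths$kind == "hole", 1, -1)
    for (k in seq_len(geometry$n_strips)) {
      dW <- weighting_value(map, k, xe, paths$y_end) -
        weighting_value(map, k, paths$x0, paths$y0)
      e[k] <- sum(q * dW) * pair_kev
    }
  }
  structure(list(energies = e,
                 backside_energy = deposited - sum(e),
                 deposited_energy = deposited),
            class = "pixel_signals")
}

#' Simulate one Compton event end to end
#'
#' Composes track-to-pairs conversion, carrier transport and signal
#' integration into a noiseless event record.
#'
#' @param interaction list with \code{photon_energy} (keV),
#'   \code{recoil_energy} (keV) and \code{origin} c(X0, Y0) (um).
#' @param track an \code{electron_track} (generated from the interaction
#'   if NULL).
#' @param geometry,field,physics,config simulation components.
#' @param map weighting map, only needed for
#'   \code{carrier_mode = "endpoint"}.
#' @param track_cfg a \code{\link{track_config}}.
#' @return list of class \code{event_record}: \code{true_position},
#'   \code{deposited_energy}, \code{signals} (a \code{pixel_signals}),
#'   \code{registered} (set later by the readout).
#' @export
simulate_event <- function(interaction, track = NULL,
                           geometry = detector_geometry(),
                           field = drift_field(geometry),
                           physics = transport_physics(),
                           config = transport_config(),
                           map = NULL, track_cfg = track_config()) {
  stopifnot(interaction$recoil_energy > 0)
  if (is.null(track))
    track <- generate_electron_track(interaction$recoil_energy,
                                     interaction$origin, geometry, track_cfg)
  ens <- track_to_pairs(track, track_cfg$w_ionization)
  if (config$carrier_mode == "fast") {
    paths <- transport_to_collection(as.matrix(ens$pair_positions), "hole",
                                     geometry, field, physics, config)
    sig <- integrated_pixel_energies(paths, geometry, method = "landing",
                                     w_ionization = track_cfg$w_ionization)
  } else {
    paths <- transport_to_collection(ens, geometry = geometry, field = field,
                                     physics = physics, config = config)
    sig <- integrated_pixel_energies(paths, geometry, map = map,
                                     method = "delta_w",
                                     w_ionization = track_cfg$w_ionization)
  }
  structure(list(true_position = c(X0 = unname(interaction$origin[1]),
                                   Y0 = unname(interaction$origin[2])),
                 photon_energy = interaction$photon_energy,
                 deposited_energy = track$total_energy,
                 signals = sig, registered = NA),
            class = "event_record")
}

#' Simulate a Compton interaction dataset
#'
#' The end-to-end noiseless simulation: photon energies are sampled from
#' the filtered spectrum, interaction types are drawn from the silicon
#' cross sections until \code{n_events} Compton interactions have been
#' collected (photoelectric and Rayleigh primaries are counted but not
#' position-analysed), recoil energies follow the Klein-Nishina
#' distribution, origins are uniform in the illuminated pixel, electron
#' tracks are generated and every hole is drift-diffusion transported to
#' the strip plane.
#'
#' @param n_events number of Compton events to simulate.
#' @param geometry,physics,field simulation components.
#' @param spectrum an \code{xray_spectrum}.
#' @param track_cfg a \code{\link{track_config}}.
#' @param config a \code{\link{transport_config}}.
#' @param pixel illuminated strip index.
#' @param seed optional integer; when given, \code{set.seed(seed)} makes
#'   the dataset reproducible.
#' @param chunk_size events transported per block (memory control).
#' @return list of class \code{compton_dataset}: \code{events} (data
#'   frame with event_id, photon_energy, recoil_energy, X0, Y0,
#'   deposited_keV, fluorescence), \code{signals} (n-by-n_strips matrix,
#'   keV), \code{interaction_counts} (named totals of sampled primaries
#'   by type), \code{geometry}.
#' @export
simulate_compton_dataset <- function(n_events,
                                     geometry = detector_geometry(),
                                     physics = transport_physics(),
                                     field = drift_field(geometry),
                                     spectrum = build_filtered_spectrum(),
                                     track_cfg = track_config(),
                                     config = transport_config(),
                                     pixel = geometry$reference_strip,
                                     seed = NULL, chunk_size = 250L) {
  n_events <- as.integer(n_events)
  if (n_events <= 0) stop("n_events must be a positive integer")
  if (!is.null(seed)) set.seed(seed)

  counts <- c(photoelectric = 0, compton = 0, rayleigh = 0)
  e_compton <- numeric(0)
  while (length(e_compton) < n_events) {
    m <- max(2L * (n_events - length(e_compton)), 1000L)
    e <- sample_spectrum(spectrum, m)
    kind <- classify_interaction(e)
    counts <- counts + table(kind)[names(counts)]
    e_compton <- c(e_compton, e[kind == "compton"])
  }
  e_compton <- e_compton[seq_len(n_events)]

  recoil <- sample_compton_recoil(e_compton)
  recoil <- pmax(recoil, 1e-3)          # keep at least one pair per event
  origin <- sample_event_origin(geometry, n_events, pixel)

  signals <- matrix(0, n_events, geometry$n_strips)
  fluor <- logical(n_events)
  drift <- abs(.drift_step_um(physics, "hole", field, config$dt))
  sig_um <- .step_sigma_um(physics, "hole", config$dt)
  for (lo in seq(1L, n_events, by = chunk_size)) {
    hi <- min(lo + chunk_size - 1L, n_events)
    idx <- lo:hi
    dep <- .generate_tracks(recoil[idx], origin$X0[idx], origin$Y0[idx],
                            geometry, track_cfg)
    fluor[idx] <- idx %in% (lo - 1L + unique(dep$event[dep$fluorescence]))
    np <- as.integer(round(dep$energy_eV / track_cfg$w_ionization))
    keep <- np > 0
    ev <- rep.int(dep$event[keep], np[keep])
    hx <- rep.int(dep$x[keep], np[keep])
    hy <- rep.int(dep$y[keep], np[keep])
    ends <- .cc_transport_endpoints(hx, hy, drift, -1L, sig_um, config$dt,
                                    geometry$thickness, geometry$x_halfwidth,
                                    config$max_steps)
    strips <- strip_at_x(geometry, ends[, 1])
    nc <- length(idx)
    acc <- tabulate((ev - 1L) * geometry$n_strips + strips,
                    nbins = nc * geometry$n_strips)
    signals[idx, ] <- t(matrix(acc, nrow = geometry$n_strips)) *
      track_cfg$w_ionization / 1000
  }

  structure(list(
    events = data.frame(event_id = seq_len(n_events),
                        photon_energy = e_compton, recoil_energy = recoil,
                        X0 = origin$X0, Y0 = origin$Y0,
                        deposited_keV = rowSums(signals),
                        fluorescence = fluor),
    signals = signals,
    interaction_counts = counts,
    geometry = geometry), class = "compton_dataset")
}

#' @export
print.compton_dataset <- function(x, ...) {
  cat(sprintf(
    "compton_dataset: %d events, mean deposited %.2f keV, %d strips\n",
    nrow(x$events), mean(x$events$deposited_keV), ncol(x$signals)))
  invisible(x)
}
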