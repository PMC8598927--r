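# Two-dimensional weighting potential of a strip electrode, solved on a
# regular grid by a direct sparse factorisation of the 5-point Laplacian.
#
# The weighting potential W of an electrode is the solution of Laplace's
# equation with that electrode at unit potential and every other electrode
# (neighbouring strips and the backside plane) grounded.  By the
# Shockley-Ramo theorem the charge a carrier induces on the electrode while
# moving from A to B is q [W(B) - W(A)].  Strips are translationally
# equivalent, so a single reference map shifted by multiples of the pitch
# serves all strips.

#' Solve the 2D weighting potential of the reference strip
#'
#' Solves Laplace's equation on \code{[-x_halfwidth, x_halfwidth] x
#' [0, thickness]} with Dirichlet data on the electrodes: the reference
#' strip electrode at 1, all other strip electrodes and the backside at 0.
#' The oxide gaps between strip electrodes carry either an insulating
#' (zero normal derivative) condition or a linear Dirichlet interpolation
#' between the adjacent electrode values.  The lateral truncation
#' boundaries are insulating by default: the single-strip potential is
#' laterally almost flat a few pitches away from the strip (pitch much
#' smaller than thickness), so a zero-gradient wall perturbs it far less
#' than grounding it; \code{sidewall_bc = "grounded"} is available for
#' error bracketing by comparison.
#'
#' The discrete system is assembled in symmetric positive definite form
#' (Neumann rows are half-weighted) and factorised with a sparse Cholesky
#' decomposition; the discrete residual is checked after the solve.
#'
#' @param geometry a \code{\link{detector_geometry}}.
#' @param grid_spacing grid step in micrometres; must divide the pitch,
#'   the electrode half-gap and the thickness to within rounding.
#' @param x_halfwidth lateral half extent of the solved domain in
#'   micrometres (default 5 pitches; the map is extended by symmetry /
#'   truncation when evaluated for distant strips).
#' @param gap_bc boundary condition on the inter-electrode gaps:
#'   \code{"neumann"} (insulating, default) or \code{"linear"} (Dirichlet
#'   ramp between electrode values).
#' @param sidewall_bc \code{"neumann"} (default) or \code{"grounded"}.
#' @param residual_tol maximum admissible discrete residual.
#' @return an object of class \code{weighting_map} with fields \code{x},
#'   \code{y} (grid coordinates), \code{values} (nx by ny matrix, in
#'   [0, 1]), \code{grid_spacing}, \code{reference_strip},
#'   \code{geometry}, and the boundary-condition choices.
#' @export
solve_weighting_potential <- function(geometry, grid_spacing = 0.25,
                                      x_halfwidth = 5 * geometry$pitch,
                                      gap_bc = c("neumann", "linear"),
                                      sidewall_bc = c("neumann", "grounded"),
                                      residual_tol = 1e-8) {
  gap_bc <- match.arg(gap_bc)
  sidewall_bc <- match.arg(sidewall_bc)
  h <- grid_spacing
  stopifnot(h > 0, x_halfwidth > 0)
  near_int <- function(z) abs(z - round(z)) < 1e-9
  if (!near_int(geometry$thickness / h) || !near_int(geometry$pitch / h) ||
      !near_int(2 * x_halfwidth / h))
    stop("grid_spacing must divide the pitch, the thickness and the domain width")

  x <- seq(-x_halfwidth, x_halfwidth, by = h)
  y <- seq(0, geometry$thickness, by = h)
  nx <- length(x); ny <- length(y)

  # Dirichlet values on the front surface: NA marks gap nodes.
  centers <- strip_centers(geometry)
  centers <- centers[abs(centers) <= x_halfwidth + geometry$electrode_width / 2]
  front <- rep(NA_real_, nx)
  on_ref <- abs(x) <= geometry$electrode_width / 2 + 1e-9
  front[on_ref] <- 1
  for (cx in centers[centers != 0])
    front[abs(x - cx) <= geometry$electrode_width / 2 + 1e-9] <- 0
  if (gap_bc == "linear" && anyNA(front)) {
    known <- which(!is.na(front))
    front <- stats::approx(x[known], front[known], xout = x, rule = 2)$y
  }

  # Node classification: TRUE = unknown.
  unknown <- matrix(TRUE, nx, ny)
  unknown[, ny] <- FALSE                         # backside, W = 0
  unknown[, 1] <- is.na(front)                   # electrodes are Dirichlet
  if (sidewall_bc == "grounded") unknown[c(1, nx), ] <- FALSE

  dir_val <- matrix(0, nx, ny)
  dir_val[, 1] <- ifelse(is.na(front), 0, front)

  idx <- matrix(0L, nx, ny)
  idx[unknown] <- seq_len(sum(unknown))
  n_unknown <- sum(unknown)

  ii <- which(unknown, arr.ind = TRUE)
  ui <- ii[, 1]; uj <- ii[, 2]
  # A node on a Neumann boundary gets weight 1/2 per boundary touched so
  # that the ghost-node-eliminated stencil stays symmetric.
  on_wall <- (sidewall_bc == "neumann") & (ui == 1L | ui == nx)
  on_front <- uj == 1L
  s <- 0.5^(on_wall + on_front)

  rows <- idx[cbind(ui, uj)]
  ti <- rows; tj <- rows; tv <- 4 * s          # diagonal
  rhs <- numeric(n_unknown)

  add_dir <- function(sel, w, vi, vj) {
    if (any(sel))
      rhs[rows[sel]] <<- rhs[rows[sel]] +
        w[sel] * dir_val[cbind(vi[sel], vj[sel])]
  }
  neighbour <- function(di, dj) {
    vi <- ui + di; vj <- uj + dj
    w <- s
    # Step that would leave the domain across a Neumann boundary: mirror it
    # onto the opposite neighbour (ghost elimination).
    out <- vi < 1L | vi > nx | vj < 1L
    if (any(out)) { vi[out] <- ui[out] - di; vj[out] <- uj[out] - dj }
    inside <- vj <= ny
    kn <- inside & unknown[cbind(pmin(vi, nx), pmin(vj, ny))]
    if (any(kn)) {
      ti <<- c(ti, rows[kn]); tj <<- c(tj, idx[cbind(vi[kn], vj[kn])])
      tv <<- c(tv, -w[kn])
    }
    dirich <- inside & !kn
    add_dir(dirich, w, vi, vj)
  }
  neighbour(-1L, 0L); neighbour(1L, 0L); neighbour(0L, -1L); neighbour(0L, 1L)

  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tv,
                            dims = c(n_unknown, n_unknown))
  A <- Matrix::forceSymmetric(A, uplo = "L")
  w_unknown <- as.numeric(Matrix::solve(A, rhs))

  res <- max(abs(A %*% w_unknown - rhs))
  if (!is.finite(res) || res > residual_tol)
    stop(sprintf("weighting-potential solve did not converge: residual %.3e", res))

  values <- dir_val
  values[unknown] <- w_unknown
  values <- pmin(pmax(values, 0), 1)

  structure(list(x = x, y = y, values = values, grid_spacing = h,
                 x_halfwidth = x_halfwidth,
                 reference_strip = geometry$reference_strip,
                 gap_bc = gap_bc, sidewall_bc = sidewall_bc,
                 residual = res, geometry = geometry),
            class = "weighting_map")
}

#' @export
print.weighting_map <- function(x, ...) {
  cat(sprintf(
    "weighting_map: %d x %d grid, h = %g um, |x| <= %g um, gaps %s, walls %s\n",
    length(x$x), length(x$y), x$grid_spacing, x$x_halfwidth, x$gap_bc,
    x$sidewall_bc))
  invisible(x)
}

# Bilinear interpolation of the reference map at (xs, y); xs already in the
# reference strip's frame.  Points beyond the lateral extent of the solved
# domain are assigned the truncation value 0 (the strip potential there is
# below the truncation error of the map itself).
.interp_map <- function(map, xs, y) {
  h <- map$grid_spacing
  out <- numeric(length(xs))
  inside <- xs >= map$x[1] & xs <= map$x[length(map$x)]
  if (!any(inside)) return(out)
  xs <- xs[inside]; yv <- y[inside]
  fi <- (xs - map$x[1]) / h
  fj <- (yv - map$y[1]) / h
  i0 <- pmin(pmax(floor(fi), 0), length(map$x) - 2)
  j0 <- pmin(pmax(floor(fj), 0), length(map$y) - 2)
  tx <- fi - i0; ty <- fj - j0
  v <- map$values
  n <- nrow(v)
  base <- (j0 * n) + i0 + 1
  w <- (1 - tx) * (1 - ty) * v[base] +
    tx * (1 - ty) * v[base + 1] +
    (1 - tx) * ty * v[base + n] +
    tx * ty * v[base + n + 1]
  out[inside] <- w
  out
}

#' Evaluate the weighting potential of a strip
#'
#' Bilinear interpolation of the reference map shifted to the requested
#' strip: W_k(x, y) = W_ref(x - (k - ref) pitch, y).  Points must lie
#' inside the wafer in y; points beyond the lateral extent of the solved
#' map evaluate to 0 (the truncation value).
#'
#' @param map a \code{weighting_map}.
#' @param strip strip index.
#' @param x,y coordinates in micrometres (vectorised, recycled).
#' @return dimensionless weighting potential in [0, 1].
#' @export
weighting_value <- function(map, strip, x, y) {
  g <- map$geometry
  stopifnot(strip >= 1L, strip <= g$n_strips)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  if (any(y < 0 | y > g$thickness))
    stop("point outside the wafer in y")
  xs <- x - (strip - map$reference_strip) * g$pitch
  .interp_map(map, xs, y)
}

#' Weighting field of a strip
#'
#' Central-difference gradient of the interpolated weighting potential;
#' the weighting field is -grad W.  Units 1/um.
#'
#' @inheritParams weighting_value
#' @param h finite-difference step in micrometres.
#' @return list with components \code{Ex}, \code{Ey} of the weighting
#'   field (-dW/dx, -dW/dy).
#' @export
weighting_gradient <- function(map, strip, x, y, h = map$grid_spacing / 2) {
  g <- map$geometry
  yc <- pmin(pmax(y, h), g$thickness - h)
  list(
    Ex = -(weighting_value(map, strip, x + h, yc) -
             weighting_value(map, strip, x - h, yc)) / (2 * h),
    Ey = -(weighting_value(map, strip, x, yc + h) -
             weighting_value(map, strip, x, yc - h)) / (2 * h)
  )
}

#' Export / import a weighting map
#'
#' The grid is written as a dense whitespace-delimited text matrix
#' (rows = x, columns = y) next to a JSON sidecar holding the grid
#' spacing, extents, boundary conditions and geometry, so a solved map
#' can be cached across runs.
#'
#' @param map a \code{weighting_map}.
#' @param file base path; \code{<file>.grid} and \code{<file>.json} are
#'   written.
#' @return \code{write_weighting_map}: the base path, invisibly.
#' @export
write_weighting_map <- function(map, file) {
  utils::write.table(map$values, paste0(file, ".grid"),
                     row.names = FALSE, col.names = FALSE)
  meta <- list(grid_spacing = map$grid_spacing,
               x_halfwidth = map$x_halfwidth,
               reference_strip = map$reference_strip,
               gap_bc = map$gap_bc, sidewall_bc = map$sidewall_bc,
               residual = map$residual,
               geometry = unclass(map$geometry))
  jsonlite::write_json(meta, paste0(file, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_weighting_map
#' @param file base path previously passed to \code{write_weighting_map}.
#' @return \code{read_weighting_map}: the reconstructed
#'   \code{weighting_map}.
#' @export
read_weighting_map <- function(file) {
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(utils::read.table(paste0(file, ".grid")))
  dimnames(vals) <- NULL
  geo <- do.call(detector_geometry, meta$geometry[c(
    "n_strips", "pitch", "electrode_width", "thickness", "bias_voltage",
    "resistivity_kohm_cm")])
  structure(list(
    x = seq(-meta$x_halfwidth, meta$x_halfwidth, by = meta$grid_spacing),
    y = seq(0, geo$thickness, by = meta$grid_spacing),
    values = vals, grid_spacing = meta$grid_spacing,
    x_halfwidth = meta$x_halfwidth, reference_strip = meta$reference_strip,
    gap_bc = meta$gap_bc, sidewall_bc = meta$sidewall_bc,
    residual = meta$residual, geometry = geo), class = "weighting_map")
}
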