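# Forward model: magnetic field of a current dipole in a homogeneous
# conducting sphere (Sarvas closed form). Radial dipoles and dipoles at the
# sphere centre are magnetically silent -- both fall out of the formula
# exactly, which the beamformer and its tests rely on.

MU0 <- 4 * pi * 1e-7

# Gain matrix (sensors x 3) of a dipole at `loc` (mm, head frame) for the
# three Cartesian unit moments, projected on each sensor's orientation.
# Units: tesla per A*m. Positions are converted to metres internally.
sarvas_gain <- function(positions_mm, orientations, loc_mm, centre_mm = c(0, 0, 0)) {
  rs <- sweep(positions_mm, 2L, centre_mm) * 1e-3      # sensors, metres
  r0 <- (as.numeric(loc_mm) - centre_mm) * 1e-3
  if (sum(r0^2) == 0) return(matrix(0, nrow(rs), 3L))
  a <- sweep(rs, 2L, r0)                               # r - r0
  an <- row_norms(a)
  rn <- row_norms(rs)
  dot_r0_r <- as.numeric(rs %*% r0)
  dot_a_r <- rowSums(a * rs)
  F <- an * (rn * an + rn^2 - dot_r0_r)
  c1 <- an^2 / rn + dot_a_r / an + 2 * an + 2 * rn
  c2 <- an + 2 * rn + dot_a_r / an
  gradF <- c1 * rs - outer(c2, r0)
  out <- matrix(0, nrow(rs), 3L)
  for (k in 1:3) {
    q <- c(0, 0, 0); q[k] <- 1
    cr <- cross3(q, r0)                                # q x r0
    Bk <- (outer(F, cr) - as.numeric(rs %*% cr) * gradF) * (MU0 / (4 * pi * F^2))
    out[, k] <- rowSums(Bk * orientations)
  }
  out
}

#' Lead fields on a source grid in a conducting sphere
#'
#' Evaluates the Sarvas closed-form magnetic field of a current dipole in
#' a homogeneous conducting sphere at every sensor, for unit moments along
#' the three Cartesian axes, at every grid voxel.
#'
#' @param array A [make_sensor_array()] result; sensors must lie outside
#'   the sphere.
#' @param grid A [make_source_grid()] result; voxels must lie inside the
#'   sphere.
#' @param sphere_centre Sphere centre, mm (default origin).
#' @param sphere_radius Sphere radius, mm (default 100).
#' @return Object of class `meg_leadfield`: list with `gains` (array
#'   sensors x voxels x 3, tesla per A*m), `grid`, `array`,
#'   `sphere_centre`, `sphere_radius`.
#' @export
sphere_leadfield <- function(array, grid, sphere_centre = c(0, 0, 0),
                             sphere_radius = 100) {
  stopifnot(inherits(array, "meg_sensor_array"), inherits(grid, "meg_source_grid"))
  vr <- row_norms(sweep(grid$voxels, 2L, sphere_centre))
  if (any(vr >= sphere_radius))
    stop_config("%d grid voxel(s) lie on or outside the %g mm conductor sphere",
                sum(vr >= sphere_radius), sphere_radius)
  sr <- row_norms(sweep(array$positions, 2L, sphere_centre))
  if (any(sr <= sphere_radius))
    stop_config("all sensors must lie outside the conductor sphere")
  nv <- n_voxels(grid)
  nc <- n_sensors(array)
  gains <- array(0, dim = c(nc, nv, 3L))
  for (v in seq_len(nv)) {
    gains[, v, ] <- sarvas_gain(array$positions, array$orientations,
                                grid$voxels[v, ], sphere_centre)
  }
  structure(list(gains = gains, grid = grid, array = array,
                 sphere_centre = sphere_centre, sphere_radius = sphere_radius),
            class = "meg_leadfield")
}

#' @export
print.meg_leadfield <- function(x, ...) {
  d <- dim(x$gains)
  cat(sprintf("<meg_leadfield> %d sensors x %d voxels x 3 (sphere r=%g mm)\n",
              d[1L], d[2L], x$sphere_radius))
  invisible(x)
}

#' Sensor-gain provider for arbitrary source locations
#'
#' Returns a function mapping a source location (3-vector, mm) to the
#' sensor gain vector of a tangentially oriented unit dipole at that
#' location, using the conducting-sphere model. Used as the default
#' forward model of [simulate_recording()].
#'
#' @inheritParams sphere_leadfield
#' @param orientation Optional fixed dipole moment direction (3-vector);
#'   by default a deterministic tangential direction is chosen at each
#'   location (radial moments are silent in the sphere model).
#' @return `function(loc_mm) -> numeric(n_sensors)`.
#' @export
make_leadfield_provider <- function(array, sphere_centre = c(0, 0, 0),
                                    sphere_radius = 100, orientation = NULL) {
  force(array); force(sphere_centre); force(orientation)
  function(loc_mm) {
    g <- sarvas_gain(array$positions, array$orientations, loc_mm, sphere_centre)
    ori <- orientation
    if (is.null(ori)) {
      r0 <- as.numeric(loc_mm) - sphere_centre
      ori <- cross3(c(0, 0, 1), r0)
      if (sqrt(sum(ori^2)) < 1e-9 * max(1, sqrt(sum(r0^2))))
        ori <- cross3(c(1, 0, 0), r0)
      nrm <- sqrt(sum(ori^2))
      ori <- if (nrm > 0) ori / nrm else c(1, 0, 0)
    }
    as.numeric(g %*% ori)
  }
}
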