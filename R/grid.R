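#' Volumetric source grid inside the head sphere
#'
#' A regular lattice of voxel centres (mm, head frame: origin at the
#' midpoint of the preauricular points, x towards the right preauricular
#' point, y towards the nasion, z up) restricted to a sphere. The default
#' 6 mm spacing with a 96 mm mask radius yields ~17,000 voxels.
#'
#' @param spacing Voxel spacing in mm (> 0, default 6).
#' @param radius Mask radius in mm (default 96); all voxels lie strictly
#'   inside the conducting sphere used by [sphere_leadfield()], whose
#'   default radius is 100 mm.
#' @param centre Sphere centre, mm (default origin).
#' @return Object of class `meg_source_grid`: list with `voxels`
#'   (n x 3 matrix of centres), `spacing`, `radius`, `centre`.
#' @examples
#' g <- make_source_grid(spacing = 20)
#' nrow(g$voxels)
#' @export
make_source_grid <- function(spacing = 6, radius = 96, centre = c(0, 0, 0)) {
  if (!is_number(spacing) || spacing <= 0) stop_config("spacing must be > 0")
  if (!is_number(radius) || radius <= 0) stop_config("radius must be > 0")
  ax <- seq(-floor(radius / spacing), floor(radius / spacing)) * spacing
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  dimnames(g) <- NULL
  keep <- row_norms(g) <= radius
  voxels <- sweep(g[keep, , drop = FALSE], 2L, centre, "+")
  structure(list(voxels = voxels, spacing = spacing, radius = radius,
                 centre = centre),
            class = "meg_source_grid")
}

#' @export
print.meg_source_grid <- function(x, ...) {
  cat(sprintf("<meg_source_grid> %d voxels, %g mm spacing, %g mm radius\n",
              nrow(x$voxels), x$spacing, x$radius))
  invisible(x)
}

n_voxels <- function(grid) nrow(grid$voxels)

#' Nearest grid voxel to a point
#' @param grid A [make_source_grid()] result.
#' @param point 3-vector, mm.
#' @return Voxel index (1-based).
#' @export
nearest_voxel <- function(grid, point) {
  d2 <- rowSums(sweep(grid$voxels, 2L, as.numeric(point))^2)
  which.min(d2)
}
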