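#' Construct a whole-head MEG sensor array
#'
#' Places magnetometer channels quasi-uniformly on the upper part of a
#' helmet sphere using a golden-angle (Fibonacci) spiral, with radially
#' oriented sensing directions. The default channel count emulates a
#' 275-channel whole-head system; the geometry is a generic helmet, not a
#' vendor-accurate layout.
#'
#' @param n_channels Number of channels (>= 4). Default 275.
#' @param helmet_radius Helmet sphere radius in mm. Must exceed the radius
#'   of the conducting head sphere used by the forward model (default head
#'   sphere is 100 mm, see [sphere_leadfield()]).
#' @param seed Integer seed; sets the azimuthal phase of the spiral so that
#'   distinct seeds give distinct (but individually deterministic) layouts.
#' @return An object of class `meg_sensor_array`: a list with
#'   `channel_ids` (character), `positions` (n x 3 matrix, mm, head frame),
#'   `orientations` (n x 3 unit vectors, radial) and `helmet_radius`.
#' @examples
#' arr <- make_sensor_array(275, 120, seed = 7)
#' range(sqrt(rowSums(arr$orientations^2)))  # all exactly 1
#' @export
make_sensor_array <- function(n_channels = 275L, helmet_radius = 120, seed = 1L) {
  if (!is_number(n_channels) || n_channels < 4)
    stop_config("n_channels must be >= 4 (got %s)", format(n_channels))
  if (!is_number(helmet_radius) || helmet_radius <= 0)
    stop_config("helmet_radius must be a positive length in mm")
  n <- as.integer(n_channels)
  phase <- with_seed(as.integer(seed), runif(1L, 0, 2 * pi))
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n) - 0.5
  # cos(polar angle) from the vertex down to ~105 degrees: upper head coverage
  u <- 1 - (1 - cos(105 * pi / 180)) * i / n
  s <- sqrt(pmax(0, 1 - u^2))
  phi <- phase + golden * (seq_len(n) - 1L)
  ori <- cbind(s * cos(phi), s * sin(phi), u)
  ori <- ori / row_norms(ori)
  structure(
    list(
      channel_ids = sprintf("MEG%03d", seq_len(n)),
      positions = ori * helmet_radius,
      orientations = ori,
      helmet_radius = helmet_radius
    ),
    class = "meg_sensor_array"
  )
}

#' @export
print.meg_sensor_array <- function(x, ...) {
  cat(sprintf("<meg_sensor_array> %d channels, helmet radius %.0f mm, radial orientations\n",
              length(x$channel_ids), x$helmet_radius))
  invisible(x)
}

n_sensors <- function(array) length(array$channel_ids)
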