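# Closed-form cone geometry linking pile height, volume and angle of repose,
# plus the sphericity shape factor and the Brown-Richards orifice flow rate.
#
# Convention: the static angle of repose alpha is measured in DEGREES from
# the horizontal. All angles are converted to radians at this boundary only.
# With that convention a cone of height h has base radius r = h / tan(alpha):
# steeper piles (larger alpha) are narrower. This is the only reading
# consistent with the volume relation V = pi * h^3 / (3 * tan(alpha)^2) and
# its inverse h = (3 * V * tan(alpha)^2 / pi)^(1/3).

deg2rad <- function(deg) deg * pi / 180

.check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) ||
      any(alpha <= 0) || any(alpha >= 90)) {
    stop("`alpha` must be an angle of repose strictly between 0 and 90 degrees",
         call. = FALSE)
  }
  invisible(alpha)
}

.check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be strictly positive and finite", name),
         call. = FALSE)
  }
  invisible(x)
}

#' Sphericity index of a 2-D particle projection
#'
#' Computes the isoperimetric shape factor \eqn{\psi = 4\pi A_f / P_{Cr}^2},
#' where \eqn{A_f} is the projected area of the particle and \eqn{P_{Cr}}
#' its perimeter (in image work, the Crofton estimate from
#' [crofton_perimeter()]). A perfect circle has \eqn{\psi = 1}; all other
#' shapes are strictly below 1 in continuous geometry.
#'
#' Discretized silhouettes can yield raw values marginally above 1 because
#' the perimeter estimator is not exact on a pixel grid; such values are
#' clamped to 1 with a warning, and the unclamped value is kept in the
#' `"raw"` attribute of the result.
#'
#' @param projected_area projected particle area (length squared; pixels
#'   for binary masks). Must be positive.
#' @param perimeter particle perimeter in the same length unit. Must be
#'   positive.
#' @return Sphericity in (0, 1]. If clamping occurred, the raw value is
#'   attached as attribute `"raw"`.
#' @seealso [particle_sphericity()] for the mask-level wrapper,
#'   [classify_particle()] for the pellet/granule rule.
#' @examples
#' sphericity_index(pi, 2 * pi)   # circle of radius 1 -> exactly 1
#' sphericity_index(1, 4)         # unit square -> pi/4
#' @export
sphericity_index <- function(projected_area, perimeter) {
  .check_positive(projected_area, "projected_area")
  .check_positive(perimeter, "perimeter")
  psi <- 4 * pi * projected_area / perimeter^2
  if (any(psi > 1)) {
    raw <- psi
    psi <- pmin(psi, 1)
    warning("sphericity above 1 from discretization; clamped to 1 ",
            "(raw value kept in attr(, \"raw\"))", call. = FALSE)
    attr(psi, "raw") <- raw
  }
  psi
}

#' Cone base radius from height and angle of repose
#'
#' For a conical pile with flank angle `alpha` (degrees from the
#' horizontal), the base radius is `height / tan(alpha)`.
#'
#' @param height cone height (positive, any length unit).
#' @param alpha static angle of repose in degrees, in (0, 90).
#' @return Base radius in the unit of `height`.
#' @export
cone_radius <- function(height, alpha) {
  .check_positive(height, "height")
  .check_alpha(alpha)
  height / tan(deg2rad(alpha))
}

#' Cone volume from height and angle of repose
#'
#' `V = pi * h^3 / (3 * tan(alpha)^2)`, i.e. `(1/3) * pi * r^2 * h` with
#' `r = cone_radius(h, alpha)`.
#'
#' @inheritParams cone_radius
#' @return Volume in `height` units cubed.
#' @export
cone_volume <- function(height, alpha) {
  .check_positive(height, "height")
  .check_alpha(alpha)
  pi * height^3 / (3 * tan(deg2rad(alpha))^2)
}

#' Cone height from volume and angle of repose
#'
#' Inverts [cone_volume()]: `h = (3 * V * tan(alpha)^2 / pi)^(1/3)`. As a
#' function of volume this is a pure power law with exponent 1/3, which is
#' the theoretical basis for fitting pile-growth flow curves with
#' `y = a + b * t^c`.
#'
#' @param volume cone volume (positive).
#' @param alpha static angle of repose in degrees, in (0, 90).
#' @return Cone height; strictly increasing in `volume`.
#' @export
cone_height <- function(volume, alpha) {
  .check_positive(volume, "volume")
  .check_alpha(alpha)
  (3 * volume * tan(deg2rad(alpha))^2 / pi)^(1 / 3)
}

#' Ideal-cone power-law coefficients
#'
#' Under constant volumetric feed, pile height grows as
#' `h(V) = (3/pi)^(1/3) * tan(alpha)^(2/3) * V^(1/3)`, so a flow curve
#' proportional to pile height follows `b * t^c` with exponent exactly
#' 1/3 and a unit-scale proportionality factor
#' `b_geom = (3/pi)^(1/3) * tan(alpha)^(2/3)`. Calibration of `b_geom`
#' to a concrete pixel/volume scale is left to the user.
#'
#' @param alpha static angle of repose in degrees, in (0, 90).
#' @return List with components `b_geom` (positive, strictly increasing in
#'   `alpha`) and `c_geom` (always exactly 1/3).
#' @export
geometry_coefficients <- function(alpha) {
  .check_alpha(alpha)
  list(
    b_geom = (3 / pi)^(1 / 3) * tan(deg2rad(alpha))^(2 / 3),
    c_geom = 1 / 3
  )
}

#' Brown-Richards orifice flow rate
#'
#' Static mass flow through a funnel outlet,
#' `Q = K * A * sqrt(2 * g * h_bed) * rho_t`: `K` a material constant,
#' `A` the outlet cross-section, `h_bed` the powder-bed height above the
#' outlet, `rho_t` the powder density and `g` gravitational acceleration.
#' Used as the simulator's default volumetric feed once divided by density.
#'
#' @param K dimensionless material constant (> 0).
#' @param A outlet cross-section area (> 0).
#' @param h_bed powder bed height above the outlet (> 0).
#' @param rho_t powder density (> 0).
#' @param g gravitational acceleration (> 0); use units consistent with
#'   `A` and `h_bed`.
#' @return Mass flow rate `Q`.
#' @export
brown_richards_rate <- function(K, A, h_bed, rho_t, g = 9810) {
  .check_positive(K, "K")
  .check_positive(A, "A")
  .check_positive(h_bed, "h_bed")
  .check_positive(rho_t, "rho_t")
  .check_positive(g, "g")
  K * A * sqrt(2 * g * h_bed) * rho_t
}
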