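#' Surface electrode specification
#'
#' @param role `"different"` (active electrode over the target muscle) or
#'   `"indifferent"` (return electrode near the wrist).
#' @param shape `"circle"` or `"rectangle"`.
#' @param dimensions circle: diameter (mm); rectangle: c(width, height) mm
#'   where width runs along the circumference and height along the arm axis.
#' @param axial_pct axial position, % of LEH-RSP length (0-105).
#' @param radial_pct radial position, % of circumference counterclockwise from
#'   the reference line (0-100).
#' @param hydrogel_thickness hydrogel pad thickness, mm.
#' @param hydrogel_material hydrogel [material_spec()].
#' @return object of class `electrode_spec`.
#' @export
electrode_spec <- function(role = c("different", "indifferent"),
                           shape = c("circle", "rectangle"),
                           dimensions, axial_pct, radial_pct,
                           hydrogel_thickness = 1,
                           hydrogel_material = default_materials()$hydrogel) {
  role <- match.arg(role)
  shape <- match.arg(shape)
  assert_num(axial_pct, "axial_pct", lower = 0, upper = 105)
  if (radial_pct < 0 || radial_pct >= 100)
    stopf("'radial_pct' must be in [0, 100)")
  if (shape == "circle") {
    assert_num(dimensions, "dimensions", lower = .Machine$double.eps, len = 1)
  } else {
    assert_num(dimensions, "dimensions", lower = .Machine$double.eps, len = 2)
  }
  structure(list(role = role, shape = shape, dimensions = dimensions,
                 axial_pct = axial_pct, radial_pct = radial_pct,
                 hydrogel_thickness = hydrogel_thickness,
                 hydrogel_material = hydrogel_material),
            class = "electrode_spec")
}

#' @export
print.electrode_spec <- function(x, ...) {
  dim_txt <- if (x$shape == "circle") sprintf("diameter %g mm", x$dimensions)
             else sprintf("%g x %g mm", x$dimensions[1], x$dimensions[2])
  cat(sprintf("<electrode_spec> %s %s (%s) at axial %.2f%%, radial %.2f%%\n",
              x$role, x$shape, dim_txt, x$axial_pct, x$radial_pct))
  invisible(x)
}

#' Place an electrode on the phantom skin surface
#'
#' Computes the footprint of the electrode: its center lies on the skin at
#' arc-length `radial_pct`% counterclockwise from the reference line on the
#' circumference at `axial_pct`% of the LEH-RSP length. The footprint is
#' described in developed surface coordinates (arc length around the
#' circumference, distance along the axis) and carries a membership predicate
#' used by the voxelizer; the hydrogel pad of the stated thickness sits
#' outside the skin over the footprint.
#'
#' @param phantom a `forearm_phantom`.
#' @param spec an [electrode_spec()].
#' @return object of class `electrode_footprint` with the 3D center point,
#'   axial/angular extent, and a membership function `contains(z, theta)`.
#' @export
place_electrode <- function(phantom, spec) {
  ctr <- surface_point(phantom, spec$axial_pct, spec$radial_pct)
  if (spec$shape == "circle") {
    half_u <- spec$dimensions / 2   # along circumference
    half_v <- spec$dimensions / 2   # along axis
  } else {
    half_u <- spec$dimensions[1] / 2
    half_v <- spec$dimensions[2] / 2
  }
  if (2 * half_u > 0.5 * ctr$circumference)
    stopf("electrode footprint spans %.0f mm, more than 50%% of the %.0f mm circumference (electrode larger than arm)",
          2 * half_u, ctr$circumference)
  z_center <- ctr$point[3]
  theta_center <- ctr$theta
  circ <- ctr$circumference
  shape <- spec$shape
  # membership in developed surface coordinates; theta is the ellipse
  # parameter, converted to arc length on the center station's circumference
  arc_tab <- ellipse_arc_table(station_at(phantom, z_center)$skin,
                               phantom$reference_azimuth)
  arc_of <- function(theta) {
    th <- (theta - arc_tab$t[1]) %% (2 * pi) + arc_tab$t[1]
    approx(arc_tab$t, arc_tab$arc, xout = th, rule = 2)$y
  }
  arc_center <- arc_of(theta_center)
  contains <- function(z, theta) {
    u <- arc_of(theta) - arc_center
    u <- u - round(u / circ) * circ       # shorter way around
    v <- z - z_center
    if (shape == "circle") (u / half_u)^2 + (v / half_v)^2 <= 1
    else abs(u) <= half_u & abs(v) <= half_v
  }
  structure(list(spec = spec, center = ctr$point, z_center = z_center,
                 theta_center = theta_center, circumference = circ,
                 half_u = half_u, half_v = half_v, contains = contains),
            class = "electrode_footprint")
}

#' Packaged evaluation electrode positions
#'
#' The eight per-muscle active-electrode positions and the two shared
#' indifferent-electrode positions used for the strength-duration evaluation
#' (axial/radial percentages of the reference coordinate system).
#'
#' @param path optional CSV overriding the packaged table.
#' @return data.frame with one row per evaluated ROI.
#' @export
load_electrode_positions <- function(path = NULL) {
  read.csv(path %||% fixture_path("electrode_positions.csv"),
           stringsAsFactors = FALSE)
}

#' Default electrode pair for an evaluated muscle
#'
#' Returns the standard pair used in the evaluation: a round 25 mm-diameter
#' active electrode at the muscle's tabulated position and a 50 mm square
#' indifferent electrode near the wrist.
#'
#' @param muscle ROI code (e.g. `"ECU"`).
#' @param positions table from [load_electrode_positions()].
#' @return list with `active` and `indifferent` [electrode_spec()]s.
#' @export
default_electrode_pair <- function(muscle,
                                   positions = load_electrode_positions()) {
  row <- positions[positions$roi == muscle, , drop = FALSE]
  if (nrow(row) != 1L)
    stopf("unknown muscle code '%s' (no electrode position tabulated)", muscle)
  list(
    active = electrode_spec("different", "circle", 25,
                            axial_pct = row$diff_axial_pct,
                            radial_pct = row$diff_radial_pct),
    indifferent = electrode_spec("indifferent", "rectangle", c(50, 50),
                                 axial_pct = row$indiff_axial_pct,
                                 radial_pct = row$indiff_radial_pct)
  )
}
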