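# Ellipse primitives -------------------------------------------------------

#' Cross-section ellipse
#'
#' @param center 2D center, mm.
#' @param semi semi-axes (a, b), mm.
#' @param roll rotation of the major axis about the arm axis, rad.
#' @return object of class `ellipse2d`.
#' @export
ellipse2d <- function(center = c(0, 0), semi, roll = 0) {
  assert_num(center, "center", len = 2)
  assert_num(semi, "semi", lower = .Machine$double.eps, len = 2)
  structure(list(center = as.numeric(center), semi = as.numeric(semi),
                 roll = as.numeric(roll)), class = "ellipse2d")
}

# normalized radius rho: <= 1 inside, 1 on the boundary. x, y vectorized.
ellipse_rho <- function(e, x, y) {
  dx <- x - e$center[1]; dy <- y - e$center[2]
  cs <- cos(e$roll); sn <- sin(e$roll)
  u <- cs * dx + sn * dy
  v <- -sn * dx + cs * dy
  sqrt((u / e$semi[1])^2 + (v / e$semi[2])^2)
}

ellipse_contains <- function(e, x, y) ellipse_rho(e, x, y) <= 1

# boundary point at parametric angle t (vectorized)
ellipse_point <- function(e, t) {
  cs <- cos(e$roll); sn <- sin(e$roll)
  u <- e$semi[1] * cos(t); v <- e$semi[2] * sin(t)
  cbind(e$center[1] + cs * u - sn * v, e$center[2] + sn * u + cs * v)
}

# is `inner` fully inside `outer`? checked by sampling the inner boundary
ellipse_nested <- function(inner, outer, n = 90) {
  p <- ellipse_point(inner, seq(0, 2 * pi, length.out = n))
  all(ellipse_contains(outer, p[, 1], p[, 2]))
}

# cumulative arc length of the boundary, counterclockwise from the reference
# azimuth; returns interpolation tables between parameter and arc fraction
ellipse_arc_table <- function(e, ref_azimuth = 0, n = 720) {
  t <- ref_azimuth + seq(0, 2 * pi, length.out = n + 1)
  p <- ellipse_point(e, t)
  seg <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  arc <- c(0, cumsum(seg))
  list(t = t, arc = arc, circumference = arc[n + 1])
}

# linear interpolation between two ellipses (weight w in [0,1] toward e2)
ellipse_lerp <- function(e1, e2, w) {
  roll1 <- e1$roll
  roll2 <- e2$roll
  # interpolate roll along the shorter way around
  d <- atan2(sin(roll2 - roll1), cos(roll2 - roll1))
  ellipse2d(center = (1 - w) * e1$center + w * e2$center,
            semi = (1 - w) * e1$semi + w * e2$semi,
            roll = roll1 + w * d)
}

# Phantom -------------------------------------------------------------------

#' Default geometry parameters for the layered forearm phantom
#'
#' The published individual geometry (ellipses fitted to 10 MR slices) is not
#' available, so the default phantom is a smoothly tapered elliptical cylinder
#' with plausible adult-forearm dimensions: the skin cross-section tapers from
#' the elbow to the wrist, the fat boundary is the skin surface offset inward
#' by the skin thickness, the muscle boundary lies a configurable fat
#' thickness further in, and two elliptical bones (ulna, radius) taper inside
#' the muscle compartment. A full per-station table can be supplied instead to
#' mimic an individual.
#'
#' @param leh_rsp_length distance lateral humeral epicondyle to radial styloid
#'   process, mm. The axial ROI/electrode coordinates are percentages of it.
#' @param skin_thickness skin layer thickness, mm.
#' @param fat_thickness fat layer thickness, mm (uniform).
#' @param skin_proximal,skin_distal skin semi-axes (a, b) at the proximal and
#'   distal end, mm.
#' @param bone_offsets 2-row matrix of bone center offsets (mm) in the
#'   cross-section.
#' @param bone_proximal,bone_distal per-bone semi-axes at the two ends, mm.
#' @param n_stations number of stations spanning the model length.
#' @return parameter list for [build_default_phantom()].
#' @export
phantom_params <- function(leh_rsp_length = 242, skin_thickness = 1,
                           fat_thickness = 3,
                           skin_proximal = c(45, 40), skin_distal = c(30, 24),
                           bone_offsets = rbind(c(12, -2), c(-12, -2)),
                           bone_proximal = c(9, 7), bone_distal = c(7, 5),
                           n_stations = 10) {
  list(leh_rsp_length = leh_rsp_length, skin_thickness = skin_thickness,
       fat_thickness = fat_thickness, skin_proximal = skin_proximal,
       skin_distal = skin_distal, bone_offsets = bone_offsets,
       bone_proximal = bone_proximal, bone_distal = bone_distal,
       n_stations = n_stations)
}

#' Build the parametric layered forearm phantom
#'
#' Constructs the four-layer (bone, muscle, fat, skin) volume conductor as a
#' stack of per-station cross-section ellipses. The axial coordinate runs from
#' the lateral humeral epicondyle (z = 0) to the radial styloid process
#' (z = `leh_rsp_length`); a 5% proximal extension (negative z) covers the most
#' proximal region of interest, so the total model length is
#' `1.05 * leh_rsp_length` (254.1 mm for the default 242 mm).
#'
#' @param params geometry parameters from [phantom_params()], or a list with a
#'   `stations` element (each station: `z_mm`, `skin`, `fat`, `muscle`,
#'   `bones` ellipses) for fully custom geometry.
#' @param reference_azimuth azimuth (rad) of the reference line from which the
#'   radial electrode coordinate is measured counterclockwise (viewed from the
#'   elbow toward the wrist).
#' @return object of class `forearm_phantom`.
#' @export
build_default_phantom <- function(params = phantom_params(),
                                  reference_azimuth = pi / 2) {
  if (!is.null(params$stations)) {
    stations <- params$stations
    L <- params$leh_rsp_length
    skin_t <- params$skin_thickness %||% 1
  } else {
    L <- params$leh_rsp_length
    skin_t <- params$skin_thickness
    ns <- max(2L, as.integer(params$n_stations))
    z <- seq(-0.05 * L, L, length.out = ns)
    w <- (z - z[1]) / (z[ns] - z[1])
    stations <- lapply(seq_len(ns), function(i) {
      skin_semi <- (1 - w[i]) * params$skin_proximal + w[i] * params$skin_distal
      fat_semi <- skin_semi - skin_t
      mus_semi <- fat_semi - params$fat_thickness
      bone_semi <- (1 - w[i]) * params$bone_proximal + w[i] * params$bone_distal
      shrink <- 1 - 0.4 * w[i]  # bones drift toward the section center distally
      bones <- lapply(seq_len(nrow(params$bone_offsets)), function(b)
        ellipse2d(center = params$bone_offsets[b, ] * shrink,
                  semi = bone_semi))
      list(z_mm = z[i],
           skin = ellipse2d(semi = skin_semi),
           fat = ellipse2d(semi = fat_semi),
           muscle = ellipse2d(semi = mus_semi),
           bones = bones)
    })
  }
  for (i in seq_along(stations)) {
    st <- stations[[i]]
    ok <- ellipse_nested(st$fat, st$skin) &&
      ellipse_nested(st$muscle, st$fat) &&
      all(vapply(st$bones, ellipse_nested, logical(1), outer = st$muscle))
    if (!ok)
      stopf("non-nested layer ellipses at station %d (z = %.1f mm)",
            i, st$z_mm)
  }
  structure(list(stations = stations,
                 leh_rsp_length = L,
                 total_length = 1.05 * L,
                 skin_thickness = skin_t,
                 reference_azimuth = reference_azimuth),
            class = "forearm_phantom")
}

#' @export
print.forearm_phantom <- function(x, ...) {
  zr <- range(vapply(x$stations, `[[`, numeric(1), "z_mm"))
  cat(sprintf("<forearm_phantom> %d stations, z in [%.1f, %.1f] mm\n",
              length(x$stations), zr[1], zr[2]))
  cat(sprintf("  LEH-RSP length %.1f mm, total length %.1f mm, skin %.1f mm\n",
              x$leh_rsp_length, x$total_length, x$skin_thickness))
  invisible(x)
}

# interpolated cross-section at axial position z (mm)
station_at <- function(phantom, z) {
  zs <- vapply(phantom$stations, `[[`, numeric(1), "z_mm")
  if (z < min(zs) - 1e-9 || z > max(zs) + 1e-9)
    stopf("axial position %.2f mm outside phantom range [%.2f, %.2f]",
          z, min(zs), max(zs))
  if (length(zs) == 1L) return(phantom$stations[[1]])
  i <- max(1L, min(findInterval(z, zs), length(zs) - 1L))
  w <- (z - zs[i]) / (zs[i + 1] - zs[i])
  w <- min(max(w, 0), 1)
  s1 <- phantom$stations[[i]]; s2 <- phantom$stations[[i + 1]]
  list(z_mm = z,
       skin = ellipse_lerp(s1$skin, s2$skin, w),
       fat = ellipse_lerp(s1$fat, s2$fat, w),
       muscle = ellipse_lerp(s1$muscle, s2$muscle, w),
       bones = lapply(seq_along(s1$bones), function(b)
         ellipse_lerp(s1$bones[[b]], s2$bones[[b]], w)))
}

#' Point on the skin surface by the axial/radial electrode coordinates
#'
#' The axial coordinate is a percentage of the LEH-RSP length from the elbow;
#' the radial coordinate is a percentage of the skin circumference, measured
#' as arc length counterclockwise (viewed elbow to wrist) from the reference
#' line.
#'
#' @param phantom a `forearm_phantom`.
#' @param axial_pct axial position, % of LEH-RSP length.
#' @param radial_pct radial position, % of circumference.
#' @return list with the 3D point (`point`, mm), local azimuth parameter
#'   (`theta`) and skin circumference at that station (`circumference`, mm).
#' @export
surface_point <- function(phantom, axial_pct, radial_pct) {
  assert_num(axial_pct, "axial_pct", lower = -5, upper = 105)
  assert_num(radial_pct, "radial_pct", lower = 0, upper = 100)
  z <- axial_pct / 100 * phantom$leh_rsp_length
  st <- station_at(phantom, z)
  tab <- ellipse_arc_table(st$skin, phantom$reference_azimuth)
  target <- radial_pct / 100 * tab$circumference
  theta <- approx(tab$arc, tab$t, xout = target, rule = 2)$y
  p2 <- ellipse_point(st$skin, theta)
  list(point = c(p2[1, 1], p2[1, 2], z), theta = theta,
       circumference = tab$circumference, station = st)
}
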