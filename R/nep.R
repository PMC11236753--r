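# Nerve entry point table and ROI construction ------------------------------

#' Load the nerve-entry-point (NEP) table
#'
#' Reads the packaged literature table of proximal-maximum, median and
#' distal-maximum NEP positions (percent of the LEH-RSP distance) for the
#' forearm muscles, and applies the modeling exclusions: the brachioradialis
#' (BR) is dropped entirely (all its tabulated positions come from extended
#' arms and are negative or proximal to the model), and remaining negative
#' bounds (ECRL proximal maximum) are clamped to 0. The finger flexors are
#' already split into proximal and distal ROIs (FDSprox/FDSdist,
#' FDPprox/FDPdist) because their NEPs vary along more than half the forearm;
#' their parenthesized bounds are offsets around the median.
#'
#' @param source optional CSV path with the same columns as the fixture
#'   (`muscle_group`, `muscle_name`, `code`, `proximal_max_pct`, `median_pct`,
#'   `distal_max_pct`).
#' @return data.frame of class `nep_table` with 20 records (for the packaged
#'   fixture): `muscle`, `group`, `name`, `proximal_pct`, `median_pct`,
#'   `distal_pct`.
#' @export
load_nep_table <- function(source = NULL) {
  raw <- read.csv(source %||% fixture_path("nep_table.csv"),
                  stringsAsFactors = FALSE, comment.char = "#")
  need <- c("code", "proximal_max_pct", "median_pct", "distal_max_pct")
  if (!all(need %in% names(raw)))
    stopf("NEP table must have columns %s", paste(need, collapse = ", "))
  # parenthesized signed values are offsets around the median (the finger
  # flexor sub-ROIs); everything else is an absolute percentage
  parse_bound <- function(x, median) {
    x <- trimws(gsub("−", "-", as.character(x)))   # unicode minus
    paren <- grepl("^\\(.*\\)$", x)
    val <- as.numeric(gsub("[()+]", "", x))
    ifelse(paren, median + val, val)
  }
  med <- as.numeric(raw$median_pct)
  prox <- parse_bound(raw$proximal_max_pct, med)
  dist <- parse_bound(raw$distal_max_pct, med)
  tab <- data.frame(muscle = raw$code, group = raw$muscle_group,
                    name = raw$muscle_name, proximal_pct = prox,
                    median_pct = med, distal_pct = dist,
                    stringsAsFactors = FALSE)
  # exclusions: drop muscles whose median lies outside the model (BR), clamp
  # remaining negative bounds to the model origin
  tab <- tab[tab$median_pct >= 0, , drop = FALSE]
  tab$proximal_pct <- pmax(tab$proximal_pct, 0)
  bad <- tab$proximal_pct > tab$median_pct | tab$median_pct > tab$distal_pct
  if (any(bad))
    stopf("NEP bounds not ordered for %s",
          paste(tab$muscle[bad], collapse = ", "))
  rownames(tab) <- NULL
  class(tab) <- c("nep_table", "data.frame")
  tab
}

#' Load the synthetic ROI placement hints
#'
#' The published per-muscle segmentation ellipses are unavailable; this table
#' supplies plausible defaults for the cross-section position, semi-axes and
#' orientation of each ROI (see the packaged CSV header for the convention).
#'
#' @param path optional CSV with the same columns.
#' @return data.frame of hints keyed by muscle code.
#' @export
load_roi_hints <- function(path = NULL) {
  read.csv(path %||% fixture_path("roi_hints_synthetic.csv"),
           stringsAsFactors = FALSE, comment.char = "#")
}

#' Region-of-interest specification
#'
#' An ROI is an elliptical cylinder inside a muscle: its axis passes through
#' `center` along the unit vector `axis`, the elliptical cross-section has the
#' given semi-axes, and the cylinder extends `length/2` to each side of the
#' center (default 10 mm proximally and distally).
#'
#' @param muscle muscle code.
#' @param center 3D center, mm.
#' @param axis unit direction of the ROI (and fiber) axis.
#' @param semi_axes cross-section semi-axes, mm.
#' @param length total axial extent, mm.
#' @param roll rotation of the cross-section about the axis, rad.
#' @return object of class `roi_spec`.
#' @export
roi_spec <- function(muscle, center, axis = c(0, 0, 1), semi_axes = c(8, 5),
                     length = 20, roll = 0) {
  assert_num(center, "center", len = 3)
  assert_num(axis, "axis", len = 3)
  assert_num(semi_axes, "semi_axes", lower = .Machine$double.eps, len = 2)
  assert_num(length, "length", lower = .Machine$double.eps)
  axis <- axis / sqrt(sum(axis^2))
  # orthonormal frame for the cross-section
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  cs <- cos(roll); sn <- sin(roll)
  u1 <- cs * e1 + sn * e2
  u2 <- -sn * e1 + cs * e2
  structure(list(muscle = muscle, center = as.numeric(center), axis = axis,
                 semi_axes = as.numeric(semi_axes), length = length,
                 roll = roll, e1 = u1, e2 = u2),
            class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec> %s: center (%.1f, %.1f, %.1f) mm, semi-axes %.1f x %.1f mm, length %g mm\n",
              x$muscle, x$center[1], x$center[2], x$center[3],
              x$semi_axes[1], x$semi_axes[2], x$length))
  invisible(x)
}

#' Build a muscle ROI from its NEP record
#'
#' The ROI is centered at the median NEP position (`median_pct`% of the
#' LEH-RSP length along the phantom axis) and extends 10 mm proximally and
#' distally. Orientation, cross-section semi-axes and the in-section position
#' come from the hint table; without a hint the ROI is aligned with the
#' phantom long axis at the muscle-layer mid-depth.
#'
#' @param record one row of the [load_nep_table()] table (or a list with
#'   `muscle` and `median_pct`).
#' @param phantom a `forearm_phantom`.
#' @param hints hint table from [load_roi_hints()], or `NULL` for the default
#'   axis-aligned placement.
#' @param length ROI length, mm.
#' @return an [roi_spec()]. A warning is issued if the ROI cross-section is
#'   not fully inside the muscle layer at the center station.
#' @export
build_roi <- function(record, phantom, hints = load_roi_hints(),
                      length = 20) {
  muscle <- record$muscle
  z <- record$median_pct / 100 * phantom$leh_rsp_length
  zs <- range(vapply(phantom$stations, `[[`, numeric(1), "z_mm"))
  if (z - length / 2 < zs[1] - 1e-9 || z + length / 2 > zs[2] + 1e-9)
    stopf("ROI '%s' (z = %.1f +/- %.0f mm) extends outside the phantom axial range [%.1f, %.1f]",
          muscle, z, length / 2, zs[1], zs[2])
  st <- station_at(phantom, z)
  hint <- NULL
  if (!is.null(hints)) {
    hr <- hints[hints$muscle == muscle, , drop = FALSE]
    if (nrow(hr) == 1L) hint <- as.list(hr)
  }
  if (is.null(hint)) {
    center <- c(st$muscle$center[1], st$muscle$center[2] + st$muscle$semi[2] / 2, z)
    semi <- c(8, 5)
    axis <- c(0, 0, 1)
    roll <- 0
  } else {
    az <- hint$azimuth_deg * pi / 180
    # position between the section center and the muscle boundary
    bnd <- ellipse_point(st$muscle, az)
    center2 <- st$muscle$center + hint$radius_frac *
      (c(bnd[1, 1], bnd[1, 2]) - st$muscle$center)
    center <- c(center2, z)
    semi <- c(hint$semi_a_mm, hint$semi_b_mm)
    p <- hint$pitch_deg * pi / 180; yw <- hint$yaw_deg * pi / 180
    axis <- c(sin(yw) * cos(p), sin(p), cos(yw) * cos(p))
    roll <- hint$roll_deg * pi / 180
  }
  roi <- roi_spec(muscle, center, axis, semi, length, roll)
  # containment check at the center station (warning only: the hints are
  # approximate and a partially protruding ROI is still usable)
  tt <- seq(0, 2 * pi, length.out = 24)
  ring <- t(vapply(tt, function(a)
    roi$center[1:2] + semi[1] * cos(a) * roi$e1[1:2] +
      semi[2] * sin(a) * roi$e2[1:2], numeric(2)))
  if (!all(ellipse_contains(st$muscle, ring[, 1], ring[, 2])))
    warnf("ROI '%s' cross-section is not fully inside the muscle layer", muscle)
  roi
}
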