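# Activating function --------------------------------------------------------

#' Discrete activating function along a fiber
#'
#' Second spatial difference of the extracellular potential at the nodes of
#' Ranvier, `AF_n = (V_e,n-1 - 2 V_e,n + V_e,n+1) / delta_x^2`, in V/m^2.
#' Positive values indicate membrane depolarization (a cathodic source above
#' the fiber produces a positive central lobe). The terminal nodes have no
#' two-sided difference and are returned as NA.
#'
#' @param v_e_mV extracellular potential at the nodes, mV (>= 3 nodes).
#' @param delta_x_um internodal distance, um.
#' @return numeric vector (same length as `v_e_mV`) of AF values in V/m^2,
#'   NA at the two endpoints.
#' @export
activating_function <- function(v_e_mV, delta_x_um) {
  n <- length(v_e_mV)
  if (n < 3) stopf("activating function needs >= 3 nodes")
  dx_m <- delta_x_um * 1e-6
  v <- v_e_mV * 1e-3
  af <- rep(NA_real_, n)
  af[2:(n - 1)] <- (v[1:(n - 2)] - 2 * v[2:(n - 1)] + v[3:n]) / dx_m^2
  af
}

# point-source extracellular potential in a homogeneous medium: mV per mA of
# (signed) source current at distance r_mm
point_source_mV_per_mA <- function(r_mm, rho_ohm_m = 3, current_mA = 1) {
  r_m <- r_mm / 1000
  rho_ohm_m * (current_mA * 1e-3) / (4 * pi * r_m) * 1000
}

#' Calibrate the activating-function threshold table against the cable model
#'
#' The AF predicts activation when its peak exceeds a threshold that depends
#' on axon diameter and pulse width. The lookup values of the cited
#' calibration study are not reprinted, so the default table is generated by
#' calibration against the linear cable model on a canonical geometry: a
#' cathodic point source at `height_mm` above the center of a straight fiber
#' in a homogeneous medium (resistivity `rho_ohm_m`). For each (diameter,
#' pulse width) pair the cable-model threshold amplitude is computed in
#' closed form and the corresponding peak AF is recorded as the threshold.
#'
#' @param diameters_um diameter grid, um.
#' @param pw_us pulse width grid, us.
#' @param params a [cable_params()].
#' @param height_mm source height above the fiber, mm.
#' @param rho_ohm_m medium resistivity, Ohm m.
#' @param fiber_length_mm fiber length used for calibration, mm.
#' @return object of class `af_threshold_table`: `diameters_um`, `pw_us`,
#'   `thresholds` (matrix, V/m^2, rows = diameters).
#' @export
calibrate_af_table <- function(diameters_um = c(2, 4, 6, 8, 10, 12, 14, 16),
                               pw_us = c(20, 50, 100, 200, 350, 500),
                               params = cable_params(), height_mm = 10,
                               rho_ohm_m = 3, fiber_length_mm = 40) {
  thr <- matrix(NA_real_, length(diameters_um), length(pw_us))
  for (i in seq_along(diameters_um)) {
    d <- diameters_um[i]
    dx_um <- delta_x_um(d)
    x <- place_nodes(d, fiber_length_mm, offset_mm = 0)
    x <- x - mean(range(x))                  # center under the source
    r <- sqrt(x^2 + height_mm^2)
    v_unit <- point_source_mV_per_mA(r, rho_ohm_m, current_mA = -1)  # cathodic
    const <- derive_node_constants(d, dx_um, params)
    af_unit <- activating_function(v_unit, dx_um)
    peak_af_unit <- max(af_unit, na.rm = TRUE)
    for (j in seq_along(pw_us)) {
      a_th <- fiber_threshold_amplitude(v_unit, pw_us[j], const, params)
      thr[i, j] <- a_th * peak_af_unit
    }
  }
  structure(list(diameters_um = diameters_um, pw_us = pw_us,
                 thresholds = thr, geometry = list(height_mm = height_mm,
                 rho_ohm_m = rho_ohm_m, fiber_length_mm = fiber_length_mm)),
            class = "af_threshold_table")
}

.festwin_cache <- new.env(parent = emptyenv())

#' Default AF threshold table (calibrated, cached per session)
#'
#' @param params a [cable_params()].
#' @return an `af_threshold_table`.
#' @export
default_af_table <- function(params = cable_params()) {
  key <- paste0("af_", paste(unlist(params), collapse = "_"))
  if (is.null(.festwin_cache[[key]]))
    .festwin_cache[[key]] <- calibrate_af_table(params = params)
  .festwin_cache[[key]]
}

#' Read an AF threshold table from CSV
#'
#' Expects columns `d_um`, `pw_us`, `threshold` on a full rectangular grid.
#'
#' @param path CSV path.
#' @return an `af_threshold_table`.
#' @export
read_af_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  ds <- sort(unique(tab$d_um)); ps <- sort(unique(tab$pw_us))
  thr <- matrix(NA_real_, length(ds), length(ps))
  for (r in seq_len(nrow(tab)))
    thr[match(tab$d_um[r], ds), match(tab$pw_us[r], ps)] <- tab$threshold[r]
  if (anyNA(thr)) stopf("AF table grid in '%s' is incomplete", path)
  structure(list(diameters_um = ds, pw_us = ps, thresholds = thr,
                 geometry = NULL), class = "af_threshold_table")
}

# bilinear interpolation with edge clamping (warning outside the grid)
af_lookup <- function(table, d_um, pw_us) {
  if (is.null(table) || !length(table$thresholds)) stopf("empty AF table")
  ds <- table$diameters_um; ps <- table$pw_us
  if (d_um < min(ds) || d_um > max(ds) || pw_us < min(ps) || pw_us > max(ps))
    warnf("(d = %g um, PW = %g us) outside the AF table grid; clamping",
          d_um, pw_us)
  d <- min(max(d_um, min(ds)), max(ds))
  p <- min(max(pw_us, min(ps)), max(ps))
  i <- max(1, min(findInterval(d, ds), length(ds) - 1))
  j <- max(1, min(findInterval(p, ps), length(ps) - 1))
  fd <- if (ds[i + 1] > ds[i]) (d - ds[i]) / (ds[i + 1] - ds[i]) else 0
  fp <- if (ps[j + 1] > ps[j]) (p - ps[j]) / (ps[j + 1] - ps[j]) else 0
  (1 - fd) * (1 - fp) * table$thresholds[i, j] +
    fd * (1 - fp) * table$thresholds[i + 1, j] +
    (1 - fd) * fp * table$thresholds[i, j + 1] +
    fd * fp * table$thresholds[i + 1, j + 1]
}

#' Predict fiber activation with the activating function
#'
#' The fiber is activated when its maximal interior AF value reaches the
#' diameter- and pulse-width-dependent threshold (bilinear interpolation in
#' the table; values outside the grid are clamped to the edge with a
#' warning).
#'
#' @param af_values AF values from [activating_function()], V/m^2.
#' @param d_um fiber diameter, um.
#' @param pw_us pulse width, us.
#' @param table an `af_threshold_table`.
#' @param fiber_id identifier carried into the verdict.
#' @return an `activation_verdict` (model `"AF"`).
#' @export
af_predict <- function(af_values, d_um, pw_us, table = default_af_table(),
                       fiber_id = NA_integer_) {
  thr <- af_lookup(table, d_um, pw_us)
  interior <- af_values[!is.na(af_values)]
  peak <- if (length(interior)) max(interior) else -Inf
  structure(list(fiber_id = fiber_id, activated = peak >= thr,
                 peak_depolarization = peak, peak_node = which.max(af_values),
                 model = "AF"), class = "activation_verdict")
}
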