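# Stimulus waveform ---------------------------------------------------------

#' Rectangular stimulation pulse with linear ramps
#'
#' The stimulator delivers a single rectangular current pulse with short
#' linear ramp-in and ramp-out segments, described as a piecewise-linear
#' time-to-current map. The plateau value equals `amplitude` and the waveform
#' is zero outside `[0, ramp_in + pulse_width + ramp_out]`.
#'
#' @param amplitude plateau current, mA.
#' @param pulse_width plateau duration, us.
#' @param ramp_in,ramp_out ramp durations, us. The printed protocols do not
#'   state them; the default 10 us is short against every pulse width used.
#' @return object of class `stimulus_pulse` with a vectorized `waveform(t_us)`
#'   function returning mA.
#' @export
stimulus_pulse <- function(amplitude, pulse_width, ramp_in = 10,
                           ramp_out = 10) {
  assert_num(amplitude, "amplitude")
  assert_num(pulse_width, "pulse_width", lower = 0)
  assert_num(ramp_in, "ramp_in", lower = 0)
  assert_num(ramp_out, "ramp_out", lower = 0)
  t_end <- ramp_in + pulse_width + ramp_out
  waveform <- function(t) {
    w <- numeric(length(t))
    if (ramp_in > 0) {
      i <- t >= 0 & t < ramp_in
      w[i] <- amplitude * t[i] / ramp_in
    }
    i <- t >= ramp_in & t <= ramp_in + pulse_width
    w[i] <- amplitude
    if (ramp_out > 0) {
      i <- t > ramp_in + pulse_width & t < t_end
      w[i] <- amplitude * (t_end - t[i]) / ramp_out
    }
    w
  }
  structure(list(amplitude = amplitude, pulse_width = pulse_width,
                 ramp_in = ramp_in, ramp_out = ramp_out, t_end = t_end,
                 waveform = waveform), class = "stimulus_pulse")
}

# Potential solver -----------------------------------------------------------

#' Solve the quasi-static potential on a conductor grid
#'
#' Finite-volume discretization of `div(sigma grad V) = 0` on the voxel grid:
#' face conductances are harmonic means of the adjacent per-axis voxel
#' conductivities, the injected current is distributed uniformly over the
#' active electrode face voxels, the outer boundary carries zero normal flux,
#' and the potential reference V = 0 is the outer face of the indifferent
#' electrode (grounded through half-cell conductances). The resulting sparse
#' symmetric positive-definite system is solved directly; the relative
#' residual is checked against `tol`.
#'
#' The solution is stored per unit current (1 mA); by linearity of the
#' resistive problem any amplitude is a rescaling.
#'
#' @param grid a `conductor_grid` with at least two electrode face sets.
#' @param active,indifferent names or indices of the electrode face sets.
#' @param current_mA injected current, mA. `0` returns the zero field.
#' @param tol maximum acceptable relative residual.
#' @return object of class `potential_field`: `v_per_mA` (3D array, volts per
#'   injected mA, NA outside the conductor), grid geometry, the achieved
#'   residual and the active-electrode face voltage.
#' @export
solve_potential <- function(grid, active = "different",
                            indifferent = "indifferent", current_mA = 1,
                            tol = 1e-6) {
  fa <- grid$electrode_faces[[active]]
  fi <- grid$electrode_faces[[indifferent]]
  if (is.null(fa) || nrow(fa) == 0)
    stopf("active electrode face is empty (missing source): system is singular")
  if (is.null(fi) || nrow(fi) == 0)
    stopf("indifferent electrode face is empty (missing sink): system is singular")
  if (length(intersect(fa$index, fi$index)))
    stopf("active and indifferent electrode faces overlap")
  dims <- grid$dims
  nvox <- prod(dims)
  dom <- which(grid$material > MAT_AIR)
  comp <- integer(nvox); comp[dom] <- seq_along(dom)
  n <- length(dom)
  h_m <- grid$h / 1000
  lin <- array(seq_len(nvox), dims)
  sig <- list(grid$sigma_x, grid$sigma_y, grid$sigma_z)
  ia <- integer(0); ib <- integer(0); gg <- numeric(0)
  for (ax in 1:3) {
    nax <- dims[ax]
    if (nax < 2) next
    idx_lo <- switch(ax, lin[-nax, , , drop = FALSE], lin[, -nax, , drop = FALSE],
                     lin[, , -nax, drop = FALSE])
    idx_hi <- switch(ax, lin[-1, , , drop = FALSE], lin[, -1, , drop = FALSE],
                     lin[, , -1, drop = FALSE])
    s <- sig[[ax]]
    s_lo <- s[idx_lo]; s_hi <- s[idx_hi]
    ok <- s_lo > 0 & s_hi > 0
    if (!any(ok)) next
    g <- h_m * 2 * s_lo[ok] * s_hi[ok] / (s_lo[ok] + s_hi[ok])
    ia <- c(ia, comp[idx_lo[ok]])
    ib <- c(ib, comp[idx_hi[ok]])
    gg <- c(gg, g)
  }
  # ground the indifferent face through half-cell conductances to its outer
  # face, which defines the V = 0 reference
  sg_i <- vapply(seq_len(nrow(fi)), function(r)
    sig[[fi$axis[r]]][fi$index[r]], numeric(1))
  g_ground <- 2 * sg_i * h_m
  ground_rows <- comp[fi$index]
  # assemble SPD system
  diag_vals <- numeric(n)
  acc <- function(rows, vals) {
    t <- tapply(vals, rows, sum)
    diag_vals[as.integer(names(t))] <<- diag_vals[as.integer(names(t))] + t
  }
  acc(ia, gg); acc(ib, gg); acc(ground_rows, g_ground)
  A <- Matrix::sparseMatrix(i = c(ia, ib, seq_len(n)),
                            j = c(ib, ia, seq_len(n)),
                            x = c(-gg, -gg, diag_vals), dims = c(n, n))
  I_amp <- current_mA * 1e-3
  b <- numeric(n)
  b[comp[fa$index]] <- b[comp[fa$index]] + I_amp / nrow(fa)
  if (current_mA == 0) {
    v <- numeric(n)
    residual <- 0
  } else {
    As <- Matrix::forceSymmetric(A)
    ch <- Matrix::Cholesky(As, perm = TRUE, LDL = FALSE)
    v <- as.numeric(Matrix::solve(ch, b))
    residual <- sqrt(sum((as.numeric(A %*% v) - b)^2)) / sqrt(sum(b^2))
    if (!is.finite(residual) || residual > tol)
      stopf("potential solve did not converge: relative residual %.3g exceeds tol %.3g",
            residual, tol)
  }
  V <- array(NA_real_, dims)
  V[dom] <- v
  # active electrode face voltage: voxel center potential plus the half-cell
  # drop to the outer face carrying the uniform injected current density
  sg_a <- vapply(seq_len(nrow(fa)), function(r)
    sig[[fa$axis[r]]][fa$index[r]], numeric(1))
  v_face <- V[fa$index] + (I_amp / nrow(fa)) / (2 * sg_a * h_m)
  v_unit <- if (current_mA == 0) V else V / current_mA
  structure(list(v_per_mA = v_unit, dims = dims, h = grid$h,
                 origin = grid$origin, material = grid$material,
                 injected_current = current_mA, residual = residual,
                 electrode_voltage = mean(v_face),
                 interpolation = "trilinear"),
            class = "potential_field")
}

#' @export
print.potential_field <- function(x, ...) {
  cat(sprintf("<potential_field> %d x %d x %d grid, %.2f mm voxels; residual %.2g\n",
              x$dims[1], x$dims[2], x$dims[3], x$h, x$residual))
  cat(sprintf("  active electrode at %.4g V per mA (indifferent face = 0)\n",
              x$electrode_voltage / max(x$injected_current, 1)))
  invisible(x)
}

# trilinear interpolation of the unit-current potential (V per mA) at points
# (n x 3 matrix, mm); corners outside the conductor (NA) are dropped with
# weight renormalization so near-surface points remain usable
sample_unit_potential <- function(field, points) {
  points <- rbind(points)
  n <- nrow(points)
  dims <- field$dims
  g <- sweep(points, 2, field$origin) / field$h + 1  # fractional voxel coords
  out <- g[, 1] < 0.5 - 1e-9 | g[, 1] > dims[1] + 0.5 + 1e-9 |
    g[, 2] < 0.5 - 1e-9 | g[, 2] > dims[2] + 0.5 + 1e-9 |
    g[, 3] < 0.5 - 1e-9 | g[, 3] > dims[3] + 0.5 + 1e-9
  if (any(out))
    stopf("point(s) outside the solved grid: %s",
          paste(apply(points[out, , drop = FALSE], 1, function(p)
            sprintf("(%.1f, %.1f, %.1f)", p[1], p[2], p[3])), collapse = "; "))
  res <- numeric(n)
  V <- field$v_per_mA
  for (p in seq_len(n)) {
    i0 <- pmin(pmax(floor(g[p, ]), 1), dims - 1)
    f <- g[p, ] - i0
    f <- pmin(pmax(f, 0), 1)
    wsum <- 0; vsum <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- ((if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
              (if (dz) f[3] else 1 - f[3]))
      val <- V[i0[1] + dx, i0[2] + dy, i0[3] + dz]
      if (!is.na(val) && w > 0) { wsum <- wsum + w; vsum <- vsum + w * val }
    }
    if (wsum == 0)
      stopf("point (%.1f, %.1f, %.1f) lies outside the conductor",
            points[p, 1], points[p, 2], points[p, 3])
    res[p] <- vsum / wsum
  }
  res
}

#' Sample extracellular potential time courses
#'
#' Under the resistive quasi-static approximation space and time factorize:
#' `V_e(p, t) = V_unit(p) * waveform(t) / 1 mA`. The unit-current potential is
#' interpolated trilinearly at the requested points.
#'
#' @param field a `potential_field` from [solve_potential()].
#' @param points n x 3 matrix of sample points, mm.
#' @param pulse a [stimulus_pulse()]; if `NULL`, the unit potential (V per mA)
#'   is returned instead of a time course.
#' @param times sample times, us (default: 1 us steps over the pulse).
#' @return if `pulse` is given, a list with `times` (us) and `v_e` (n x length
#'   (times) matrix, mV); otherwise a numeric vector of V per mA.
#' @export
sample_potential <- function(field, points, pulse = NULL, times = NULL) {
  v_unit <- sample_unit_potential(field, points)
  if (is.null(pulse)) return(v_unit)
  if (is.null(times)) times <- seq(0, pulse$t_end, by = 1)
  w <- pulse$waveform(times)           # mA
  v_e <- outer(v_unit * 1000, w)       # mV = (V/mA * 1000) * mA
  list(times = times, v_e = v_e)
}

# net current (mA) crossing the plane between z-slices k and k+1; used by the
# conservation checks
plane_current <- function(grid, field, k) {
  dims <- grid$dims
  stopifnot(k >= 1, k < dims[3])
  h_m <- grid$h / 1000
  s1 <- grid$sigma_z[, , k]; s2 <- grid$sigma_z[, , k + 1]
  v1 <- field$v_per_mA[, , k] * field$injected_current
  v2 <- field$v_per_mA[, , k + 1] * field$injected_current
  ok <- s1 > 0 & s2 > 0 & !is.na(v1) & !is.na(v2)
  g <- h_m * 2 * s1[ok] * s2[ok] / (s1[ok] + s2[ok])
  sum(g * (v1[ok] - v2[ok])) * 1000   # A -> mA
}
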