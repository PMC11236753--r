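# Voxel conductor grid ------------------------------------------------------

# material codes used in the voxel grid
MAT_AIR <- 0L; MAT_HYDROGEL <- 1L; MAT_SKIN <- 2L; MAT_FAT <- 3L
MAT_MUSCLE <- 4L; MAT_BONE <- 5L

new_conductor_grid <- function(dims, h, origin, material, sigma_x, sigma_y,
                               sigma_z, electrode_faces, materials) {
  structure(list(dims = dims, h = h, origin = origin, material = material,
                 sigma_x = sigma_x, sigma_y = sigma_y, sigma_z = sigma_z,
                 electrode_faces = electrode_faces, materials = materials),
            class = "conductor_grid")
}

#' @export
print.conductor_grid <- function(x, ...) {
  cat(sprintf("<conductor_grid> %d x %d x %d voxels at %.2f mm (%d in tissue, %d electrodes)\n",
              x$dims[1], x$dims[2], x$dims[3], x$h,
              sum(x$material > MAT_AIR), length(x$electrode_faces)))
  invisible(x)
}

# map material codes to per-axis conductivities (muscle anisotropic: the fiber
# direction is the phantom long axis z, so sigma_axial applies to z and
# sigma_radial to x and y)
material_sigmas <- function(materials) {
  tab <- matrix(0, nrow = 6, ncol = 3)  # rows: code + 1
  set <- function(code, sx, sy, sz) tab[code + 1, ] <<- c(sx, sy, sz)
  set(MAT_HYDROGEL, materials$hydrogel$sigma_axial,
      materials$hydrogel$sigma_axial, materials$hydrogel$sigma_axial)
  set(MAT_SKIN, materials$skin$sigma_axial, materials$skin$sigma_axial,
      materials$skin$sigma_axial)
  set(MAT_FAT, materials$fat$sigma_axial, materials$fat$sigma_axial,
      materials$fat$sigma_axial)
  set(MAT_MUSCLE, materials$muscle$sigma_radial, materials$muscle$sigma_radial,
      materials$muscle$sigma_axial)
  set(MAT_BONE, materials$bone$sigma_axial, materials$bone$sigma_axial,
      materials$bone$sigma_axial)
  tab
}

#' Voxelize the phantom and electrodes into a conductor grid
#'
#' Assigns one material per voxel by point-in-ellipse tests against the
#' axially interpolated station geometry, builds the diagonal conductivity
#' tensor per voxel (muscle anisotropic, axial along the phantom axis), adds
#' hydrogel voxels outside the skin over each electrode footprint, and records
#' the electrode face voxels through which current is injected.
#'
#' @param phantom a `forearm_phantom`.
#' @param electrodes list of [electrode_spec()] or `electrode_footprint`
#'   objects (specs are placed automatically). May be empty.
#' @param resolution voxel edge length, mm. A resolution coarser than the skin
#'   thickness triggers a warning; the skin layer is then guaranteed to be at
#'   least one voxel thick by assigning the outermost tissue voxel ring of
#'   every slice to skin.
#' @param materials material set from [default_materials()].
#' @return object of class `conductor_grid`.
#' @export
voxelize <- function(phantom, electrodes = list(), resolution = 4,
                     materials = default_materials()) {
  assert_num(resolution, "resolution", lower = .Machine$double.eps)
  if (resolution > phantom$skin_thickness)
    warnf("resolution (%.2f mm) is coarser than the skin thickness (%.2f mm); skin is kept at least one voxel thick",
          resolution, phantom$skin_thickness)
  fps <- lapply(electrodes, function(e) {
    if (inherits(e, "electrode_footprint")) e else place_electrode(phantom, e)
  })
  h <- resolution
  zs <- vapply(phantom$stations, `[[`, numeric(1), "z_mm")
  pad <- max(c(1.5 * h, vapply(fps, function(f)
    f$spec$hydrogel_thickness + h, numeric(1))), na.rm = TRUE)
  # transverse bounding box over all stations
  amax <- max(vapply(phantom$stations, function(s) max(abs(s$skin$center)) +
                       max(s$skin$semi), numeric(1)))
  x0 <- -amax - pad; x1 <- amax + pad
  nx <- ceiling((x1 - x0) / h); ny <- nx
  nz <- ceiling((max(zs) - min(zs)) / h)
  xs <- x0 + (seq_len(nx) - 0.5) * h
  ys <- x0 + (seq_len(ny) - 0.5) * h
  zvals <- min(zs) + (seq_len(nz) - 0.5) * h
  dims <- c(nx, ny, nz)
  material <- array(MAT_AIR, dims)
  gx <- rep(xs, times = ny)
  gy <- rep(ys, each = nx)
  for (k in seq_len(nz)) {
    st <- station_at(phantom, zvals[k])
    rho_skin <- ellipse_rho(st$skin, gx, gy)
    slice <- rep(MAT_AIR, nx * ny)
    inside <- rho_skin <= 1
    slice[inside] <- MAT_SKIN
    slice[ellipse_contains(st$fat, gx, gy)] <- MAT_FAT
    slice[ellipse_contains(st$muscle, gx, gy)] <- MAT_MUSCLE
    for (b in st$bones) slice[ellipse_contains(b, gx, gy)] <- MAT_BONE
    sm <- matrix(slice, nx, ny)
    # outermost tissue ring is skin (guarantees a contiguous >= 1 voxel skin)
    inm <- matrix(inside, nx, ny)
    nb_out <- matrix(FALSE, nx, ny)
    nb_out[-1, ] <- nb_out[-1, ] | !inm[-nx, ]
    nb_out[-nx, ] <- nb_out[-nx, ] | !inm[-1, ]
    nb_out[, -1] <- nb_out[, -1] | !inm[, -ny]
    nb_out[, -ny] <- nb_out[, -ny] | !inm[, -1]
    sm[inm & nb_out] <- MAT_SKIN
    # hydrogel pads
    for (ei in seq_along(fps)) {
      fp <- fps[[ei]]
      t_hg <- fp$spec$hydrogel_thickness
      out <- rho_skin > 1
      if (!any(out)) next
      rr <- sqrt((gx - st$skin$center[1])^2 + (gy - st$skin$center[2])^2)
      dist_out <- rr * (1 - 1 / pmax(rho_skin, 1e-9))
      cand <- out & dist_out > 0 & dist_out <= max(t_hg, 1.01 * h)
      if (!any(cand)) next
      # local ellipse parameter of each candidate direction
      cs <- cos(st$skin$roll); sn <- sin(st$skin$roll)
      dx <- gx[cand] - st$skin$center[1]; dy <- gy[cand] - st$skin$center[2]
      u <- cs * dx + sn * dy; v <- -sn * dx + cs * dy
      th <- atan2(v / st$skin$semi[2], u / st$skin$semi[1]) + st$skin$roll
      hit <- fp$contains(rep(zvals[k], sum(cand)), th)
      idx <- which(cand)[hit]
      smv <- as.vector(sm)
      idx <- idx[smv[idx] == MAT_AIR]
      sm[idx] <- MAT_HYDROGEL
      attr(sm, paste0("electrode", ei)) <-
        c(attr(sm, paste0("electrode", ei)), idx)
    }
    material[, , k] <- sm
    for (ei in seq_along(fps)) {
      idx <- attr(sm, paste0("electrode", ei))
      if (length(idx))
        fps[[ei]]$voxels <- c(fps[[ei]]$voxels,
                              idx + (k - 1L) * nx * ny)
    }
  }
  sig <- material_sigmas(materials)
  sigma_x <- array(sig[material + 1L, 1], dims)
  sigma_y <- array(sig[material + 1L, 2], dims)
  sigma_z <- array(sig[material + 1L, 3], dims)
  electrode_faces <- lapply(fps, function(fp) {
    vox <- fp$voxels
    if (is.null(vox))
      stopf("electrode '%s' footprint is empty at this resolution",
            fp$spec$role)
    # outward axis: predominant radial direction of the voxel center
    ijk <- arrayInd(vox, dims)
    cx <- xs[ijk[, 1]]; cy <- ys[ijk[, 2]]
    axis <- ifelse(abs(cx) >= abs(cy), 1L, 2L)
    data.frame(index = vox, axis = axis)
  })
  names(electrode_faces) <- vapply(fps, function(f) f$spec$role, character(1))
  new_conductor_grid(dims, h, c(xs[1], ys[1], zvals[1]), material,
                     sigma_x, sigma_y, sigma_z, electrode_faces, materials)
}

#' Homogeneous cuboid grid (verification geometry)
#'
#' Builds a homogeneous rectangular conductor with the two z-end faces acting
#' as the active and indifferent electrodes. With full end faces the solved
#' problem has the closed-form resistor solution dV = I L / (sigma A), which
#' makes this the canonical solver verification object. A small centered
#' square patch can replace the full active face to create a genuinely 3D
#' field for convergence and symmetry checks.
#'
#' @param dims_mm cuboid edge lengths (x, y, z), mm.
#' @param resolution voxel edge length, mm.
#' @param sigma conductivity, S/m (scalar, or length-3 for an anisotropic
#'   medium, per-axis).
#' @param active_patch_mm optional edge length of a centered square active
#'   patch on the z = 0 face; default uses the full face.
#' @return object of class `conductor_grid`.
#' @export
cuboid_grid <- function(dims_mm = c(10, 10, 100), resolution = 2.5,
                        sigma = 1 / 3, active_patch_mm = NULL) {
  h <- resolution
  n <- pmax(1L, as.integer(round(dims_mm / h)))
  dims <- n
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  material <- array(MAT_MUSCLE, dims)
  sigma_x <- array(sigma[1], dims)
  sigma_y <- array(sigma[2], dims)
  sigma_z <- array(sigma[3], dims)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  xs <- (seq_len(nx) - 0.5) * h - dims_mm[1] / 2
  ys <- (seq_len(ny) - 0.5) * h - dims_mm[2] / 2
  L <- array(seq_len(prod(dims)), dims)
  sel_active <- if (is.null(active_patch_mm)) {
    as.vector(L[, , 1])
  } else {
    keep <- abs(xs) <= active_patch_mm / 2
    keepy <- abs(ys) <= active_patch_mm / 2
    as.vector(L[keep, keepy, 1])
  }
  electrode_faces <- list(
    different = data.frame(index = sel_active, axis = 3L),
    indifferent = data.frame(index = as.vector(L[, , nz]), axis = 3L)
  )
  new_conductor_grid(dims, h, c(xs[1], ys[1], h / 2), material,
                     sigma_x, sigma_y, sigma_z, electrode_faces,
                     default_materials())
}
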