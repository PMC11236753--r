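# Minimal ASCII STL I/O (triangle soup); no STL package exists in the R
# stack, and the meshes here are simple watertight cylinders.

stl_write_ascii <- function(triangles, path, name = "mesh") {
  con <- tryCatch(file(path, "w"), error = function(e)
    stopf("cannot write STL to '%s': %s", path, conditionMessage(e)))
  on.exit(close(con))
  cat(sprintf("solid %s\n", name), file = con)
  for (i in seq_len(dim(triangles)[3])) {
    tr <- triangles[, , i]
    e1 <- tr[2, ] - tr[1, ]; e2 <- tr[3, ] - tr[1, ]
    nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
             e1[3] * e2[1] - e1[1] * e2[3],
             e1[1] * e2[2] - e1[2] * e2[1])
    nn <- sqrt(sum(nrm^2))
    if (nn > 0) nrm <- nrm / nn
    cat(sprintf("facet normal %.9g %.9g %.9g\n outer loop\n", nrm[1], nrm[2],
                nrm[3]), file = con)
    for (v in 1:3)
      cat(sprintf("  vertex %.9g %.9g %.9g\n", tr[v, 1], tr[v, 2], tr[v, 3]),
          file = con)
    cat(" endloop\nendfacet\n", file = con)
  }
  cat(sprintf("endsolid %s\n", name), file = con)
  invisible(path)
}

#' Read an ASCII STL file
#'
#' @param path file path.
#' @return a 3 x 3 x n array of triangles (vertex, coordinate, facet).
#' @export
read_stl <- function(path) {
  lines <- readLines(path)
  vtx <- grep("^\\s*vertex", lines, value = TRUE)
  if (!length(vtx)) stopf("'%s' contains no vertices (not ASCII STL?)", path)
  nums <- t(vapply(strsplit(trimws(vtx), "\\s+"), function(p)
    as.numeric(p[2:4]), numeric(3)))
  n <- nrow(nums) / 3
  tri <- array(NA_real_, c(3, 3, n))
  for (i in seq_len(n)) tri[, , i] <- nums[(3 * i - 2):(3 * i), ]
  tri
}

# triangulated elliptical cylinder for an ROI (side strip + end caps)
roi_mesh <- function(roi, n_seg = 64) {
  tt <- seq(0, 2 * pi, length.out = n_seg + 1)[-(n_seg + 1)]
  ring <- function(s) {  # s in {-1, +1}: bottom/top cap center offset
    ctr <- roi$center + s * (roi$length / 2) * roi$axis
    t(vapply(tt, function(a)
      ctr + roi$semi_axes[1] * cos(a) * roi$e1 +
        roi$semi_axes[2] * sin(a) * roi$e2, numeric(3)))
  }
  bot <- ring(-1); top <- ring(1)
  cb <- roi$center - (roi$length / 2) * roi$axis
  ct <- roi$center + (roi$length / 2) * roi$axis
  tris <- list()
  nxt <- c(seq_len(n_seg)[-1], 1L)
  for (i in seq_len(n_seg)) {
    j <- nxt[i]
    tris[[length(tris) + 1]] <- rbind(bot[i, ], bot[j, ], top[j, ])
    tris[[length(tris) + 1]] <- rbind(bot[i, ], top[j, ], top[i, ])
    tris[[length(tris) + 1]] <- rbind(cb, bot[j, ], bot[i, ])
    tris[[length(tris) + 1]] <- rbind(ct, top[i, ], top[j, ])
  }
  tri <- array(NA_real_, c(3, 3, length(tris)))
  for (i in seq_along(tris)) tri[, , i] <- tris[[i]]
  tri
}

#' Export an ROI as an STL mesh
#'
#' Writes the ROI's elliptical cylinder as a watertight ASCII STL mesh
#' (side strip plus triangulated end caps).
#'
#' @param roi an [roi_spec()].
#' @param path output file path.
#' @param n_seg number of segments around the circumference.
#' @return the path, invisibly.
#' @export
export_roi_stl <- function(roi, path, n_seg = 64) {
  if (roi$length <= 0) stopf("degenerate ROI: zero length")
  tri <- roi_mesh(roi, n_seg)
  stl_write_ascii(tri, path, name = paste0("roi_", roi$muscle))
  invisible(path)
}

# area of the cap at the given end (+1 top / -1 bottom) of a cylinder mesh:
# sum of triangle areas whose vertices all lie on that cap plane
mesh_cap_area <- function(tri, center, axis, half_len, tol = 1e-6) {
  s <- apply(tri, 3, function(tr) {
    d <- (tr - matrix(center, 3, 3, byrow = TRUE)) %*% axis
    all(abs(abs(d) - half_len) < tol) && all(abs(d - d[1]) < tol)
  })
  idx <- which(s)
  total <- 0
  for (i in idx) {
    tr <- tri[, , i]
    e1 <- tr[2, ] - tr[1, ]; e2 <- tr[3, ] - tr[1, ]
    cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    total <- total + 0.5 * sqrt(sum(cr^2))
  }
  total / 2  # two caps matched; report one
}

#' Export the phantom skin surface as STL
#'
#' Triangulates the skin surface between consecutive stations (ring strips)
#' plus flat end caps.
#'
#' @param phantom a `forearm_phantom`.
#' @param path output file path.
#' @param n_seg segments around the circumference.
#' @return the path, invisibly.
#' @export
export_phantom_stl <- function(phantom, path, n_seg = 48) {
  tt <- seq(0, 2 * pi, length.out = n_seg + 1)[-(n_seg + 1)]
  rings <- lapply(phantom$stations, function(st) {
    p <- ellipse_point(st$skin, tt)
    cbind(p, st$z_mm)
  })
  tris <- list()
  nxt <- c(seq_len(n_seg)[-1], 1L)
  for (k in seq_len(length(rings) - 1)) {
    b <- rings[[k]]; t2 <- rings[[k + 1]]
    for (i in seq_len(n_seg)) {
      j <- nxt[i]
      tris[[length(tris) + 1]] <- rbind(b[i, ], b[j, ], t2[j, ])
      tris[[length(tris) + 1]] <- rbind(b[i, ], t2[j, ], t2[i, ])
    }
  }
  for (endk in c(1, length(rings))) {
    r <- rings[[endk]]
    ctr <- colMeans(r)
    for (i in seq_len(n_seg)) {
      j <- nxt[i]
      tris[[length(tris) + 1]] <- if (endk == 1) rbind(ctr, r[j, ], r[i, ])
                                  else rbind(ctr, r[i, ], r[j, ])
    }
  }
  tri <- array(NA_real_, c(3, 3, length(tris)))
  for (i in seq_along(tris)) tri[, , i] <- tris[[i]]
  stl_write_ascii(tri, path, name = "phantom_skin")
  invisible(path)
}
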