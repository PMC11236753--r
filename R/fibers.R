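# Fiber diameters ------------------------------------------------------------

#' Bimodal myelinated fiber diameter distribution
#'
#' Mixture of two truncated normal components on a bounded support. The
#' default emulates the averaged human peripheral-nerve histograms used for
#' FES modeling: support 2-16 um with modes at 5 um and 11 um. The exact
#' component spreads and weights of the averaged histogram are not tabulated
#' anywhere, so the shipped values are an approximate, configurable stand-in
#' that reproduces the stated range and peak locations.
#'
#' @param means component means, um.
#' @param sds component standard deviations, um.
#' @param weights mixture weights (summing to 1).
#' @param support truncation bounds, um.
#' @return object of class `diameter_distribution`.
#' @export
diameter_distribution <- function(means = c(5, 11), sds = c(1.5, 2),
                                  weights = c(0.55, 0.45),
                                  support = c(2, 16)) {
  assert_num(means, "means", len = 2)
  assert_num(sds, "sds", lower = .Machine$double.eps, len = 2)
  assert_num(weights, "weights", lower = 0, len = 2)
  if (abs(sum(weights) - 1) > 1e-9) stopf("weights must sum to 1")
  if (support[1] >= support[2]) stopf("support must be increasing")
  structure(list(means = means, sds = sds, weights = weights,
                 support = support), class = "diameter_distribution")
}

#' Sample fiber diameters
#'
#' Draws from the truncated-normal mixture by component selection followed by
#' inverse-CDF sampling of the truncated component, so every sample lies
#' inside the support and the draw is reproducible under a fixed seed.
#'
#' @param dist a [diameter_distribution()].
#' @param n number of samples (0 gives an empty vector).
#' @param seed optional integer seed (local to this call).
#' @return numeric vector of diameters, um.
#' @export
sample_diameters <- function(dist = diameter_distribution(), n, seed = NULL) {
  if (n == 0) return(numeric(0))
  assert_num(n, "n", lower = 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  comp <- sample.int(2L, n, replace = TRUE, prob = dist$weights)
  lo <- pnorm(dist$support[1], dist$means[comp], dist$sds[comp])
  hi <- pnorm(dist$support[2], dist$means[comp], dist$sds[comp])
  qnorm(lo + runif(n) * (hi - lo), dist$means[comp], dist$sds[comp])
}

#' Histogram modes of a bimodal diameter sample
#'
#' Bins the sample into 1 um bins centered on integer diameters, locates the
#' antimode (minimum bin between the two dominant local maxima) and reports
#' the modal bin centers of the small- and large-fiber components.
#'
#' @param d numeric vector of diameters, um.
#' @param support histogram support, um.
#' @return list with `low_mode`, `high_mode`, `antimode` (bin centers, um)
#'   and the bin `counts`.
#' @export
diameter_modes <- function(d, support = c(2, 16)) {
  centers <- seq(ceiling(support[1]), floor(support[2]))
  breaks <- c(centers - 0.5, max(centers) + 0.5)
  counts <- tabulate(findInterval(d, breaks, rightmost.closed = TRUE),
                     nbins = length(centers))
  k <- length(counts)
  locmax <- which(vapply(seq_len(k), function(i) {
    left <- if (i > 1) counts[i - 1] else -Inf
    right <- if (i < k) counts[i + 1] else -Inf
    counts[i] > left & counts[i] >= right
  }, logical(1)))
  if (length(locmax) < 2)
    stopf("sample histogram is not bimodal")
  top2 <- locmax[order(counts[locmax], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  anti <- if (hi - lo < 2) lo else lo + which.min(counts[(lo + 1):(hi - 1)])
  list(low_mode = centers[lo], high_mode = centers[hi],
       antimode = centers[anti], counts = setNames(counts, centers))
}

# Node placement -------------------------------------------------------------

#' Internodal distance for a fiber diameter
#'
#' Linear map from the diameter support 2-16 um to internodal distances
#' 155-1500 um (the printed endpoints of the MRG-style scaling; the linear
#' interpolation reproduces the cited intermediate values, e.g. ~510 um at
#' 5.7 um).
#'
#' @param d_um fiber diameter, um (vectorized).
#' @return internodal distance, um.
#' @export
delta_x_um <- function(d_um) {
  assert_num(d_um, "d_um", lower = 0)
  155 + (d_um - 2) / (16 - 2) * (1500 - 155)
}

#' Place nodes of Ranvier along a fiber axis
#'
#' Nodes are spaced exactly `delta_x(d)` apart; the first node sits at a
#' uniform random offset in `[0, delta_x)` from the ROI bottom face and nodes
#' follow until the top face.
#'
#' @param d_um fiber diameter, um.
#' @param roi_length_mm axial extent of the ROI, mm.
#' @param offset_mm optional fixed first-node offset (mm); default is drawn
#'   uniformly from `[0, delta_x)` using the current RNG state.
#' @return numeric vector of node coordinates along the axis, mm, in
#'   `[0, roi_length_mm]`.
#' @export
place_nodes <- function(d_um, roi_length_mm, offset_mm = NULL) {
  dx_mm <- delta_x_um(d_um) / 1000
  if (roi_length_mm <= dx_mm)
    stopf("ROI length %.2f mm does not fit two nodes at delta_x = %.3f mm (fiber too short)",
          roi_length_mm, dx_mm)
  if (is.null(offset_mm)) offset_mm <- runif(1, 0, dx_mm)
  if (offset_mm < 0 || offset_mm >= dx_mm)
    stopf("offset must be in [0, delta_x)")
  seq(offset_mm, roi_length_mm, by = dx_mm)
}

# Fiber population ------------------------------------------------------------

#' Populate an ROI with straight myelinated fibers
#'
#' Places `n` fibers parallel to the ROI axis with cross-section positions
#' uniform over the ROI ellipse, diameters drawn from the bimodal
#' distribution, and nodes of Ranvier at diameter-dependent spacing with
#' random end offsets.
#'
#' @param roi an [roi_spec()].
#' @param n number of fibers (default 500, chosen large enough that the
#'   activation fraction is insensitive to the random draw).
#' @param dist a [diameter_distribution()].
#' @param seed optional integer seed (local to this call).
#' @return object of class `fiber_population`: `fibers` (data.frame with id,
#'   diameter, delta_x, local cross-section position, node count) and `nodes`
#'   (list of n x 3 matrices of node positions, mm).
#' @export
place_fibers <- function(roi, n = 500, dist = diameter_distribution(),
                         seed = NULL) {
  assert_num(n, "n", lower = 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  d <- sample_diameters(dist, n)
  # uniform over the ellipse: uniform disk mapped by the semi-axes
  r <- sqrt(runif(n)); a <- runif(n, 0, 2 * pi)
  u <- roi$semi_axes[1] * r * cos(a)
  v <- roi$semi_axes[2] * r * sin(a)
  base <- roi$center - (roi$length / 2) * roi$axis
  nodes <- vector("list", n)
  nnodes <- integer(n)
  dx <- delta_x_um(d)
  for (i in seq_len(n)) {
    t <- place_nodes(d[i], roi$length)
    p0 <- base + u[i] * roi$e1 + v[i] * roi$e2
    nodes[[i]] <- cbind(p0[1] + t * roi$axis[1],
                        p0[2] + t * roi$axis[2],
                        p0[3] + t * roi$axis[3])
    nnodes[i] <- length(t)
  }
  structure(list(
    muscle = roi$muscle, roi = roi,
    fibers = data.frame(id = seq_len(n), d_um = d, delta_x_um = dx,
                        u_mm = u, v_mm = v, n_nodes = nnodes),
    nodes = nodes), class = "fiber_population")
}

#' @export
print.fiber_population <- function(x, ...) {
  cat(sprintf("<fiber_population> %s: %d fibers, diameters %.1f-%.1f um, %d-%d nodes\n",
              x$muscle, nrow(x$fibers), min(x$fibers$d_um), max(x$fibers$d_um),
              min(x$fibers$n_nodes), max(x$fibers$n_nodes)))
  invisible(x)
}

#' Export a fiber population as a node table
#'
#' @param population a `fiber_population`.
#' @param path optional CSV path; if `NULL` the data.frame is returned only.
#' @return data.frame (fiber_id, muscle, d_um, node_index, x_mm, y_mm, z_mm).
#' @export
export_population_csv <- function(population, path = NULL) {
  rows <- lapply(seq_len(nrow(population$fibers)), function(i) {
    nd <- population$nodes[[i]]
    data.frame(fiber_id = i, muscle = population$muscle,
               d_um = population$fibers$d_um[i],
               node_index = seq_len(nrow(nd)),
               x_mm = nd[, 1], y_mm = nd[, 2], z_mm = nd[, 3])
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  invisible(out)
}
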