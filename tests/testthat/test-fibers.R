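test_that("the NEP table applies the stated exclusions", {
  nep <- load_nep_table()
  expect_equal(nrow(nep), 20)
  expect_false("BR" %in% nep$muscle)
  expect_equal(nep$median_pct[nep$muscle == "FCR"], 25)
  expect_equal(nep$median_pct[nep$muscle == "FDSdist"], 74)
  expect_equal(nep$proximal_pct[nep$muscle == "ECRL"], 0)  # clamped
  # finger-flexor sub-ROIs carry the offset bounds around the median
  expect_equal(nep$proximal_pct[nep$muscle == "FDSprox"], 51.5 - 5.5)
  expect_equal(nep$distal_pct[nep$muscle == "FDPdist"], 36.7 + 5.5)
})

test_that("ROIs are centered at the median NEP with 10 mm extension", {
  ph <- build_default_phantom()
  nep <- load_nep_table()
  roi <- suppressWarnings(
    build_roi(as.list(nep[nep$muscle == "FCR", ]), ph))
  expect_equal(roi$center[3], 0.25 * 242)
  expect_equal(roi$length, 20)
  # default orientation without hints is the phantom long axis
  roi2 <- build_roi(list(muscle = "X", median_pct = 40), ph, hints = NULL)
  expect_equal(roi2$axis, c(0, 0, 1))
  # out-of-range ROI errors
  expect_error(build_roi(list(muscle = "X", median_pct = 104), ph,
                         hints = NULL), "axial range")
})

test_that("sampled diameters stay in support and reproduce under a seed", {
  d1 <- sample_diameters(n = 5000, seed = 42)
  d2 <- sample_diameters(n = 5000, seed = 42)
  expect_identical(d1, d2)
  expect_true(all(d1 >= 2 & d1 <= 16))
  expect_identical(sample_diameters(n = 0), numeric(0))
})

test_that("the large-sample histogram is bimodal with modes at 5 and 11 um", {
  d <- sample_diameters(n = 1e5, seed = 7)
  m <- diameter_modes(d)
  expect_equal(m$low_mode, 5)
  expect_equal(m$high_mode, 11)
  expect_true(m$antimode > 5 && m$antimode < 11)
})

test_that("the large-fiber fraction matches the mixture weight", {
  dist <- diameter_distribution()
  n <- 1e4
  d <- sample_diameters(dist, n = n, seed = 9)
  anti <- diameter_modes(sample_diameters(dist, n = 1e5, seed = 8))$antimode
  frac <- mean(d > anti)
  # the antimode split misclassifies a small overlap mass; compare against
  # the mixture's own probability of exceeding the antimode
  p_hi <- sum(dist$weights * (pnorm(16, dist$means, dist$sds) -
                                pnorm(anti, dist$means, dist$sds))) /
    sum(dist$weights * (pnorm(16, dist$means, dist$sds) -
                          pnorm(2, dist$means, dist$sds)))
  expect_lt(abs(frac - p_hi), 3 * sqrt(p_hi * (1 - p_hi) / n))
})

test_that("internodal distance maps diameters linearly to 155-1500 um", {
  expect_equal(delta_x_um(2), 155)
  expect_equal(delta_x_um(16), 1500)
  expect_equal(delta_x_um(9), 827.5)
})

test_that("node placement spaces nodes exactly and respects the ROI faces", {
  nd <- place_nodes(16, 20, offset_mm = 0)
  expect_equal(nd, seq(0, 19.5, by = 1.5))
  expect_length(nd, 14)
  # spacing is exact for random offsets too
  set.seed(3)
  for (d in c(2.7, 8.1, 14.2)) {
    nd <- place_nodes(d, 20)
    expect_equal(diff(nd), rep(delta_x_um(d) / 1000, length(nd) - 1))
    expect_true(all(nd >= 0 & nd <= 20))
  }
  expect_error(place_nodes(16, 1.2), "too short")
})

test_that("fiber populations are uniform over the ROI ellipse", {
  roi <- roi_spec("U", c(0, 0, 0), c(0, 0, 1), semi_axes = c(6, 4),
                  length = 20)
  pop <- place_fibers(roi, n = 1e4, seed = 5)
  # chi-square on 16 equal-area cells of the unit-disk pullback
  un <- pop$fibers$u_mm / 6; vn <- pop$fibers$v_mm / 4
  r2 <- un^2 + vn^2
  expect_true(all(r2 <= 1 + 1e-12))
  sector <- floor((atan2(vn, un) + pi) / (2 * pi) * 8)
  ring <- ifelse(r2 < 0.5, 0, 1)
  cell <- sector * 2 + ring
  counts <- tabulate(cell + 1, nbins = 16)
  chi <- sum((counts - 1e4 / 16)^2 / (1e4 / 16))
  expect_lt(chi, qchisq(0.999, df = 15))
})

test_that("populations are reproducible and fibers follow the ROI axis", {
  pop1 <- test_population()
  pop2 <- place_fibers(pop1$roi, n = nrow(pop1$fibers), seed = 101)
  expect_identical(pop1$fibers, pop2$fibers)
  expect_identical(pop1$nodes, pop2$nodes)
  expect_true(all(pop1$fibers$n_nodes >= 3))
  for (nd in pop1$nodes[1:5]) {
    dirs <- diff(nd)
    expect_equal(dirs[, 2], rep(0, nrow(dirs)))  # axis is +x
    expect_equal(dirs[, 3], rep(0, nrow(dirs)))
  }
})
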