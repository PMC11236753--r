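test_that("node constants follow the diameter scaling", {
  p <- cable_params()
  nc <- derive_node_constants(10, delta_x_um(10), p)
  # C_m = 2 uF/cm^2 * pi * 7 um * 2.5 um ~ 1.10 pF
  expect_equal(nc$C_m, 2e-2 * pi * 7e-6 * 2.5e-6, tolerance = 1e-12)
  expect_equal(nc$C_m, 1.10e-12, tolerance = 0.005)
  # G_a doubles when delta_x halves
  nc2 <- derive_node_constants(10, delta_x_um(10) / 2, p)
  expect_equal(nc2$G_a, 2 * nc$G_a)
  # 15 mV depolarization threshold from the membrane potentials
  expect_equal(p$V_th - p$V_r, 15)
})

test_that("rest is stable and spatially uniform fields do not excite", {
  p <- cable_params()
  nc <- derive_node_constants(8, delta_x_um(8), p)
  times <- seq(0, 1000, by = 1)
  # zero drive holds the membrane at rest
  res0 <- simulate_lc(matrix(0, 5, length(times)), times, nc, p,
                      keep_trajectory = TRUE)
  expect_true(all(res0$v_m == 0))
  expect_false(res0$verdict$activated)
  # uniform extracellular potential: the spatial difference drive vanishes
  resu <- simulate_lc(matrix(30, 5, length(times)), times, nc, p)
  expect_equal(resu$peak_depolarization, 0)
  expect_false(resu$verdict$activated)
})

test_that("the implicit integrator matches the matrix exponential", {
  p <- cable_params()
  for (setup in list(list(d = 10, n = 3), list(d = 4, n = 9))) {
    nc <- derive_node_constants(setup$d, delta_x_um(setup$d), p)
    n <- setup$n
    times <- seq(0, 200, by = 1)
    ve <- matrix(0, n, length(times))
    ve[ceiling(n / 2), ] <- -50          # step at the center node
    res <- simulate_lc(ve, times, nc, p, keep_trajectory = TRUE)
    L <- festwin:::cable_laplacian(n)
    a <- nc$G_a / nc$C_m; gm <- nc$G_m / nc$C_m
    M <- a * L - diag(gm, n)
    b <- a * (L %*% ve[, 2])
    oracle <- vapply(times * 1e-6, function(t)
      as.numeric(solve(M, (as.matrix(Matrix::expm(M * t)) - diag(n)) %*% b)),
      numeric(n))
    expect_lt(max(abs(res$v_m - oracle)) / max(abs(oracle)), 0.001)
  }
})

test_that("closed-form thresholds agree with bisection on the simulator", {
  p <- cable_params()
  set.seed(17)
  for (i in 1:8) {
    d <- runif(1, 3, 15)
    h <- runif(1, 6, 15)
    pw <- sample(c(50, 100, 200, 400), 1)
    vu <- point_source_nodes(d, h)
    nc <- derive_node_constants(d, delta_x_um(d), p)
    a_cf <- fiber_threshold_amplitude(vu, pw, nc, p)
    activated_at <- function(A) {
      dr <- festwin:::unit_pulse_drive(vu * A, pw, p)
      simulate_lc(dr$v_e, dr$times, nc, p)$verdict$activated
    }
    lo <- a_cf / 4; hi <- a_cf * 4
    for (j in 1:30) {
      mid <- (lo + hi) / 2
      if (activated_at(mid)) hi <- mid else lo <- mid
    }
    expect_lt(abs(hi - a_cf) / a_cf, 0.005)
  }
})

test_that("responses scale linearly and hyperpolarizing fields never fire", {
  p <- cable_params()
  d <- 10
  vu <- point_source_nodes(d)
  nc <- derive_node_constants(d, delta_x_um(d), p)
  dr1 <- festwin:::unit_pulse_drive(vu, 100, p)
  dr3 <- festwin:::unit_pulse_drive(vu * 3, 100, p)
  r1 <- simulate_lc(dr1$v_e, dr1$times, nc, p, keep_trajectory = TRUE)
  r3 <- simulate_lc(dr3$v_e, dr3$times, nc, p, keep_trajectory = TRUE)
  expect_equal(r3$v_m, 3 * r1$v_m, tolerance = 1e-10)
  # a spatially uniform field never depolarizes: threshold is the Inf sentinel
  expect_equal(fiber_threshold_amplitude(rep(-40, length(vu)), 100, nc, p),
               Inf)
})

test_that("larger co-located fibers recruit at lower or equal thresholds", {
  p <- cable_params()
  set.seed(23)
  for (i in 1:25) {
    dd <- sort(runif(2, 2.5, 15.5))
    h <- runif(1, 5, 20)
    pw <- runif(1, 40, 400)
    th <- vapply(dd, function(d) {
      vu <- point_source_nodes(d, h)
      fiber_threshold_amplitude(vu, pw,
                                derive_node_constants(d, delta_x_um(d), p), p)
    }, numeric(1))
    expect_lte(th[2], th[1] * (1 + 1e-9))
  }
})

test_that("single-fiber SD curves decrease, flatten to a rheobase, and are convex", {
  p <- cable_params()
  vu <- point_source_nodes(10)
  nc <- derive_node_constants(10, delta_x_um(10), p)
  pws <- c(20, 50, 100, 200, 350, 500, 5000)
  th <- vapply(pws, function(pw)
    fiber_threshold_amplitude(vu, pw, nc, p), numeric(1))
  expect_true(all(diff(th) <= 1e-9))
  # rheobase plateau: PW 500 within 10% of PW 5000
  expect_lt(th[6] / th[7], 1.10)
  # convexity over the printed range
  pws2 <- c(20, 60, 100, 140, 180, 260, 380, 500)
  th2 <- vapply(pws2, function(pw)
    fiber_threshold_amplitude(vu, pw, nc, p), numeric(1))
  expect_true(all(diff(diff(th2) / diff(pws2)) >= -1e-9))
})
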