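test_that("the discrete activating function is exact on known fields", {
  # affine potential: second difference vanishes at interior nodes
  af <- activating_function(seq(-10, 10, length.out = 9), 500)
  expect_true(all(is.na(af[c(1, 9)])))
  expect_equal(af[2:8], rep(0, 7))
  # analytic point source: rho = 3 Ohm m, I = -1 mA, 10 mm above a node
  # -> continuous AF = rho |I| / (4 pi h^3) = 238.7 V/m^2 at that node
  dx <- 50  # um: fine spacing approximates the continuous limit
  x <- seq(-5, 5, by = dx / 1000)
  v <- festwin:::point_source_mV_per_mA(sqrt(x^2 + 100), 3, -1)
  af2 <- activating_function(v, dx)
  expect_equal(af2[which.min(abs(x))], 3 * 1e-3 / (4 * pi * 0.01^3),
               tolerance = 0.001)
  # the cathodic source depolarizes (positive AF) under the electrode
  expect_gt(af2[which.min(abs(x))], 0)
  # discrete AF converges to the continuous value as delta_x shrinks
  errs <- vapply(c(800, 400, 200), function(dxc) {
    xc <- seq(-6, 6, by = dxc / 1000)
    vc <- festwin:::point_source_mV_per_mA(sqrt(xc^2 + 100), 3, -1)
    abs(activating_function(vc, dxc)[which.min(abs(xc))] - 238.7324)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("AF verdicts respect the threshold and its monotonicity", {
  tab <- shared_af_table()
  d <- 8; pw <- 100
  vu <- point_source_nodes(d)
  af <- activating_function(vu * 20, delta_x_um(d))
  v1 <- af_predict(af, d, pw, tab)
  # all-negative AF never activates
  afneg <- af; afneg[!is.na(afneg)] <- -abs(afneg[!is.na(afneg)])
  expect_false(af_predict(afneg, d, pw, tab)$activated)
  # doubling every threshold can only shrink the activated set
  tab2 <- tab; tab2$thresholds <- tab$thresholds * 2
  v2 <- af_predict(af, d, pw, tab2)
  expect_true(v1$activated | !v2$activated)
  expect_error(af_predict(af, d, pw,
                          structure(list(thresholds = numeric(0)),
                                    class = "af_threshold_table")),
               "empty")
})

test_that("AF thresholds decrease with diameter and AF agrees with LC", {
  tab <- shared_af_table()
  # monotone non-increasing in diameter at fixed pulse width
  for (j in seq_along(tab$pw_us))
    expect_true(all(diff(tab$thresholds[, j]) <= 1e-9))
  # verdict agreement >= 90% near threshold on the calibration geometry
  p <- cable_params()
  set.seed(11)
  n <- 40; agree <- 0
  for (i in seq_len(n)) {
    d <- runif(1, 2.5, 15.5); h <- runif(1, 6, 18); pw <- runif(1, 30, 450)
    vu <- point_source_nodes(d, h)
    nc <- derive_node_constants(d, delta_x_um(d), p)
    a_th <- fiber_threshold_amplitude(vu, pw, nc, p)
    A <- runif(1, 0.5, 2) * a_th
    lc <- A >= a_th
    af <- af_predict(activating_function(vu * A, delta_x_um(d)), d, pw,
                     tab)$activated
    agree <- agree + (lc == af)
  }
  expect_gte(agree / n, 0.9)
})
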