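test_that("homogeneous cuboid reproduces the closed-form resistor voltage", {
  # dV = I L / (sigma A) = 1 mA * 0.1 m / (1/3 S/m * 1e-4 m^2) = 3.0 V
  g <- cuboid_grid(c(10, 10, 100), resolution = 2.5, sigma = 1 / 3)
  f <- solve_potential(g, current_mA = 1)
  expect_equal(f$electrode_voltage, 3.0, tolerance = 0.02)
  expect_lt(f$residual, 1e-8)
})

test_that("zero current gives the zero field", {
  g <- cuboid_grid(c(10, 10, 40), resolution = 5, sigma = 1 / 3)
  f <- solve_potential(g, current_mA = 0)
  expect_true(all(f$v_per_mA[!is.na(f$v_per_mA)] == 0))
})

test_that("the solve is linear in the injected current", {
  g <- test_grid()
  f1 <- test_field()
  for (alpha in c(0.5, 2, 10)) {
    fa <- solve_potential(g, current_mA = alpha)
    expect_equal(fa$v_per_mA, f1$v_per_mA, tolerance = 1e-10)
  }
})

test_that("current is conserved across interior cross-sections", {
  g <- cuboid_grid(c(10, 10, 100), resolution = 2.5, sigma = 1 / 3)
  f <- solve_potential(g, current_mA = 1)
  for (k in c(5, 20, 35))
    expect_equal(festwin:::plane_current(g, f, k), 1, tolerance = 0.02)
  # also on the patch-electrode cuboid (genuinely 3D field)
  g2 <- test_grid(); f2 <- test_field()
  for (k in c(3, 15, 27))
    expect_equal(festwin:::plane_current(g2, f2, k), 1, tolerance = 0.02)
})

test_that("refining the grid converges monotonically", {
  set.seed(21)
  pts <- cbind(runif(10, -10, 10), runif(10, -10, 10), runif(10, 15, 45))
  vs <- lapply(c(8, 4, 2), function(h) {
    gi <- cuboid_grid(c(40, 40, 60), resolution = h, sigma = 1 / 3,
                      active_patch_mm = 8)
    sample_potential(solve_potential(gi), pts)
  })
  d12 <- sqrt(mean((vs[[1]] - vs[[2]])^2))
  d23 <- sqrt(mean((vs[[2]] - vs[[3]])^2))
  expect_lt(d23, d12)
})

test_that("mirror-symmetric points see equal potentials", {
  f <- test_field()
  v <- sample_potential(f, rbind(c(-8, 0, 21), c(8, 0, 21),
                                 c(0, -8, 21), c(0, 8, 21)))
  expect_equal(v[2], v[1], tolerance = 1e-10)
  expect_equal(v[4], v[3], tolerance = 1e-10)
})

test_that("anisotropic muscle decays slower along the high-conductivity axis", {
  g <- cuboid_grid(c(60, 60, 120), resolution = 3,
                   sigma = c(1 / 9, 1 / 9, 1 / 3), active_patch_mm = 6)
  f <- solve_potential(g)
  vz <- sample_potential(f, rbind(c(0, 0, 3), c(0, 0, 13)))
  vx <- sample_potential(f, rbind(c(3, 0, 1), c(13, 0, 1)))
  expect_gt(vz[2] / vz[1], vx[2] / vx[1])
})

test_that("missing electrodes and outside points raise explicit errors", {
  g <- cuboid_grid(c(10, 10, 40), resolution = 5)
  g$electrode_faces$indifferent <- g$electrode_faces$indifferent[0, ]
  expect_error(solve_potential(g), "sink")
  f <- test_field()
  expect_error(sample_potential(f, rbind(c(500, 0, 0))), "outside")
})

test_that("potential time courses factorize into space and time", {
  f <- test_field()
  pulse <- stimulus_pulse(amplitude = 12, pulse_width = 200)
  pts <- rbind(c(0, 0, 10), c(5, -3, 25))
  s <- sample_potential(f, pts, pulse)
  v_unit <- sample_potential(f, pts)
  # zero before onset, amplitude-scaled at the plateau
  expect_equal(s$v_e[, s$times == 0], c(0, 0))
  mid <- which(s$times == 110)
  expect_equal(s$v_e[, mid], v_unit * 1000 * 12)
})

test_that("the pulse waveform has the stated support and plateau", {
  p <- stimulus_pulse(7, 300, ramp_in = 10, ramp_out = 20)
  expect_equal(p$waveform(c(-5, 0, 331, 400)), c(0, 0, 0, 0))
  expect_equal(p$waveform(c(10, 150, 310)), c(7, 7, 7))
  expect_equal(p$waveform(5), 3.5)
})
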