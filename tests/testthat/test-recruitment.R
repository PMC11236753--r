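test_that("activation fractions hit the trivial endpoints and exact counts", {
  pop <- test_population()
  f <- test_field()
  th <- fiber_thresholds(pop, f, 200)
  expect_equal(roi_activation_fraction(pop, f, stimulus_pulse(0, 200)), 0)
  big <- max(th[is.finite(th)]) * 1.01
  expect_equal(roi_activation_fraction(pop, f, stimulus_pulse(big, 200)), 1)
  a <- unname(quantile(th, 0.4, type = 1))
  expect_equal(roi_activation_fraction(pop, f, stimulus_pulse(a, 200)),
               sum(th <= a) / length(th))
  expect_error(roi_activation_fraction(
    structure(list(fibers = data.frame()), class = "fiber_population"),
    f, stimulus_pulse(1, 200)), "empty")
})

test_that("order-statistic SD thresholds equal bisection over the fraction", {
  pop <- test_population()
  f <- test_field()
  set.seed(31)
  for (i in 1:5) {
    pw <- sample(c(50, 100, 250, 400), 1)
    ath <- runif(1, 0.1, 0.6)
    crv <- sd_curve(pop, f, pw, ath, bounds = c(0, 1000))
    a_os <- crv$points$amp_mA
    frac_at <- function(A)
      roi_activation_fraction(pop, f, stimulus_pulse(A, pw))
    lo <- 0; hi <- 200
    for (j in 1:40) {
      mid <- (lo + hi) / 2
      if (frac_at(mid) >= ath) hi <- mid else lo <- mid
    }
    expect_equal(a_os, hi, tolerance = 1e-6)
  }
})

test_that("SD curves are non-increasing and deterministic; grid mode rounds up", {
  pop <- test_population()
  f <- test_field()
  pws <- c(20, 50, 100, 200, 300, 500)
  crv <- sd_curve(pop, f, pws, ath = 0.2, bounds = c(0, 1000))
  ok <- is.finite(crv$points$amp_mA)
  expect_true(all(diff(crv$points$amp_mA[ok]) <= 1e-9))
  crv2 <- sd_curve(pop, f, pws, ath = 0.2, bounds = c(0, 1000))
  expect_identical(crv$points, crv2$points)
  g <- sd_curve(pop, f, pws, ath = 0.2, mode = "grid", bounds = c(0, 1000))
  expect_equal(g$points$amp_mA, ceiling(crv$points$amp_mA))
  # out-of-bounds thresholds become the not-reached sentinel
  tight <- sd_curve(pop, f, pws, ath = 0.2, bounds = c(0, 0.01))
  expect_true(all(is.na(tight$points$amp_mA)))
  # rheobase plateau at the population level
  wide <- sd_curve(pop, f, c(500, 5000), ath = 0.2, bounds = c(0, 1e4))
  expect_lt(wide$points$amp_mA[1] / wide$points$amp_mA[2], 1.10)
})

test_that("intensity-activation curves are monotone with onset at the SD threshold", {
  pop <- test_population()
  f <- test_field()
  pw <- 200; ath <- 0.25
  th_sd <- sd_curve(pop, f, pw, ath, bounds = c(0, 1000))$points$amp_mA
  th_all <- fiber_thresholds(pop, f, pw)
  amps <- seq(0, ceiling(max(th_all[is.finite(th_all)]) * 1.05), by = 0.5)
  cur <- intensity_activation_curve(pop, f, pw, amps, ath)
  expect_true(all(diff(cur$fraction) >= 0))
  onset <- min(cur$amp_mA[cur$active])
  # the onset is the first grid amplitude at/above the SD threshold
  expect_equal(onset, min(amps[amps >= th_sd]))
  # recruitment passes 0.1 -> 0.9 over a finite amplitude span (sigmoid-like)
  expect_true(any(cur$fraction <= 0.1) && any(cur$fraction >= 0.9))
  expect_error(intensity_activation_curve(pop, f, pw, rev(amps), ath),
               "ascending")
})
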