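test_that("the Weiss fit recovers parameters and is scale-equivariant", {
  pw <- experimental_pw_grid()
  f <- fit_sd(pw, 5 * (1 + 200 / pw))
  expect_equal(f$b, 5, tolerance = 0.01)
  expect_equal(f$c, 200, tolerance = 0.01)
  f2 <- fit_sd(pw, 2 * 5 * (1 + 200 / pw))
  expect_equal(f2$b, 2 * f$b, tolerance = 1e-9)
  expect_equal(f2$c, f$c, tolerance = 1e-9)
  # flat data collapse to the single-parameter limit c = 0
  ff <- fit_sd(pw, rep(4.2, length(pw)))
  expect_equal(ff$b, 4.2)
  expect_equal(ff$c, 0, tolerance = 1e-9)
  expect_equal(predict(ff, c(20, 500)), c(4.2, 4.2))
  expect_error(fit_sd(c(100, 100, 100), c(1, 2, 3)), "distinct")
})

test_that("mean relative difference follows its definition", {
  pw <- experimental_pw_grid()
  base <- fit_sd(pw, 5 * (1 + 200 / pw))
  expect_equal(mean_rel_diff(base, base, c(20, 200)), 0)
  up <- fit_sd(pw, 1.1 * 5 * (1 + 200 / pw))
  expect_equal(mean_rel_diff(up, base, c(20, 200)), 0.1, tolerance = 1e-9)
  expect_equal(mean_rel_diff(up, base, c(201, 500)), 0.1, tolerance = 1e-9)
  # the 20-200 us range spans 181 integer pulse widths
  expect_length(seq(20, 200), 181)
  # zero iff coincident on every integer pulse width
  expect_gt(mean_rel_diff(fit_sd(pw, 5 * (1 + 201 / pw)), base, c(20, 200)), 0)
})

test_that("ath selection reproduces the packaged table's decisions", {
  tab <- load_rel_diff_table()
  ecu <- select_ath(tab[tab$muscle == "ECU" & tab$pw_range == "20-200", ],
                    "ECU", "20-200")
  expect_equal(ecu$ath, 0.30)
  expect_equal(ecu$min_value, 0.030)
  expect_false(ecu$tie_break_used)
  # ED ties at printed precision; the fourth decimal decides for 0.20
  ed <- select_ath(tab[tab$muscle == "ED" & tab$pw_range == "20-200", ],
                   "ED", "20-200")
  expect_equal(ed$ath, 0.20)
  expect_true(ed$tie_break_used)
  # unique minimum in a synthetic map
  s <- select_ath(setNames(c(0.3, 0.1, 0.2), c(0.05, 0.10, 0.15)))
  expect_equal(s$ath, 0.10)
  expect_false(s$tie_break_used)
  # permutation invariance of the candidate ordering
  s2 <- select_ath(setNames(c(0.2, 0.3, 0.1), c(0.15, 0.05, 0.10)))
  expect_equal(s2$ath, s$ath)
  # exact ties resolve to the smaller ath
  s3 <- select_ath(setNames(c(0.2, 0.1, 0.1), c(0.05, 0.10, 0.15)))
  expect_equal(s3$ath, 0.10)
})

test_that("range-wise default thresholds average the selected values", {
  sel <- select_ath_table()
  expect_equal(nrow(sel), 16)
  d <- default_ath(sel)
  expect_equal(unname(d["20-200"]), 0.20)
  expect_equal(unname(d["201-500"]), 0.12)
  # a single selection is its own (rounded-up) default
  one <- data.frame(pw_range = "20-200", ath = 0.15)
  expect_equal(unname(default_ath(one)), 0.15)
})

test_that("RSD follows the sample-standard-deviation convention", {
  expect_equal(rsd(rbind(rep(2, 6), rep(2, 6))), 0)
  expect_equal(rsd(rbind(rep(1, 4), rep(3, 4))), sqrt(2) / 2)
  m <- rbind(c(5, 4, 3), c(6, 5, 4), c(5.5, 4.5, 3.2))
  expect_equal(rsd(3 * m), rsd(m))
  expect_error(rsd(rbind(c(1, 2, 3))), ">= 2")
})
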