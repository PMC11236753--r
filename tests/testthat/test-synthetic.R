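test_that("synthetic experiments emulate the measurement protocol", {
  ex <- generate_experiment(seed = 3)
  expect_equal(sort(unique(ex$pw_us)), experimental_pw_grid())
  expect_length(experimental_pw_grid(), 13)
  expect_equal(max(ex$repeat_id), 4)
  expect_true(all(ex$amp_mA > 0))
  # reproducible under the seed
  expect_identical(ex, generate_experiment(seed = 3))
})

test_that("noiseless repeats are identical with zero RSD and exact recovery", {
  ex <- generate_experiment(b = 5, c = 200, noise_sd = 0, seed = 1)
  m <- do.call(rbind, lapply(split(ex$amp_mA, ex$repeat_id), rbind))
  expect_equal(rsd(m), 0)
  f <- fit_sd(ex$pw_us[ex$repeat_id == 1], ex$amp_mA[ex$repeat_id == 1])
  expect_equal(f$b, 5, tolerance = 0.01)
  expect_equal(f$c, 200, tolerance = 0.01)
})

test_that("the default noise level lands repeats in the reported RSD band", {
  # average over seeds: the generator emulates the 0.04-0.09 repeat spread
  r <- vapply(1:10, function(s) {
    ex <- generate_experiment(seed = s)
    rsd(do.call(rbind, lapply(split(ex$amp_mA, ex$repeat_id), rbind)))
  }, numeric(1))
  expect_gt(mean(r), 0.04)
  expect_lt(mean(r), 0.09)
})

test_that("packaged fixtures carry the printed values", {
  fx <- reference_tables()
  expect_named(fx, c("materials", "nep_table", "cable_params",
                     "settings_grid", "electrode_positions",
                     "rel_diff_table"))
  mats <- default_materials()
  expect_equal(mats$muscle$sigma_axial, 1 / 3)
  expect_equal(mats$muscle$sigma_radial, 1 / 9)
  expect_equal(mats$hydrogel$sigma_axial, 1 / 11)
  expect_equal(mats$skin$sigma_axial, 1 / 700)
  expect_equal(mats$fat$sigma_axial, 1 / 33)
  expect_equal(mats$bone$sigma_axial, 1 / 50)
  expect_equal(mats$skin$epsilon_r, 6000)
  nep <- load_nep_table()
  expect_equal(nep$median_pct[nep$muscle == "FCR"], 25)
  cp <- load_cable_params_table()
  expect_equal(cp$value[cp$symbol == "rho_i"], "0.7")
  expect_equal(cp$value[cp$symbol == "V_r"], "-70")
})

test_that("voxelized grids carry the printed conductivities per material", {
  ph <- build_default_phantom()
  pair <- default_electrode_pair("ECU")
  g <- suppressWarnings(voxelize(ph, list(pair$active, pair$indifferent),
                                 resolution = 5))
  mus <- g$material == festwin:::MAT_MUSCLE
  expect_true(any(mus))
  expect_equal(unique(g$sigma_z[mus]), 1 / 3)
  expect_equal(unique(g$sigma_x[mus]), 1 / 9)
  hyd <- g$material == festwin:::MAT_HYDROGEL
  expect_true(any(hyd))
  expect_equal(unique(g$sigma_z[hyd]), 1 / 11)
  # empty electrode list: tissue-only grid
  g0 <- suppressWarnings(voxelize(ph, list(), resolution = 5))
  expect_length(g0$electrode_faces, 0)
  expect_false(any(g0$material == festwin:::MAT_HYDROGEL))
})
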