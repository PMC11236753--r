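# shared small fixtures, built once per test run

.fixtures <- new.env()

# extracellular unit potential (mV per mA, cathodic) of a point source at
# height h_mm above a straight fiber of diameter d_um, nodes centered
point_source_nodes <- function(d_um, h_mm = 10, half_len_mm = 20,
                               rho_ohm_m = 3) {
  x <- seq(-half_len_mm, half_len_mm, by = delta_x_um(d_um) / 1000)
  festwin:::point_source_mV_per_mA(sqrt(x^2 + h_mm^2), rho_ohm_m, -1)
}

# small cuboid field with a surface patch electrode (solved once)
test_field <- function() {
  if (is.null(.fixtures$field)) {
    g <- cuboid_grid(c(40, 40, 60), resolution = 2, sigma = 1 / 3,
                     active_patch_mm = 6)
    .fixtures$grid <- g
    .fixtures$field <- solve_potential(g)
  }
  .fixtures$field
}
test_grid <- function() { test_field(); .fixtures$grid }

# small fiber population transverse to the patch electrode axis
test_population <- function(n = 40, seed = 101) {
  key <- sprintf("pop_%d_%d", n, seed)
  if (is.null(.fixtures[[key]])) {
    roi <- roi_spec("TEST", center = c(0, 0, 15), axis = c(1, 0, 0),
                    semi_axes = c(6, 4), length = 24)
    .fixtures[[key]] <- place_fibers(roi, n = n, seed = seed)
  }
  .fixtures[[key]]
}

# AF table is expensive to calibrate; share it across tests
shared_af_table <- function() {
  if (is.null(.fixtures$af_table)) .fixtures$af_table <- default_af_table()
  .fixtures$af_table
}
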