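#' Tissue and electrode material specification
#'
#' A material carries a (possibly anisotropic) conductivity and a relative
#' permittivity. The potential solver is purely resistive (quasi-static
#' approximation for rectangular stimulation pulses), so `epsilon_r` is carried
#' for completeness and future extension but does not enter the solve.
#'
#' @param name material name.
#' @param sigma_axial conductivity along the arm axis, S/m.
#' @param sigma_radial conductivity transverse to the arm axis, S/m
#'   (defaults to `sigma_axial`; only skeletal muscle is anisotropic).
#' @param epsilon_r relative permittivity (dimensionless, >= 1).
#' @return an object of class `material_spec`.
#' @export
material_spec <- function(name, sigma_axial, sigma_radial = sigma_axial,
                          epsilon_r = 1) {
  assert_num(sigma_axial, "sigma_axial", lower = .Machine$double.eps)
  assert_num(sigma_radial, "sigma_radial", lower = .Machine$double.eps)
  assert_num(epsilon_r, "epsilon_r", lower = 1)
  structure(list(name = as.character(name), sigma_axial = sigma_axial,
                 sigma_radial = sigma_radial, epsilon_r = epsilon_r),
            class = "material_spec")
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("<material_spec> %s: sigma = %.5g/%.5g S/m (axial/radial), eps_r = %g\n",
              x$name, x$sigma_axial, x$sigma_radial, x$epsilon_r))
  invisible(x)
}

#' Standard FES material table
#'
#' Loads the packaged standard material values used throughout transcutaneous
#' FES simulation (hydrogel, skin, fat, anisotropic muscle, cortical bone).
#' Conductivities are stored in the source CSV as the printed fractions
#' (e.g. muscle 1/3 S/m axial, 1/9 S/m radial) and parsed on load.
#'
#' @param path optional CSV overriding the packaged table (same columns:
#'   `material`, `sigma_S_per_m`, `epsilon_r`).
#' @return named list of [material_spec()]: `hydrogel`, `skin`, `fat`,
#'   `muscle`, `bone`.
#' @export
default_materials <- function(path = NULL) {
  tab <- read.csv(path %||% fixture_path("materials.csv"),
                  stringsAsFactors = FALSE)
  sig <- setNames(parse_fraction(tab$sigma_S_per_m), tab$material)
  eps <- setNames(as.numeric(tab$epsilon_r), tab$material)
  list(
    hydrogel = material_spec("hydrogel", sig[["Hydrogel"]],
                             epsilon_r = eps[["Hydrogel"]]),
    skin = material_spec("skin", sig[["Skin"]], epsilon_r = eps[["Skin"]]),
    fat = material_spec("fat", sig[["Fat"]], epsilon_r = eps[["Fat"]]),
    muscle = material_spec("muscle", sig[["Muscle (axial)"]],
                           sig[["Muscle (radial)"]],
                           epsilon_r = eps[["Muscle (axial)"]]),
    bone = material_spec("bone", sig[["Bone"]], epsilon_r = eps[["Bone"]])
  )
}
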