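# Synthetic experimental strength-duration data ------------------------------

#' Experimental pulse-width grid
#'
#' The measurement protocol's 13 pulse widths: 20-100 us in 20 us steps and
#' 150-500 us in 50 us steps.
#'
#' @return integer vector of pulse widths, us.
#' @export
experimental_pw_grid <- function() {
  c(seq(20, 100, by = 20), seq(150, 500, by = 50))
}

#' Simulation amplitude grid
#'
#' The simulation protocol's amplitude grid: 1-50 mA in 1 mA increments.
#'
#' @return numeric vector, mA.
#' @export
simulation_amplitude_grid <- function() seq(1, 50, by = 1)

#' Load the packaged stimulation settings grid
#'
#' @param path optional CSV override.
#' @return data.frame mirroring the printed settings table.
#' @export
load_settings_grid <- function(path = NULL) {
  read.csv(path %||% fixture_path("settings_grid.csv"),
           stringsAsFactors = FALSE, check.names = FALSE)
}

#' Synthetic repeated strength-duration experiments
#'
#' Emulates the repeated electrode-placement experiments: the true curve is a
#' Weiss hyperbola `A(PW) = b (1 + c/PW)` and each measured point carries
#' multiplicative zero-mean Gaussian noise, independently per point and
#' repeat. The raw measurements behind the published evaluation are not
#' deposited, so this generator stands in for them; the default relative
#' noise (6%) places the repeat-to-repeat relative standard deviation in the
#' published 0.04-0.09 band.
#'
#' @param muscle label.
#' @param b true rheobase, mA.
#' @param c true chronaxie, us.
#' @param noise_sd relative noise standard deviation (>= 0).
#' @param repeats number of repeated experiments.
#' @param seed integer seed (local to this call).
#' @param pw_grid pulse widths, us (default: the experimental 13-point grid).
#' @return data.frame (muscle, repeat_id, pw_us, amp_mA) of class
#'   `synthetic_experiment`.
#' @export
generate_experiment <- function(muscle = "FCR", b = 5, c = 200,
                                noise_sd = 0.06, repeats = 4, seed = NULL,
                                pw_grid = experimental_pw_grid()) {
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  assert_num(b, "b", lower = .Machine$double.eps)
  assert_num(c, "c", lower = 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  truth <- b * (1 + c / pw_grid)
  out <- do.call(rbind, lapply(seq_len(repeats), function(r) {
    eps <- rnorm(length(pw_grid), 0, noise_sd)
    data.frame(muscle = muscle, repeat_id = r, pw_us = pw_grid,
               amp_mA = pmax(truth * (1 + eps), .Machine$double.eps),
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("synthetic_experiment", "data.frame")
  out
}

#' Load the packaged cable-parameter table
#'
#' @param path optional CSV override.
#' @return data.frame mirroring the printed axon/membrane characteristics.
#' @export
load_cable_params_table <- function(path = NULL) {
  read.csv(path %||% fixture_path("cable_params.csv"),
           stringsAsFactors = FALSE)
}

#' All packaged reference tables
#'
#' The literature and protocol tables the simulator ships with, as raw
#' data.frames (loaders above apply parsing and exclusions).
#'
#' @return named list: `materials`, `nep_table`, `cable_params`,
#'   `settings_grid`, `electrode_positions`, `rel_diff_table`.
#' @export
reference_tables <- function() {
  list(materials = read.csv(fixture_path("materials.csv"),
                            stringsAsFactors = FALSE),
       nep_table = read.csv(fixture_path("nep_table.csv"),
                            stringsAsFactors = FALSE),
       cable_params = load_cable_params_table(),
       settings_grid = load_settings_grid(),
       electrode_positions = load_electrode_positions(),
       rel_diff_table = read.csv(fixture_path("rel_diff_table.csv"),
                                 stringsAsFactors = FALSE,
                                 check.names = FALSE))
}
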