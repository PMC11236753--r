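# Muscle recruitment ---------------------------------------------------------

# per-node unit potentials (mV per mA of stimulus, sign included) for every
# fiber of a population; polarity "cathodic" makes the active electrode the
# cathode (depolarizing phase), which is the stimulator convention
population_unit_potentials <- function(population, field,
                                       polarity = c("cathodic", "anodic")) {
  polarity <- match.arg(polarity)
  sgn <- if (polarity == "cathodic") -1 else 1
  lapply(population$nodes, function(nd)
    sgn * sample_unit_potential(field, nd) * 1000)   # V/mA -> mV/mA
}

#' Per-fiber activation threshold amplitudes
#'
#' Computes the closed-form cable-model threshold amplitude of every fiber in
#' a population for one pulse width, using the unit-current field solution.
#'
#' @param population a `fiber_population`.
#' @param field a `potential_field` solved for the electrode pair.
#' @param pulse_width plateau width, us.
#' @param params a [cable_params()].
#' @param polarity `"cathodic"` (default) or `"anodic"` drive at the active
#'   electrode.
#' @param v_units optional precomputed list from the internal unit-potential
#'   sampler (saves resampling across pulse widths).
#' @return numeric vector of thresholds, mA (`Inf` where the field never
#'   depolarizes).
#' @export
fiber_thresholds <- function(population, field, pulse_width,
                             params = cable_params(), polarity = "cathodic",
                             v_units = NULL) {
  if (is.null(v_units))
    v_units <- population_unit_potentials(population, field, polarity)
  n <- nrow(population$fibers)
  out <- numeric(n)
  for (i in seq_len(n)) {
    const <- derive_node_constants(population$fibers$d_um[i],
                                   population$fibers$delta_x_um[i], params)
    out[i] <- fiber_threshold_amplitude(v_units[[i]], pulse_width, const,
                                        params)
  }
  out
}

#' Fraction of an ROI's fibers activated by a pulse
#'
#' @param population a `fiber_population` (non-empty).
#' @param field a `potential_field`.
#' @param pulse a [stimulus_pulse()].
#' @param params a [cable_params()].
#' @param model `"lc"` (linear cable; exact via per-fiber closed-form
#'   thresholds) or `"af"` (activating function with threshold table).
#' @param af_table AF threshold table (model `"af"` only).
#' @param polarity drive polarity at the active electrode.
#' @return activation fraction in [0, 1].
#' @export
roi_activation_fraction <- function(population, field, pulse,
                                    params = cable_params(), model = "lc",
                                    af_table = NULL, polarity = "cathodic") {
  n <- nrow(population$fibers)
  if (n == 0) stopf("empty fiber population")
  if (model == "lc") {
    th <- fiber_thresholds(population, field, pulse$pulse_width, params,
                           polarity)
    mean(pulse$amplitude >= th)
  } else {
    if (is.null(af_table)) af_table <- default_af_table(params)
    v_units <- population_unit_potentials(population, field, polarity)
    act <- vapply(seq_len(n), function(i) {
      v_e <- v_units[[i]] * pulse$amplitude
      af <- activating_function(v_e, population$fibers$delta_x_um[i])
      af_predict(af, population$fibers$d_um[i], pulse$pulse_width,
                 af_table, fiber_id = i)$activated
    }, logical(1))
    mean(act)
  }
}

#' Simulated strength-duration curve for one muscle
#'
#' For each pulse width, the threshold amplitude is the smallest amplitude at
#' which the activation fraction reaches `ath`. Under the linear cable model
#' this is exactly the `ceiling(ath * n)`-th order statistic of the per-fiber
#' closed-form thresholds (continuous mode); grid mode rounds up to the 1 mA
#' amplitude grid of the experimental protocol.
#'
#' @param population a `fiber_population`.
#' @param field a `potential_field`.
#' @param pw_list pulse widths, us.
#' @param ath activation threshold (fraction of the ROI) in (0, 1).
#' @param params a [cable_params()].
#' @param bounds amplitude search bounds, mA; thresholds above the upper
#'   bound are recorded as NA (not reached).
#' @param mode `"continuous"` or `"grid"` (1 mA increments).
#' @param polarity drive polarity at the active electrode.
#' @return object of class `sd_curve`: data.frame `points` (pw_us, amp_mA),
#'   plus `ath`, `model`, `mode`.
#' @export
sd_curve <- function(population, field, pw_list, ath,
                     params = cable_params(), bounds = c(0, 50),
                     mode = c("continuous", "grid"), polarity = "cathodic") {
  mode <- match.arg(mode)
  if (ath <= 0 || ath >= 1) stopf("ath must be in (0, 1)")
  n <- nrow(population$fibers)
  k <- ceiling(ath * n)
  v_units <- population_unit_potentials(population, field, polarity)
  amps <- vapply(pw_list, function(pw) {
    th <- sort(fiber_thresholds(population, field, pw, params, polarity,
                                v_units = v_units))
    a <- th[k]
    if (mode == "grid") a <- ceiling(a)
    if (!is.finite(a) || a > bounds[2] || a < bounds[1]) NA_real_ else a
  }, numeric(1))
  structure(list(points = data.frame(pw_us = pw_list, amp_mA = amps),
                 muscle = population$muscle, ath = ath, model = "LC",
                 mode = mode), class = "sd_curve")
}

#' @export
print.sd_curve <- function(x, ...) {
  cat(sprintf("<sd_curve> %s (ath = %.2f, %s, %s): %d pulse widths, amplitudes %.2f-%.2f mA\n",
              x$muscle %||% "?", x$ath, x$model, x$mode, nrow(x$points),
              min(x$points$amp_mA, na.rm = TRUE),
              max(x$points$amp_mA, na.rm = TRUE)))
  invisible(x)
}

#' Intensity-activation curve at a fixed pulse width
#'
#' Activation fraction over an ascending amplitude grid; the `active` flag
#' marks amplitudes at which the muscle counts as active (fraction >= ath),
#' i.e. the "corrected" reading whose onset equals the strength-duration
#' threshold at that pulse width.
#'
#' @param population a `fiber_population`.
#' @param field a `potential_field`.
#' @param pw_us pulse width, us.
#' @param amplitudes ascending amplitude grid, mA.
#' @param ath activation threshold in (0, 1).
#' @param params a [cable_params()].
#' @param polarity drive polarity.
#' @return data.frame (amp_mA, fraction, active).
#' @export
intensity_activation_curve <- function(population, field, pw_us, amplitudes,
                                       ath, params = cable_params(),
                                       polarity = "cathodic") {
  if (is.unsorted(amplitudes)) stopf("amplitude grid must be ascending")
  th <- sort(fiber_thresholds(population, field, pw_us, params, polarity))
  frac <- vapply(amplitudes, function(a) mean(a >= th), numeric(1))
  data.frame(amp_mA = amplitudes, fraction = frac, active = frac >= ath)
}
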