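# Strength-duration curve fitting and comparison -----------------------------

#' Fit a Weiss hyperbola to strength-duration points
#'
#' Fits `A(PW) = b (1 + c / PW)` by least squares; the model is linear in
#' `(b, b c)` via the regressor `1/PW`, so the fit is exact noiseless
#' recovery. `b` is the rheobase-like plateau amplitude (mA) and `c` the
#' chronaxie-like time constant (us). Flat data give `c = 0`.
#'
#' @param pw_us pulse widths, us (>= 3 distinct values).
#' @param amp_mA amplitudes, mA.
#' @return object of class `sd_fit` with `b`, `c`, `residuals` and the fitted
#'   PW range; evaluable with [predict.sd_fit()].
#' @export
fit_sd <- function(pw_us, amp_mA) {
  keep <- is.finite(pw_us) & is.finite(amp_mA)
  pw_us <- pw_us[keep]; amp_mA <- amp_mA[keep]
  if (length(unique(pw_us)) < 3)
    stopf("degenerate strength-duration data: need >= 3 distinct pulse widths")
  fit <- lm(amp_mA ~ I(1 / pw_us))
  b <- unname(coef(fit)[1]); bc <- unname(coef(fit)[2])
  if (!is.finite(b) || b <= 0)
    stopf("degenerate strength-duration data: non-positive rheobase estimate")
  c_us <- bc / b
  if (c_us < 0) {
    warnf("amplitudes increase with pulse width; clamping chronaxie to 0")
    c_us <- 0
  }
  structure(list(b = b, c = c_us, residuals = unname(residuals(fit)),
                 pw_range = range(pw_us)), class = "sd_fit")
}

#' Evaluate a fitted strength-duration curve
#'
#' @param object an `sd_fit`.
#' @param pw_us pulse widths, us (>= 1).
#' @param ... unused.
#' @return amplitudes, mA.
#' @export
predict.sd_fit <- function(object, pw_us, ...) {
  assert_num(pw_us, "pw_us", lower = 1)
  object$b * (1 + object$c / pw_us)
}

#' @export
print.sd_fit <- function(x, ...) {
  cat(sprintf("<sd_fit> A(PW) = %.4g (1 + %.4g / PW) mA; RMS residual %.3g mA (PW %g-%g us)\n",
              x$b, x$c, sqrt(mean(x$residuals^2)), x$pw_range[1], x$pw_range[2]))
  invisible(x)
}

# evaluate either an sd_fit or an sd_curve at integer pulse widths
eval_sd <- function(obj, pw) {
  if (inherits(obj, "sd_fit")) return(predict(obj, pw))
  if (inherits(obj, "sd_curve")) {
    pts <- obj$points[is.finite(obj$points$amp_mA), ]
    if (nrow(pts) < 2) stopf("sd_curve has too few finite points to evaluate")
    if (min(pw) < min(pts$pw_us) || max(pw) > max(pts$pw_us))
      stopf("requested pulse widths outside the curve's range")
    return(approx(pts$pw_us, pts$amp_mA, xout = pw)$y)
  }
  stopf("expected an sd_fit or sd_curve")
}

#' Mean relative difference between two strength-duration curves
#'
#' Evaluates both curves at every integer pulse width in the range
#' (inclusive; e.g. 20-200 us uses 181 points) and averages
#' `|A_sim - A_exp| / A_exp`.
#'
#' @param sim simulated curve: `sd_fit` or `sd_curve` (point curves are
#'   interpolated linearly between their pulse widths).
#' @param exp experimental fitted curve: `sd_fit`.
#' @param pw_range c(lower, upper) pulse width bounds, us.
#' @return mean relative difference (>= 0).
#' @export
mean_rel_diff <- function(sim, exp, pw_range) {
  pw <- seq(ceiling(pw_range[1]), floor(pw_range[2]))
  a_exp <- eval_sd(exp, pw)
  if (any(a_exp == 0)) stopf("experimental curve is zero inside the range")
  a_sim <- eval_sd(sim, pw)
  mean(abs(a_sim - a_exp) / a_exp)
}
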