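#' Centre of pressure from ankle torque
#'
#' With the platform stationary, the anterior-posterior centre of pressure is
#' the ankle torque divided by body weight: `x_cop(t) = torque(t) / (mass *
#' g)`. Only valid for platform-stationary segments; on a moving platform the
#' reaction force contains platform-driven components.
#'
#' @param torque numeric series, ankle torque in N*m.
#' @param body_mass body mass in kg (> 0).
#' @param g gravitational acceleration, m/s^2.
#' @return numeric series, x_cop in m.
#' @export
cop_from_torque <- function(torque, body_mass, g = 9.81) {
  if (!is.numeric(body_mass) || length(body_mass) != 1L || body_mass <= 0)
    stop("`body_mass` must be a single positive number (kg)")
  torque / (body_mass * g)
}

#' Fit centre-of-mass calibration coefficients
#'
#' During a quasi-static calibration motion the centre of pressure tracks the
#' centre-of-mass projection, so a least-squares regression of `x_cop` on the
#' hip and shoulder translations yields coefficients `(a, b, c)` with
#' `x_com = a + b * x_hip + c * x_sho`. The fit is a joint ordinary
#' least-squares regression on both predictors.
#'
#' @param x_hip,x_sho,x_cop numeric series (m), equal length >= 3.
#' @param max_condition reject designs whose (centred, scaled) predictor
#'   matrix has a condition number above this bound (collinearity guard).
#' @return object of class `calibration_coefficients`: list with `a` (m),
#'   `b`, `c` (dimensionless), `residual_rms` (m), `n_samples`.
#' @export
fit_calibration <- function(x_hip, x_sho, x_cop, max_condition = 1e8) {
  n <- length(x_cop)
  if (length(x_hip) != n || length(x_sho) != n)
    stop("x_hip, x_sho, x_cop must have equal length")
  if (n < 3L) stop("need at least 3 samples to fit 3 coefficients")
  sd_h <- stats::sd(x_hip); sd_s <- stats::sd(x_sho)
  if (sd_h == 0 || sd_s == 0)
    stop("rank-deficient design: a regressor is constant")
  # condition number of the standardized design (hip, sho)
  Z <- cbind((x_hip - mean(x_hip)) / sd_h, (x_sho - mean(x_sho)) / sd_s)
  sv <- svd(Z, nu = 0, nv = 0)$d
  if (sv[2] <= 0 || sv[1] / sv[2] > max_condition)
    stop(sprintf(
      "rank-deficient design: hip and shoulder translations are collinear (condition number %.3g)",
      if (sv[2] > 0) sv[1] / sv[2] else Inf))
  fit <- stats::lm.fit(cbind(1, x_hip, x_sho), x_cop)
  coefs <- unname(fit$coefficients)
  if (coefs[2] < 0 || coefs[3] < 0)
    warning("negative segment weight fitted (b or c < 0): physically implausible for a two-segment stander")
  structure(
    list(a = coefs[1], b = coefs[2], c = coefs[3],
         residual_rms = sqrt(mean(fit$residuals^2)),
         n_samples = n),
    class = "calibration_coefficients")
}

#' @export
print.calibration_coefficients <- function(x, ...) {
  cat(sprintf(
    "COM calibration: x_com = %.5g + %.4f * x_hip + %.4f * x_sho  (residual RMS %.3g m, n = %d)\n",
    x$a, x$b, x$c, x$residual_rms, x$n_samples))
  invisible(x)
}

#' Centre-of-mass translation from calibrated sway-rod signals
#'
#' Applies the calibration affine map pointwise:
#' `x_com(t) = a + b * x_hip(t) + c * x_sho(t)`.
#'
#' @param x_hip,x_sho numeric series (m), equal length.
#' @param coeffs a `calibration_coefficients` object (or list with a, b, c).
#' @return numeric series, x_com in m.
#' @export
compute_com <- function(x_hip, x_sho, coeffs) {
  if (length(x_hip) != length(x_sho))
    stop("x_hip and x_sho must have equal length")
  coeffs$a + coeffs$b * x_hip + coeffs$c * x_sho
}

#' Angular centre-of-mass sway
#'
#' Converts the centre-of-mass translation into an angle about the ankle
#' joint, `theta_com(t) = asin(x_com(t) / h_com)`, in degrees.
#'
#' @param x_com numeric series (m).
#' @param h_com centre-of-mass height above the ankle axis (m, > 0). If
#'   unknown, [h_com_default()] gives a documented approximation.
#' @return numeric series, theta_com in deg.
#' @export
com_angle <- function(x_com, h_com) {
  if (!is.numeric(h_com) || length(h_com) != 1L || h_com <= 0)
    stop("`h_com` must be a single positive number (m)")
  bad <- which(abs(x_com) >= h_com)
  if (length(bad))
    stop(sprintf("|x_com| >= h_com at sample %d (x_com = %.4g m, h_com = %.4g m): asin domain exceeded",
                 bad[1], x_com[bad[1]], h_com))
  asin(x_com / h_com) * 180 / pi
}

#' Approximate centre-of-mass height from body height
#'
#' Convenience approximation when no anthropometric COM-height estimate is
#' available: `h_com = 0.55 * body_height`, measured above the ankle axis.
#' This is a coarse population-level approximation; prefer a per-subject
#' measurement or anthropometric model when available.
#'
#' @param body_height body height in m.
#' @return approximate h_com in m.
#' @export
h_com_default <- function(body_height) {
  if (!is.numeric(body_height) || any(body_height <= 0))
    stop("`body_height` must be positive (m)")
  0.55 * body_height
}
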