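#' Second-order mechanical model of the force probe
#'
#' The flexible probe that the fly pulls on behaves as a damped
#' harmonic oscillator: \eqn{F = m\,\ddot x + c\,\dot x + k\,x}, with
#' displacement \eqn{x} in micrometres, time in milliseconds and force in
#' micronewtons. In these units mass is carried in milligrams and drag in
#' mg/ms, which are mutually consistent (1 mg um/ms^2 = 1 uN).
#'
#' The decay time constant of the free ring-down is \eqn{\tau = 2m/c} and,
#' in the underdamped regime (\eqn{k/m > (c/2m)^2}), the damped angular
#' frequency is \eqn{\omega_d = \sqrt{k/m - (c/2m)^2}} giving an oscillation
#' period \eqn{2\pi/\omega_d}. Both are always recomputed from (k, m, c).
#'
#' Defaults are the calibrated constants of the probe used throughout the
#' study: k = 0.2234 uN/um, m = 0.1702 mg, c = 0.1377 mg/ms, for which
#' tau = 2.47 ms and period = 5.86 ms.
#'
#' @param k Spring constant (uN/um).
#' @param m Effective mass (mg).
#' @param c Drag coefficient (mg/ms).
#' @return An object of class `probe_model`: a list with elements `k`, `m`,
#'   `c`, `tau_ms`, `omega_d` (rad/ms, `NA` if overdamped), `period_ms`
#'   (`NA` if overdamped) and `underdamped`.
#' @examples
#' probe_model()
#' probe_model(k = 0.2234, m = 0.1702, c = 0.1377)$tau_ms
#' @export
probe_model <- function(k = 0.2234, m = 0.1702, c = 0.1377) {
  check_number(k, "k", positive = TRUE)
  check_number(m, "m", positive = TRUE)
  check_number(c, "c", positive = TRUE)
  tau <- 2 * m / c
  disc <- k / m - (c / (2 * m))^2
  underdamped <- disc > 0
  omega_d <- if (underdamped) sqrt(disc) else NA_real_
  structure(
    list(
      k = k, m = m, c = c,
      tau_ms = tau,
      omega_d = omega_d,
      period_ms = if (underdamped) 2 * pi / omega_d else NA_real_,
      underdamped = underdamped
    ),
    class = "probe_model"
  )
}

#' @export
print.probe_model <- function(x, ...) {
  cat("<probe_model>\n")
  cat(sprintf("  k = %.4f uN/um, m = %.4f mg, c = %.4f mg/ms\n", x$k, x$m, x$c))
  if (x$underdamped) {
    cat(sprintf("  underdamped: tau = %.3f ms, period = %.3f ms\n",
                x$tau_ms, x$period_ms))
  } else {
    cat(sprintf("  overdamped: tau = %.3f ms\n", x$tau_ms))
  }
  invisible(x)
}

#' Simulate the probe's displacement response to a force input
#'
#' Numerically integrates the probe equation of motion
#' \eqn{m\ddot x + c\dot x + kx = F(t)} with a fixed-step fourth-order
#' Runge-Kutta scheme (default substep 0.05 ms; the probe's ~2.5 ms
#' relaxation requires sub-millisecond resolution), returning displacement
#' on the same grid as the input force.
#'
#' @param force_uN Force input (uN) sampled on a uniform grid.
#' @param dt_ms Grid spacing of `force_uN` in ms. Must satisfy
#'   `dt_ms <= 0.1 * tau` (tau = 2m/c) so the input resolves the probe
#'   dynamics; integrate on a fine grid and decimate afterwards if you need
#'   a coarser output rate.
#' @param probe A [probe_model()].
#' @param x0,v0 Initial displacement (um) and velocity (um/ms).
#' @param h_ms Internal integration substep (ms).
#' @return A tibble with columns `time_ms`, `force_uN`, `displacement_um`.
#' @examples
#' pr <- probe_model()
#' resp <- simulate_probe_response(rep(11.17, 200), dt_ms = 0.2, probe = pr)
#' tail(resp$displacement_um, 1) # ~ 50 um at steady state
#' @export
simulate_probe_response <- function(force_uN, dt_ms, probe = probe_model(),
                                    x0 = 0, v0 = 0, h_ms = 0.05) {
  if (!inherits(probe, "probe_model")) abort("`probe` must be a probe_model.")
  if (!is.numeric(force_uN) || length(force_uN) < 2L || anyNA(force_uN)) {
    abort("`force_uN` must be a numeric vector (length >= 2, no NA).")
  }
  check_number(dt_ms, "dt_ms", positive = TRUE)
  if (dt_ms > 0.1 * probe$tau_ms) {
    abort(sprintf(
      "`dt_ms` (%.3g ms) too coarse: must be <= 0.1 * tau = %.3g ms.",
      dt_ms, 0.1 * probe$tau_ms
    ))
  }
  x <- .probe_rk4(as.numeric(force_uN), dt_ms, probe$k, probe$m, probe$c,
                  x0, v0, min(h_ms, dt_ms))
  tibble::tibble(
    time_ms = (seq_along(force_uN) - 1) * dt_ms,
    force_uN = as.numeric(force_uN),
    displacement_um = x
  )
}

# closed-form free response of the underdamped probe (used as an oracle and
# for ring-down starting values): x(t) = e^(-t/tau) (x0 cos wd t +
# ((v0 + x0/tau)/wd) sin wd t)
probe_free_response <- function(t_ms, probe, x0, v0 = 0) {
  stopifnot(probe$underdamped)
  tau <- probe$tau_ms
  wd <- probe$omega_d
  exp(-t_ms / tau) * (x0 * cos(wd * t_ms) + ((v0 + x0 / tau) / wd) * sin(wd * t_ms))
}

#' Convert probe displacement to femur-tibia joint angle change
#'
#' The probe tip sits near the end of the tibia at a known lever arm from
#' the joint, so a lateral displacement `d` corresponds to a joint rotation
#' of `asin(d / lever_arm)`. Positive displacements are flexion, negative
#' extension. With the study's 417 um lever arm, 60 um is ~8 degrees and
#' 150 um is ~21 degrees.
#'
#' @param displacement_um Displacement(s) in um (vectorised).
#' @param lever_arm_um Lever arm from joint to probe contact point (um).
#' @return Angle change(s) in degrees.
#' @examples
#' displacement_to_joint_angle(60)   # ~8.27
#' displacement_to_joint_angle(150)  # ~21.1
#' @export
displacement_to_joint_angle <- function(displacement_um, lever_arm_um = 417) {
  check_number(lever_arm_um, "lever_arm_um", positive = TRUE)
  if (any(abs(displacement_um) >= lever_arm_um)) {
    abort("|displacement| must be smaller than the lever arm.")
  }
  asin(displacement_um / lever_arm_um) * 180 / pi
}
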