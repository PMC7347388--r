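#' Tidy a spring-constant calibration
#'
#' @param x An `fm_calibration`.
#' @param ... Unused.
#' @return One row per model term with estimate and standard error.
#' @export
tidy.fm_calibration <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept_uN", "k_uN_per_um"),
    estimate = unname(sm[, 1L]),
    std_error = unname(sm[, 2L])
  )
}

#' @rdname tidy.fm_calibration
#' @export
glance.fm_calibration <- function(x, ...) {
  tibble::tibble(k = x$k, intercept = x$intercept, k_se = x$k_se,
                 sigma = x$sigma, n = x$n,
                 r_squared = summary(x$fit)$r.squared)
}

#' Tidy a ring-down dynamics fit
#'
#' @param x An `fm_flick`.
#' @param ... Unused.
#' @return One row per physical parameter.
#' @export
tidy.fm_flick <- function(x, ...) {
  tibble::tibble(
    term = c("m_mg", "c_mg_per_ms", "tau_ms", "period_ms"),
    estimate = c(x$m, x$c, x$tau_ms, x$period_ms)
  )
}

#' @rdname tidy.fm_flick
#' @export
glance.fm_flick <- function(x, ...) {
  tibble::tibble(m = x$m, c = x$c, tau_ms = x$tau_ms,
                 period_ms = x$period_ms, overdamped = x$overdamped)
}

#' Tidy a force-per-spike curve
#'
#' @param x An `fm_force_curve`.
#' @param ... Unused.
#' @return The per-spike-count curve as a tibble.
#' @export
tidy.fm_force_curve <- function(x, ...) x$curve

#' @rdname tidy.fm_force_curve
#' @export
glance.fm_force_curve <- function(x, ...) {
  tibble::tibble(slope_uN_per_spike = x$slope_uN_per_spike,
                 ratio_2_to_1 = x$ratio_2_to_1,
                 n_counts = nrow(x$curve))
}

#' Tidy a fitted leg arc
#'
#' @param x An `fm_arc`.
#' @param ... Unused.
#' @return One-row tibble of the ellipse geometry and azimuth.
#' @export
tidy.fm_arc <- function(x, ...) {
  tibble::tibble(center_x = x$center[1L], center_y = x$center[2L],
                 a = x$a, b = x$b, theta_deg = x$theta_deg,
                 azimuth_deg = x$azimuth_deg, n = x$n)
}
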