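#' Track the probe position in a video frame
#'
#' Recovers the probe's position along a user-drawn axis line: the image is
#' resampled (bilinear interpolation) on a grid aligned with the axis,
#' rows perpendicular to the axis are averaged into a single intensity
#' profile, and the position is the centre of mass of the profile samples
#' within one full width at half maximum on either side of the peak, above
#' baseline. The baseline is the profile median, which is robust to bright
#' clutter elsewhere along the axis.
#'
#' @param frame Numeric matrix of pixel intensities (rows = y, cols = x).
#' @param axis_line 2x2 numeric matrix: rows are the (x, y) endpoints of a
#'   line drawn along the probe's axis of motion, in pixel coordinates.
#' @param pixel_size_um Physical size of one pixel (um/px).
#' @param half_width Half-width (px) of the band around the axis to average.
#' @return A one-row tibble with `position_um` (distance of the intensity
#'   peak from the first axis endpoint), `position_px`, `quality` (peak
#'   prominence above baseline) and `valid`. A frame with no peak above
#'   baseline is returned with `valid = FALSE` rather than an error.
#' @export
track_probe_position <- function(frame, axis_line, pixel_size_um = 1.0,
                                 half_width = 10) {
  if (!is.matrix(frame)) abort("`frame` must be a matrix.")
  axis_line <- as.matrix(axis_line)
  if (!all(dim(axis_line) == c(2L, 2L))) {
    abort("`axis_line` must be a 2x2 matrix of (x, y) endpoints.")
  }
  p0 <- axis_line[1L, ]
  p1 <- axis_line[2L, ]
  if (any(c(p0, p1) < 1) || any(axis_line[, 1] > ncol(frame)) ||
      any(axis_line[, 2] > nrow(frame))) {
    abort("`axis_line` endpoints must lie within the image.")
  }
  len <- sqrt(sum((p1 - p0)^2))
  if (len < 2) abort("`axis_line` is degenerate.")
  u <- (p1 - p0) / len                       # along-axis unit vector
  v <- c(-u[2L], u[1L])                      # perpendicular
  s <- seq(0, len, by = 1)
  t_off <- seq(-half_width, half_width, by = 1)
  # bilinear sampling of frame at (x, y); zero outside
  sample_img <- function(x, y) {
    x0 <- floor(x); y0 <- floor(y)
    fx <- x - x0; fy <- y - y0
    get_px <- function(xx, yy) {
      ok <- xx >= 1 & xx <= ncol(frame) & yy >= 1 & yy <= nrow(frame)
      out <- numeric(length(xx))
      out[ok] <- frame[cbind(yy[ok], xx[ok])]
      out
    }
    (1 - fx) * (1 - fy) * get_px(x0, y0) +
      fx * (1 - fy) * get_px(x0 + 1L, y0) +
      (1 - fx) * fy * get_px(x0, y0 + 1L) +
      fx * fy * get_px(x0 + 1L, y0 + 1L)
  }
  profile <- vapply(s, function(si) {
    xs <- p0[1L] + si * u[1L] + t_off * v[1L]
    ys <- p0[2L] + si * u[2L] + t_off * v[2L]
    mean(sample_img(xs, ys))
  }, numeric(1))

  baseline <- median(profile)
  peak_i <- which.max(profile)
  prominence <- profile[peak_i] - baseline
  noise <- mad(profile, constant = 1.4826)
  if (prominence <= 0 || (noise > 0 && prominence < 3 * noise) ||
      (noise == 0 && prominence == 0)) {
    return(tibble::tibble(position_um = NA_real_, position_px = NA_real_,
                          quality = prominence, valid = FALSE))
  }
  half <- baseline + prominence / 2
  above <- profile >= half
  # contiguous half-max region containing the peak -> FWHM
  lo <- peak_i; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- peak_i; while (hi < length(profile) && above[hi + 1L]) hi <- hi + 1L
  fwhm <- hi - lo + 1L
  win <- max(1L, peak_i - fwhm):min(length(profile), peak_i + fwhm)
  w <- pmax(profile[win] - baseline, 0)
  pos_px <- sum(s[win] * w) / sum(w)
  tibble::tibble(
    position_um = pos_px * pixel_size_um,
    position_px = pos_px,
    quality = prominence,
    valid = TRUE
  )
}

#' Calibrate the probe's spring constant from force-position pairs
#'
#' Ordinary least-squares fit of force against position. At steady state
#' the probe is a linear spring (F = k x), so the slope is the spring
#' constant. In the study the probe tip was pressed on an analytical
#' balance at a series of positions, reading force as measured mass times
#' gravity; the calibrated probe had k = 0.2234 uN/um.
#'
#' @param data Data frame with columns `position_um` and `force_uN`
#'   (the calibration CSV layout), or `NULL` if vectors are given.
#' @param position_um,force_uN Numeric vectors, used when `data` is NULL.
#' @return An object of class `fm_calibration`: list with `k` (slope,
#'   uN/um), `intercept` (uN), `k_se`, `sigma` (residual s.d.), `n` and the
#'   underlying `lm` fit. Has [tidy()] and [glance()] methods.
#' @examples
#' x <- seq(0, 400, length.out = 20)
#' cal <- calibrate_spring_constant(
#'   data.frame(position_um = x, force_uN = 0.2234 * x)
#' )
#' cal$k
#' @export
calibrate_spring_constant <- function(data = NULL, position_um = NULL,
                                      force_uN = NULL) {
  if (!is.null(data)) {
    if (!all(c("position_um", "force_uN") %in% names(data))) {
      abort("`data` must have columns `position_um` and `force_uN`.")
    }
    position_um <- data$position_um
    force_uN <- data$force_uN
  }
  if (length(position_um) != length(force_uN)) {
    abort("position and force must have equal length.")
  }
  if (length(unique(position_um)) < 3L) {
    abort("need at least 3 distinct probe positions to calibrate.")
  }
  fit <- lm(force_uN ~ position_um)
  sm <- summary(fit)
  structure(
    list(
      k = unname(coef(fit)[2L]),
      intercept = unname(coef(fit)[1L]),
      k_se = sm$coefficients[2L, 2L],
      sigma = sm$sigma,
      n = length(position_um),
      fit = fit
    ),
    class = "fm_calibration"
  )
}

#' @export
print.fm_calibration <- function(x, ...) {
  cat(sprintf("<fm_calibration> k = %.4f +/- %.4f uN/um (n = %d, resid sd = %.3g uN)\n",
              x$k, x$k_se, x$n, x$sigma))
  invisible(x)
}

#' Fit the probe's dynamical parameters from a ring-down ("flick") trace
#'
#' After the probe is deflected and abruptly released it relaxes back to
#' rest as a free damped oscillator. Given the independently calibrated
#' spring constant, the underdamped free response
#' \eqn{x(t) = A e^{-t/\tau} \cos(\omega_d t + \phi) + b}
#' is fitted by nonlinear least squares, and the effective mass and drag
#' follow from \eqn{m = k / (\omega_d^2 + 1/\tau^2)} and \eqn{c = 2m/\tau}.
#' If the centred trace never crosses zero after release the response is
#' flagged overdamped and a biexponential is fitted instead, with
#' \eqn{m = k/(r_1 r_2)}, \eqn{c = m (r_1 + r_2)} from the two decay rates.
#'
#' @param ringdown Displacement trace (um) starting at/near release.
#' @param k Spring constant (uN/um) from [calibrate_spring_constant()].
#' @param fs Sampling rate (Hz), at least 1000 Hz (the study imaged flicks
#'   at 1.2 kHz).
#' @return An object of class `fm_flick`: list with `m` (mg), `c` (mg/ms),
#'   `tau_ms`, `period_ms`, `omega_d`, `overdamped`, `baseline`, and `fit`.
#'   Has [tidy()] and [glance()] methods.
#' @export
fit_flick_dynamics <- function(ringdown, k, fs) {
  check_number(k, "k", positive = TRUE)
  check_number(fs, "fs", positive = TRUE)
  if (fs < 1000) abort("`fs` must be >= 1000 Hz to resolve the ring-down.")
  x <- as.numeric(ringdown)
  if (length(x) < 10L || anyNA(x)) abort("`ringdown` too short or has NA.")
  dt <- 1000 / fs # ms per sample
  tt <- (seq_along(x) - 1) * dt
  b0 <- median(tail(x, max(5L, length(x) %/% 5L)))
  y <- x - b0

  # sign changes after release indicate oscillation (underdamped); small
  # fluctuations around the settled baseline are ignored
  ypk <- which.max(abs(y))
  post <- y[ypk:length(y)]
  big_post <- post[abs(post) > 0.05 * max(abs(y))]
  crossings <- sum(diff(sign(big_post)) != 0)

  if (crossings == 0) {
    # overdamped: biexponential decay y = A1 exp(-r1 t) + A2 exp(-r2 t);
    # start the two rates either side of the log-linear decay estimate
    big <- abs(y) > max(abs(y)) * 0.02
    r_est <- -unname(coef(lm(log(abs(y[big])) ~ tt[big]))[2L])
    if (!is.finite(r_est) || r_est <= 0) r_est <- 2 / (tt[length(tt)] + dt)
    fit <- minpack.lm::nlsLM(
      y ~ A1 * exp(-r1 * tt) + A2 * exp(-r2 * tt),
      start = list(A1 = y[1] * 0.7, A2 = y[1] * 0.3,
                   r1 = 3 * r_est, r2 = 0.5 * r_est),
      lower = c(-Inf, -Inf, 1e-8, 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    cf <- coef(fit)
    r1 <- max(cf[["r1"]], cf[["r2"]])
    r2 <- min(cf[["r1"]], cf[["r2"]])
    m <- k / (r1 * r2)
    cc <- m * (r1 + r2)
    return(structure(
      list(m = m, c = cc, tau_ms = 2 * m / cc, period_ms = NA_real_,
           omega_d = NA_real_, overdamped = TRUE, baseline = b0, fit = fit),
      class = "fm_flick"
    ))
  }

  # starting values: decay from the log-envelope of rectified extrema,
  # frequency from the dominant spectral component (robust to noise)
  pk <- local_maxima(abs(y), threshold = max(abs(y)) * 0.05, min_sep = 2L)
  tau0 <- if (length(pk) >= 2L) {
    sl <- unname(coef(lm(log(abs(y[pk])) ~ tt[pk]))[2L])
    if (is.finite(sl) && sl < 0) -1 / sl else tt[length(tt)] / 3
  } else tt[length(tt)] / 3
  nfft <- length(y)
  spec <- Mod(stats::fft(y))[2:max(2L, floor(nfft / 2))]
  f_axis <- seq_along(spec) / (nfft * dt)   # cycles per ms
  wd0 <- max(2 * pi * f_axis[which.max(spec)], 1e-3)
  do_fit <- function(tau_s, wd_s) {
    minpack.lm::nlsLM(
      x ~ A * exp(-tt / tau) * cos(wd * tt + phi) + b,
      start = list(A = y[1], tau = tau_s, wd = wd_s, phi = 0, b = b0),
      lower = c(-Inf, 1e-6, 1e-6, -pi, -Inf),
      upper = c(Inf, Inf, Inf, pi, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
  }
  fit <- tryCatch(do_fit(tau0, wd0),
                  error = function(e) do_fit(tt[length(tt)] / 5, wd0))
  cf <- coef(fit)
  tau <- cf[["tau"]]
  wd <- cf[["wd"]]
  m <- k / (wd^2 + 1 / tau^2)
  cc <- 2 * m / tau
  structure(
    list(m = m, c = cc, tau_ms = tau, period_ms = 2 * pi / wd, omega_d = wd,
         overdamped = FALSE, baseline = cf[["b"]], fit = fit),
    class = "fm_flick"
  )
}

#' @export
print.fm_flick <- function(x, ...) {
  cat(sprintf("<fm_flick> m = %.4f mg, c = %.4f mg/ms, tau = %.3f ms%s\n",
              x$m, x$c, x$tau_ms,
              if (x$overdamped) " (overdamped)" else
                sprintf(", period = %.3f ms", x$period_ms)))
  invisible(x)
}

#' Reconstruct the force on the probe from its tracked displacement
#'
#' In quasistatic mode force is simply `k * x`: the probe relaxes within
#' ~2.5 ms, far faster than the behavior, so drag and inertia are
#' negligible at the video frame rate. Dynamic mode adds the drag and
#' inertia terms, `c * x' + m * x''`, with derivatives taken by central
#' differences of a Savitzky-Golay smoothed copy of the trace (window 7,
#' order 2) to suppress tracking jitter; the spring term uses the raw
#' positions.
#'
#' @param positions_um Displacement trace (um), uniformly sampled.
#' @param probe A [probe_model()].
#' @param fps Frame rate (Hz). Ignored if `frame_times_s` is given.
#' @param frame_times_s Optional frame times (s); dynamic mode rejects
#'   non-uniform sampling with more than 10% jitter.
#' @param mode `"quasistatic"` (default) or `"dynamic"`.
#' @return A tibble with `time_s`, `displacement_um`, `force_uN`.
#' @examples
#' reconstruct_force(rep(50, 10), probe_model(), fps = 170)$force_uN[1] # ~11.17
#' @export
reconstruct_force <- function(positions_um, probe = probe_model(), fps = NULL,
                              frame_times_s = NULL,
                              mode = c("quasistatic", "dynamic")) {
  mode <- match.arg(mode)
  x <- as.numeric(positions_um)
  if (anyNA(x)) abort("`positions_um` must not contain NA.")
  if (is.null(frame_times_s)) {
    if (is.null(fps)) abort("supply `fps` or `frame_times_s`.")
    frame_times_s <- (seq_along(x) - 1) / fps
    dt_ms <- 1000 / fps
  } else {
    if (length(frame_times_s) != length(x)) {
      abort("`frame_times_s` must match `positions_um` in length.")
    }
    d <- diff(frame_times_s)
    if (any(d <= 0)) abort("`frame_times_s` must be strictly increasing.")
    if (mode == "dynamic" && (max(d) - min(d)) / median(d) > 0.1) {
      abort("dynamic mode requires uniform frame intervals (jitter <= 10%).")
    }
    dt_ms <- median(d) * 1000
  }
  if (mode == "quasistatic") {
    return(tibble::tibble(time_s = frame_times_s, displacement_um = x,
                          force_uN = probe$k * x))
  }
  if (length(x) < 5L) abort("dynamic mode needs at least 5 frames.")
  n_sg <- min(7L, length(x) - (1 - length(x) %% 2)) # odd, <= length
  if (n_sg < 5L) n_sg <- 5L
  xs <- signal::sgolayfilt(x, p = 2, n = n_sg)
  n <- length(x)
  # fourth-order central stencils in the interior (needed to track the
  # drag/inertia terms accurately at the video rate), second-order at edges
  v <- c(xs[2L] - xs[1L], (xs[3:n] - xs[1:(n - 2L)]) / 2,
         xs[n] - xs[n - 1L]) / dt_ms                    # um/ms
  a <- c(0, xs[3:n] - 2 * xs[2:(n - 1L)] + xs[1:(n - 2L)], 0) / dt_ms^2
  if (n >= 7L) {
    i <- 3:(n - 2L)
    v[i] <- (-xs[i + 2L] + 8 * xs[i + 1L] - 8 * xs[i - 1L] + xs[i - 2L]) /
      (12 * dt_ms)
    a[i] <- (-xs[i + 2L] + 16 * xs[i + 1L] - 30 * xs[i] + 16 * xs[i - 1L] -
               xs[i - 2L]) / (12 * dt_ms^2)
  }
  tibble::tibble(
    time_s = frame_times_s,
    displacement_um = x,
    force_uN = probe$k * x + probe$c * v + probe$m * a
  )
}
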