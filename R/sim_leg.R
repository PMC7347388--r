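#' Simulate tracked leg points for a swinging tibia
#'
#' Emulates pose-tracked video of the restrained fly: six femur points are
#' fixed; six tibia points lie along the tibia segment at the commanded
#' femur-tibia joint angle, sweeping a circular arc that is foreshortened
#' by `cos(azimuth)` along the axis perpendicular to the femur (the leg
#' waves in a plane tilted out of the camera plane, so the circular arc
#' projects to an ellipse). Gaussian pixel jitter is added to every point,
#' and with probability `outlier_rate` per frame a single tibia point is
#' displaced by a large offset (emulating a tracking failure) and logged
#' in the ground truth.
#'
#' Conventions: the femur lies along the negative x axis with the joint at
#' the origin; a joint angle of 180 degrees is a fully straight leg.
#'
#' @param joint_angle_deg Joint angle per frame (degrees).
#' @param azimuth_deg Out-of-plane tilt of the swing arc, in `[0, 90)`.
#' @param arc_radius_px Radius (px) of the circle traced by the tibia
#'   centroid.
#' @param noise_px Gaussian jitter s.d. (px).
#' @param outlier_rate Per-frame probability of one displaced point,
#'   in `[0, 1)`.
#' @param outlier_px Magnitude of the outlier displacement (px).
#' @param seed Integer seed.
#' @return A list of class `fm_tracked`: `points` (long tibble with
#'   `frame`, `role` ("femur"/"tibia"), `idx`, `x`, `y`) and `truth`
#'   (list with `joint_angle_deg`, `azimuth_deg`, `arc_radius_px`,
#'   `outliers` tibble of injected frame/point pairs).
#' @export
simulate_leg_points <- function(joint_angle_deg, azimuth_deg = 60,
                                arc_radius_px = 100, noise_px = 1,
                                outlier_rate = 0, outlier_px = 50,
                                seed = 1L) {
  if (azimuth_deg < 0 || azimuth_deg >= 90) abort("`azimuth_deg` must be in [0, 90).")
  if (outlier_rate < 0 || outlier_rate >= 1) abort("`outlier_rate` must be in [0, 1).")
  with_seed(seed, {
    nf <- length(joint_angle_deg)
    caz <- cos(azimuth_deg * pi / 180)
    # femur: six fixed points along the femur shaft (x < 0)
    femur_frac <- seq(-1.5, -0.25, length.out = 6)
    femur_x <- femur_frac * arc_radius_px
    femur_y <- rep(c(-3, 3), 3)                  # slight two-row spread
    # tibia: six points at fixed fractions of the tibia length; their mean
    # radius defines the centroid circle of radius arc_radius_px
    tib_frac <- seq(0.6, 1.4, length.out = 6)
    tib_frac <- tib_frac / mean(tib_frac)
    phi <- (180 - joint_angle_deg) * pi / 180    # tibia direction from +x

    frames <- purrr::map(seq_len(nf), function(f) {
      tx <- tib_frac * arc_radius_px * cos(phi[f])
      ty <- tib_frac * arc_radius_px * sin(phi[f]) * caz
      tibble::tibble(
        frame = f,
        role = rep(c("femur", "tibia"), each = 6L),
        idx = rep(1:6, 2L),
        x = c(femur_x, tx) + rnorm(12L, sd = noise_px),
        y = c(femur_y, ty) + rnorm(12L, sd = noise_px)
      )
    })
    pts <- dplyr::bind_rows(frames)

    out_log <- tibble::tibble(frame = integer(), idx = integer())
    if (outlier_rate > 0) {
      hit <- which(runif(nf) < outlier_rate)
      if (length(hit)) {
        which_pt <- sample(1:6, length(hit), replace = TRUE)
        ang <- runif(length(hit), 0, 2 * pi)
        for (j in seq_along(hit)) {
          sel <- pts$frame == hit[j] & pts$role == "tibia" & pts$idx == which_pt[j]
          pts$x[sel] <- pts$x[sel] + outlier_px * cos(ang[j])
          pts$y[sel] <- pts$y[sel] + outlier_px * sin(ang[j])
        }
        out_log <- tibble::tibble(frame = hit, idx = which_pt)
      }
    }
    structure(
      list(points = pts,
           truth = list(joint_angle_deg = joint_angle_deg,
                        azimuth_deg = azimuth_deg,
                        arc_radius_px = arc_radius_px,
                        outliers = out_log)),
      class = "fm_tracked"
    )
  })
}

#' @export
print.fm_tracked <- function(x, ...) {
  cat(sprintf("<fm_tracked> %d frames, azimuth %.1f deg, %d injected outliers\n",
              length(x$truth$joint_angle_deg), x$truth$azimuth_deg,
              nrow(x$truth$outliers)))
  invisible(x)
}
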