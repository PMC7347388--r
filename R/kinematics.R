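#' Clean tracked leg points
#'
#' Post-processes pose-tracked leg points. For each frame the nearest-
#' neighbour distance of every tibia point is compared against the pooled
#' distribution across frames (robust z-score using median and MAD): a
#' frame with exactly one outlying point has that point filled in by a
#' random draw consistent with the pairwise distance distributions (the
#' filled position minimises the squared deviation from distances drawn
#' for each partner point) and flagged; a frame with two or more outlying
#' points is excluded. Coordinates are then median-filtered across frames
#' (default width 5) and the tibia centroid is appended to every retained
#' frame.
#'
#' @param tracked An `fm_tracked` object or its long `points` tibble
#'   (columns `frame`, `role`, `idx`, `x`, `y`).
#' @param outlier_sd Robust z-score beyond which a nearest-neighbour
#'   distance marks its point as misidentified.
#' @param median_width Median filter width in frames (odd).
#' @param seed Seed for the distance draws used when filling points.
#' @return A list of class `fm_cleaned`: `points` (long tibble including
#'   `role = "centroid"` rows, with a logical `filled` column), `fills`
#'   (tibble `frame`, `idx`), `excluded` (tibble `frame`, `reason`).
#' @export
clean_points <- function(tracked, outlier_sd = 5, median_width = 5,
                         seed = 1L) {
  pts <- if (inherits(tracked, "fm_tracked")) tracked$points else
    tibble::as_tibble(tracked)
  if (!all(c("frame", "role", "idx", "x", "y") %in% names(pts))) {
    abort("`tracked` needs columns frame, role, idx, x, y.")
  }
  frames <- sort(unique(pts$frame))
  if (length(frames) < 100L) {
    abort("need at least 100 frames to estimate distance distributions.")
  }
  tib <- pts[pts$role == "tibia", ]
  nf <- length(frames)
  # 6 x nf coordinate matrices in (idx, frame) order
  xs <- matrix(tib$x[order(tib$frame, tib$idx)], nrow = 6L)
  ys <- matrix(tib$y[order(tib$frame, tib$idx)], nrow = 6L)

  nn_dist <- function(px, py) {
    d <- as.matrix(stats::dist(cbind(px, py)))
    diag(d) <- Inf
    apply(d, 1L, min)
  }
  nn <- vapply(seq_len(nf), function(f) nn_dist(xs[, f], ys[, f]),
               numeric(6L))
  med <- median(nn)
  scale_ <- mad(nn, constant = 1.4826)
  z <- (nn - med) / scale_
  bad <- z > outlier_sd                      # 6 x nf

  # pairwise distance pools from frames with no outliers
  clean_f <- which(colSums(bad) == 0L)
  pair_pools <- list()
  for (i in 1:5) for (j in (i + 1):6) {
    pair_pools[[paste(i, j)]] <- sqrt((xs[i, clean_f] - xs[j, clean_f])^2 +
                                        (ys[i, clean_f] - ys[j, clean_f])^2)
  }
  pool_for <- function(i, j) pair_pools[[paste(min(i, j), max(i, j))]]

  fills <- tibble::tibble(frame = integer(), idx = integer())
  excluded <- tibble::tibble(frame = integer(), reason = character())
  filled_flag <- matrix(FALSE, 6L, nf)
  with_seed(seed, {
    for (f in seq_len(nf)) {
      nbad <- sum(bad[, f])
      if (nbad == 0L) next
      if (nbad >= 2L) {
        excluded <- dplyr::bind_rows(excluded,
          tibble::tibble(frame = frames[f], reason = "multi-point"))
        next
      }
      j <- which(bad[, f])
      others <- setdiff(1:6, j)
      draws <- vapply(others, function(i) sample(pool_for(i, j), 1L),
                      numeric(1))
      obj <- function(p) {
        sum((sqrt((p[1] - xs[others, f])^2 + (p[2] - ys[others, f])^2) -
               draws)^2)
      }
      init <- c(median(xs[j, clean_f]), median(ys[j, clean_f]))
      if (f > 1L && !bad[j, f - 1L]) init <- c(xs[j, f - 1L], ys[j, f - 1L])
      sol <- optim(init, obj, method = "Nelder-Mead")
      xs[j, f] <- sol$par[1L]
      ys[j, f] <- sol$par[2L]
      filled_flag[j, f] <- TRUE
      fills <- dplyr::bind_rows(fills,
        tibble::tibble(frame = frames[f], idx = j))
    }
  })

  keep_f <- setdiff(seq_len(nf), match(excluded$frame, frames))
  # median filter across retained frames
  mw <- min(median_width, length(keep_f) - (1 - length(keep_f) %% 2))
  if (mw >= 3L) {
    for (i in 1:6) {
      xs[i, keep_f] <- as.numeric(runmed(xs[i, keep_f], mw, endrule = "keep"))
      ys[i, keep_f] <- as.numeric(runmed(ys[i, keep_f], mw, endrule = "keep"))
    }
  }

  fem <- pts[pts$role == "femur" & pts$frame %in% frames[keep_f], ]
  out_t <- purrr::map_dfr(keep_f, function(f) {
    tibble::tibble(frame = frames[f], role = "tibia", idx = 1:6,
                   x = xs[, f], y = ys[, f], filled = filled_flag[, f])
  })
  cent <- out_t |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop") |>
    dplyr::mutate(role = "centroid", idx = 1L, filled = FALSE)
  fem$filled <- FALSE
  structure(
    list(points = dplyr::bind_rows(fem, out_t, cent) |>
           dplyr::arrange(.data$frame, .data$role, .data$idx),
         fills = fills, excluded = excluded),
    class = "fm_cleaned"
  )
}

#' Fit the leg-arc ellipse to tibia centroids
#'
#' The tibia centroid sweeps a circular arc tilted out of the camera
#' plane, so its image is an ellipse whose minor/major axis ratio is the
#' cosine of the azimuthal (out-of-plane) angle. A direct least-squares
#' conic fit (eigen-decomposition of the ellipse-constrained scatter)
#' gives center, semi-axes and orientation; the azimuth follows as
#' `acos(b / a)`.
#'
#' @param centroids Data frame with columns `x`, `y` (tibia centroids per
#'   frame), or an `fm_cleaned` object (its centroid rows are used).
#' @param min_arc_deg Minimum angular span of the centroids about the
#'   fitted center (degrees).
#' @return An object of class `fm_arc`: list with `center` (x, y), `a`,
#'   `b` (semi-axes, a >= b), `theta_deg` (major-axis orientation),
#'   `azimuth_deg`, `n`.
#' @export
fit_arc <- function(centroids, min_arc_deg = 60) {
  if (inherits(centroids, "fm_cleaned")) {
    centroids <- centroids$points[centroids$points$role == "centroid", ]
  }
  x <- centroids$x
  y <- centroids$y
  if (length(x) < 20L) abort("need at least 20 centroid frames.")
  conic <- tryCatch(fit_ellipse_conic(x, y),
                    error = function(e) abort(paste(
                      "degenerate centroid geometry:", conditionMessage(e))))
  geo <- conic_to_ellipse(conic)
  if (is.null(geo)) abort("centroids do not determine an ellipse (collinear?).")
  # angular span about the center, in the unprojected frame
  ct <- cos(geo$theta); st <- sin(geo$theta)
  xr <- ct * (x - geo$cx) + st * (y - geo$cy)
  yr <- (-st * (x - geo$cx) + ct * (y - geo$cy)) * geo$a / geo$b
  ang <- sort(atan2(yr, xr))
  gaps <- diff(c(ang, ang[1L] + 2 * pi))
  span <- (2 * pi - max(gaps)) * 180 / pi
  if (span < min_arc_deg) {
    abort(sprintf("centroids span only %.1f deg of arc (< %g).",
                  span, min_arc_deg))
  }
  structure(
    list(center = c(x = geo$cx, y = geo$cy), a = geo$a, b = geo$b,
         theta_deg = geo$theta * 180 / pi,
         azimuth_deg = acos(pmin(1, geo$b / geo$a)) * 180 / pi,
         n = length(x)),
    class = "fm_arc"
  )
}

#' @export
print.fm_arc <- function(x, ...) {
  cat(sprintf(
    "<fm_arc> center (%.1f, %.1f), a = %.1f, b = %.1f px, azimuth = %.1f deg\n",
    x$center[1], x$center[2], x$a, x$b, x$azimuth_deg))
  invisible(x)
}

# Direct least-squares ellipse fit (Fitzgibbon/Halir-Flusser): returns the
# conic coefficients (A, B, C, D, E, F) with the ellipse constraint
# 4AC - B^2 = 1 imposed through a generalized eigenproblem.
fit_ellipse_conic <- function(x, y) {
  x0 <- mean(x); y0 <- mean(y)
  xs <- x - x0; ys <- y - y0
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3L, ] / 2, -M[2L, ], M[1L, ] / 2)
  ev <- eigen(M)
  vv <- Re(ev$vectors)
  cond <- 4 * vv[1L, ] * vv[3L, ] - vv[2L, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0L) stop("no ellipse solution")
  a1 <- vv[, ok[1L]]
  a2 <- as.numeric(Tm %*% a1)
  # undo the centering shift
  A <- a1[1L]; B <- a1[2L]; C <- a1[3L]
  D <- a2[1L]; E <- a2[2L]; F <- a2[3L]
  c(A = A, B = B, C = C,
    D = D - 2 * A * x0 - B * y0,
    E = E - 2 * C * y0 - B * x0,
    F = F + A * x0^2 + B * x0 * y0 + C * y0^2 - D * x0 - E * y0)
}

# conic -> geometric ellipse (center, semi-axes a >= b, orientation theta of
# the major axis); NULL if not an ellipse
conic_to_ellipse <- function(cf) {
  A <- cf[["A"]]; B <- cf[["B"]]; C <- cf[["C"]]
  D <- cf[["D"]]; E <- cf[["E"]]; F <- cf[["F"]]
  Q <- matrix(c(A, B / 2, B / 2, C), 2L)
  if (det(Q) <= 0) return(NULL)
  ctr <- -0.5 * solve(Q, c(D, E))
  Fc <- A * ctr[1L]^2 + B * ctr[1L] * ctr[2L] + C * ctr[2L]^2 +
    D * ctr[1L] + E * ctr[2L] + F
  ev <- eigen(Q, symmetric = TRUE)
  lam <- ev$values
  if (any(lam * (-Fc) <= 0)) return(NULL)
  ax <- sqrt(-Fc / lam)             # paired with ev$vectors columns
  major <- which.max(ax)
  theta <- atan2(ev$vectors[2L, major], ev$vectors[1L, major])
  list(cx = ctr[1L], cy = ctr[2L], a = max(ax), b = min(ax), theta = theta)
}

#' Recover true joint angles from cleaned points and the fitted arc
#'
#' Each tibia centroid is unprojected (the coordinate along the ellipse's
#' minor axis is divided by cos(azimuth), i.e. scaled by a/b) and the
#' femur-tibia joint angle is the angle at the arc center between the
#' unprojected femur direction and the unprojected centroid direction,
#' with 180 degrees = fully straight leg. Frames whose centroid sits far
#' off the ellipse (normalised radial residual > 3 robust s.d.) are
#' flagged. Postures are labelled extended (> 120 deg), flexed (< 30 deg)
#' or mid.
#'
#' @param cleaned An `fm_cleaned` object from [clean_points()] (same
#'   session as the arc fit).
#' @param arc An `fm_arc` from [fit_arc()].
#' @param extended_min,flexed_max Posture label thresholds (degrees).
#' @return A tibble with columns `frame`, `angle_deg`, `label`, `valid`,
#'   `residual_px`.
#' @export
joint_angles <- function(cleaned, arc, extended_min = 120, flexed_max = 30) {
  if (!inherits(cleaned, "fm_cleaned")) abort("`cleaned` must be fm_cleaned.")
  if (!inherits(arc, "fm_arc")) abort("`arc` must be an fm_arc.")
  cent <- cleaned$points[cleaned$points$role == "centroid", ]
  fem <- cleaned$points[cleaned$points$role == "femur", ]
  th <- arc$theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  stretch <- arc$a / arc$b
  unproject <- function(px, py) {
    xr <- ct * (px - arc$center[1L]) + st * (py - arc$center[2L])
    yr <- (-st * (px - arc$center[1L]) + ct * (py - arc$center[2L])) * stretch
    cbind(xr, yr)
  }
  fdir <- unproject(mean(fem$x), mean(fem$y))
  cpts <- unproject(cent$x, cent$y)
  dot <- cpts[, 1L] * fdir[1L] + cpts[, 2L] * fdir[2L]
  nrm <- sqrt(rowSums(cpts^2)) * sqrt(sum(fdir^2))
  ang <- acos(pmin(1, pmax(-1, dot / nrm))) * 180 / pi
  resid <- abs(sqrt(rowSums(cpts^2)) - arc$a)
  rsd <- mad(resid, constant = 1.4826)
  flagged <- if (rsd > 0) (resid - median(resid)) / rsd > 3 else rep(FALSE, length(resid))
  tibble::tibble(
    frame = cent$frame,
    angle_deg = ang,
    label = dplyr::case_when(
      ang > extended_min ~ "extended",
      ang < flexed_max ~ "flexed",
      TRUE ~ "mid"
    ),
    valid = !flagged,
    residual_px = resid
  )
}
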