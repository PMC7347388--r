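#' Segment a muscle movie into activity clusters
#'
#' Groups pixels whose fluorescence time series are correlated, using
#' k-means with one minus the Pearson correlation as the distance. Each
#' retained pixel's time series is standardised to zero mean and unit
#' variance, after which squared Euclidean distance is exactly
#' proportional to (1 - correlation), so standard k-means (multiple
#' restarts, best inertia kept) performs correlation-metric clustering.
#' Zero-variance pixels are excluded beforehand. Cluster labels are
#' renumbered ventral to dorsal (increasing row of the cluster centroid).
#'
#' @param movie An `fm_movie` or a numeric array (rows x cols x frames).
#' @param roi Logical matrix marking the region of interest; defaults to
#'   all pixels (or the labelled region of an `fm_movie`).
#' @param k Number of clusters (the study settled on 6 for the femur
#'   field of view; planted-cluster tests use the known number).
#' @param nstart Number of k-means restarts.
#' @param seed Integer seed for the restarts.
#' @return An object of class `fm_cluster_map`: list with `labels`
#'   (integer matrix, 0 = excluded/background), `k`, `roi`, and
#'   `pixel_counts`.
#' @export
cluster_pixels <- function(movie, roi = NULL, k = 6, nstart = 5, seed = 1L) {
  frames <- if (inherits(movie, "fm_movie")) movie$frames else movie
  if (length(dim(frames)) != 3L) abort("`movie` must be rows x cols x frames.")
  if (dim(frames)[3] < 50L) abort("need at least 50 frames to cluster.")
  if (is.null(roi)) {
    roi <- if (inherits(movie, "fm_movie")) movie$label_image > 0 else
      matrix(TRUE, dim(frames)[1], dim(frames)[2])
  }
  if (!any(roi)) abort("`roi` is empty.")
  px <- which(roi)
  nf <- dim(frames)[3]
  series <- matrix(frames, ncol = nf)[px, , drop = FALSE]
  v <- apply(series, 1L, var)
  ok <- v > 0
  labels <- matrix(0L, dim(frames)[1], dim(frames)[2])
  if (!any(ok)) {
    warn("all pixels have zero variance; returning an empty cluster map.")
    return(structure(list(labels = labels, k = 0L, roi = roi,
                          pixel_counts = integer()),
                     class = "fm_cluster_map"))
  }
  series <- series[ok, , drop = FALSE]
  px <- px[ok]
  if (k > nrow(series)) abort("`k` exceeds the number of usable pixels.")
  z <- t(scale(t(series)))  # rows: mean 0, sd 1 -> Euclidean ~ 1 - cor
  km <- with_seed(seed, kmeans(z, centers = k, nstart = nstart, iter.max = 100))
  lab <- km$cluster
  # renumber ventral -> dorsal by mean row index of each cluster
  rows <- ((px - 1L) %% dim(frames)[1]) + 1L
  ord <- order(vapply(seq_len(k), function(g) mean(rows[lab == g]), numeric(1)))
  relab <- integer(k)
  relab[ord] <- seq_len(k)
  labels[px] <- relab[lab]
  structure(
    list(labels = labels, k = as.integer(k), roi = roi,
         pixel_counts = tabulate(labels[labels > 0], nbins = k)),
    class = "fm_cluster_map"
  )
}

#' @export
print.fm_cluster_map <- function(x, ...) {
  cat(sprintf("<fm_cluster_map> %d clusters, %d labelled px (roi %d px)\n",
              x$k, sum(x$pixel_counts), sum(x$roi)))
  invisible(x)
}

#' Refine a cluster map by smoothed neighbourhood support
#'
#' Spatially regularises raw cluster assignments: each cluster's indicator
#' image is smoothed with a Gaussian kernel and only pixels whose smoothed
#' same-label support reaches the threshold (default 0.75, i.e. at least
#' three quarters of the Gaussian-weighted neighbourhood shares the label)
#' are retained. Isolated mislabelled pixels and thin interdigitated
#' regions are dropped to background; solid cluster interiors are
#' untouched.
#'
#' @param map An `fm_cluster_map`.
#' @param sigma_px Gaussian kernel s.d. in pixels.
#' @param support Minimum smoothed support to retain a pixel.
#' @return A refined `fm_cluster_map`.
#' @export
refine_cluster_map <- function(map, sigma_px = 2, support = 0.75) {
  if (!inherits(map, "fm_cluster_map")) abort("`map` must be an fm_cluster_map.")
  labels <- map$labels
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (g in seq_len(map$k)) {
    ind <- (labels == g) * 1
    if (!any(ind > 0)) next
    sm <- gaussian_smooth2d(ind, sigma_px)
    keep <- labels == g & sm >= support
    out[keep] <- g
  }
  structure(
    list(labels = out, k = map$k, roi = map$roi,
         pixel_counts = tabulate(out[out > 0], nbins = map$k)),
    class = "fm_cluster_map"
  )
}

#' Extract per-cluster fluorescence traces
#'
#' Per frame, a cluster's fluorescence is the mean over its visible member
#' pixels. Frames where an occluder covers more than `occlusion_limit`
#' (default 40%) of a cluster's pixels are marked invalid for that
#' cluster. dF/F normalises to a baseline F0 equal to the 10th percentile
#' of the cluster's valid trace (robust to activity-dominated traces).
#'
#' @param movie An `fm_movie` or numeric array (rows x cols x frames).
#' @param map An `fm_cluster_map`.
#' @param occluder Optional logical array matching the movie: TRUE where a
#'   pixel is covered.
#' @param occlusion_limit Occluded fraction above which a frame is invalid.
#' @param baseline_quantile Quantile of the trace used as F0.
#' @param fps Frame rate, used for the time axis (taken from an `fm_movie`
#'   automatically).
#' @return A tibble of class `fm_cluster_traces` with columns `frame`,
#'   `time_s`, `cluster`, `f`, `dff`, `occlusion`, `valid`.
#' @export
extract_cluster_traces <- function(movie, map, occluder = NULL,
                                   occlusion_limit = 0.40,
                                   baseline_quantile = 0.10, fps = NULL) {
  frames <- if (inherits(movie, "fm_movie")) movie$frames else movie
  fps <- fps %||% if (inherits(movie, "fm_movie")) movie$fps else
    abort("supply `fps` for a raw array.")
  if (!inherits(map, "fm_cluster_map")) abort("`map` must be an fm_cluster_map.")
  if (sum(map$pixel_counts) == 0L) abort("cluster map is empty.")
  nf <- dim(frames)[3]
  flat <- matrix(frames, ncol = nf)
  occ_flat <- if (!is.null(occluder)) matrix(occluder, ncol = nf) else NULL
  res <- purrr::map_dfr(seq_len(map$k), function(g) {
    px <- which(map$labels == g)
    if (length(px) == 0L) {
      return(tibble::tibble(frame = integer(), time_s = numeric(),
                            cluster = integer(), f = numeric(),
                            dff = numeric(), occlusion = numeric(),
                            valid = logical()))
    }
    sub <- flat[px, , drop = FALSE]
    if (!is.null(occ_flat)) {
      cov <- occ_flat[px, , drop = FALSE]
      occ_frac <- colMeans(cov)
      f <- vapply(seq_len(nf), function(j) {
        vis <- !cov[, j]
        if (any(vis)) mean(sub[vis, j]) else NA_real_
      }, numeric(1))
    } else {
      occ_frac <- rep(0, nf)
      f <- colMeans(sub)
    }
    valid <- occ_frac <= occlusion_limit & !is.na(f)
    if (!any(valid)) {
      warn(sprintf("cluster %d is occluded in every frame.", g))
      f0 <- NA_real_
    } else {
      f0 <- quantile(f[valid], baseline_quantile, names = FALSE)
    }
    tibble::tibble(
      frame = seq_len(nf), time_s = (seq_len(nf) - 1) / fps,
      cluster = g, f = f,
      dff = (f - f0) / f0,
      occlusion = occ_frac, valid = valid
    )
  })
  class(res) <- c("fm_cluster_traces", class(res))
  attr(res, "fps") <- fps
  res
}

#' Detect activation events from cluster calcium traces
#'
#' The calcium indicator decays slowly relative to leg movements, so
#' positive derivatives of cluster fluorescence indicate muscle
#' activation while negative derivatives reflect noise. Each cluster's
#' dF/F trace is Savitzky-Golay filtered (simultaneously smoothing and
#' differentiating; default polynomial order 7, frame length 9) on the
#' calcium clock and the derivative is interpolated onto the video-rate
#' grid. The noise level is estimated from the negative derivative
#' samples (mirrored around zero), and activations are contiguous runs of
#' derivative above `threshold_mult` (default 2) times that noise s.d.
#'
#' @param traces An `fm_cluster_traces` tibble.
#' @param video_times Time grid (s) to interpolate the derivative onto,
#'   e.g. the 170 Hz probe-video frame times. Defaults to the calcium grid.
#' @param sg_order,sg_length Savitzky-Golay polynomial order and frame
#'   length (odd, > order).
#' @param threshold_mult Multiplier on the noise s.d.
#' @return A tibble with columns `cluster`, `start_s`, `end_s`. The
#'   video-rate derivative is attached as attribute `"derivative"` (tibble
#'   `cluster`, `time_s`, `deriv`, `active`).
#' @export
detect_activations <- function(traces, video_times = NULL, sg_order = 7,
                               sg_length = 9, threshold_mult = 2) {
  if (!inherits(traces, "fm_cluster_traces")) {
    abort("`traces` must come from extract_cluster_traces().")
  }
  fps <- attr(traces, "fps")
  deriv_all <- list()
  out <- list()
  for (g in sort(unique(traces$cluster))) {
    tr <- traces[traces$cluster == g, ]
    vt <- video_times %||% tr$time_s
    dgrid <- rep(NA_real_, length(vt))
    runs <- true_runs(tr$valid)
    if (nrow(runs) > 0) {
      for (r in seq_len(nrow(runs))) {
        seg <- runs[r, 1L]:runs[r, 2L]
        if (length(seg) < sg_length) next
        d_cal <- sg_derivative(tr$dff[seg], p = sg_order, n = sg_length,
                               dt = 1 / fps)
        t_cal <- tr$time_s[seg]
        sel <- vt >= t_cal[1L] & vt <= t_cal[length(t_cal)]
        if (any(sel)) dgrid[sel] <- approx(t_cal, d_cal, xout = vt[sel])$y
      }
    }
    neg <- dgrid[!is.na(dgrid) & dgrid < 0]
    noise_sd <- if (length(neg) >= 2L) sd(c(neg, -neg)) else Inf
    active <- !is.na(dgrid) & dgrid > threshold_mult * noise_sd
    deriv_all[[length(deriv_all) + 1L]] <-
      tibble::tibble(cluster = g, time_s = vt, deriv = dgrid, active = active)
    runs_a <- true_runs(active)
    if (nrow(runs_a) > 0) {
      out[[length(out) + 1L]] <- tibble::tibble(
        cluster = g,
        start_s = vt[runs_a[, 1L]],
        end_s = vt[runs_a[, 2L]]
      )
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(cluster = integer(), start_s = numeric(), end_s = numeric())
  attr(res, "derivative") <- dplyr::bind_rows(deriv_all)
  res
}

#' Compare cluster activity between extended and flexed postures
#'
#' Splits frames by the femur-tibia joint angle into extended (> 120
#' degrees) and flexed (< 30 degrees) postures — intermediate frames are
#' ignored — and reports each cluster's mean dF/F and frame count in each
#' posture. Significance testing is left to standard routines (e.g.
#' `stats::aov` on the returned frames).
#'
#' @param traces An `fm_cluster_traces` tibble.
#' @param joint_angle_deg Joint angle per calcium frame (degrees), same
#'   length as one cluster's trace.
#' @param extended_min,flexed_max Posture thresholds (degrees).
#' @return A tibble with one row per cluster: `cluster`, `mean_dff_extended`,
#'   `mean_dff_flexed`, `n_extended`, `n_flexed`.
#' @export
posture_contrast <- function(traces, joint_angle_deg, extended_min = 120,
                             flexed_max = 30) {
  if (!inherits(traces, "fm_cluster_traces")) {
    abort("`traces` must come from extract_cluster_traces().")
  }
  nf <- max(traces$frame)
  if (length(joint_angle_deg) != nf) {
    abort("`joint_angle_deg` must have one angle per frame.")
  }
  ext <- which(joint_angle_deg > extended_min)
  flx <- which(joint_angle_deg < flexed_max)
  if (length(ext) == 0L) abort("no extended frames (angle > 120 deg).")
  if (length(flx) == 0L) abort("no flexed frames (angle < 30 deg).")
  traces |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      mean_dff_extended = mean(.data$dff[.data$frame %in% ext]),
      mean_dff_flexed = mean(.data$dff[.data$frame %in% flx]),
      n_extended = sum(.data$frame %in% ext),
      n_flexed = sum(.data$frame %in% flx),
      .groups = "drop"
    )
}
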