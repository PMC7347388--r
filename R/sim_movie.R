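#' Simulate a muscle calcium movie with known cluster structure
#'
#' Builds a GCaMP-like movie from a label image and per-cluster activation
#' intervals: each cluster's fluorescence is a baseline plus an amplitude
#' times the activation train convolved with a difference-of-exponentials
#' indicator kernel (default rise 50 ms, decay 300 ms — slow relative to
#' leg movements, as for GCaMP6f); pixel values are the cluster trace plus
#' i.i.d. Gaussian noise. An optional occluder (emulating the force probe
#' crossing the field of view) zeroes covered pixels, and the per-frame
#' occlusion fraction of every cluster is recorded in the ground truth.
#'
#' @param label_image Integer matrix: 0 = background, 1..K cluster labels.
#'   Labels partition the masked region (overlap is impossible by
#'   construction of a label image; non-integer images are rejected).
#' @param activations Data frame with columns `cluster`, `start_s`, `end_s`.
#' @param duration_s,fps Movie duration (s) and frame rate (Hz).
#' @param gcamp List with `rise_ms` and `decay_ms`.
#' @param baseline,amplitude Baseline fluorescence and activation amplitude
#'   (arbitrary units).
#' @param noise_sd Pixel noise s.d.
#' @param occluder Optional logical array (rows x cols x frames): TRUE
#'   where a pixel is covered on a frame.
#' @param seed Integer seed.
#' @return A list of class `fm_movie`: `frames` (numeric array rows x cols
#'   x nframes), `times_s`, `fps`, `label_image`, and `truth` (list with
#'   `activations`, `cluster_traces` tibble, and `occlusion` tibble of
#'   per-frame per-cluster occluded fractions).
#' @export
simulate_muscle_movie <- function(label_image, activations,
                                  duration_s = 10, fps = 50,
                                  gcamp = list(rise_ms = 50, decay_ms = 300),
                                  baseline = 100, amplitude = 100,
                                  noise_sd = 5, occluder = NULL,
                                  seed = 1L) {
  if (!is.matrix(label_image) || any(label_image != round(label_image))) {
    abort("`label_image` must be an integer label matrix.")
  }
  kmax <- max(label_image)
  if (kmax < 1) abort("`label_image` has no clusters.")
  if (!all(c("cluster", "start_s", "end_s") %in% names(activations))) {
    abort("`activations` needs columns cluster, start_s, end_s.")
  }
  if (any(activations$end_s > duration_s) || any(activations$start_s < 0)) {
    abort("activation intervals must lie within the movie duration.")
  }
  with_seed(seed, {
    nf <- floor(duration_s * fps) + 1L
    times <- (seq_len(nf) - 1) / fps
    dt_ms <- 1000 / fps
    kern <- doe_kernel(gcamp$rise_ms, gcamp$decay_ms, dt_ms)
    traces <- matrix(baseline, nrow = nf, ncol = kmax)
    for (k in seq_len(kmax)) {
      act <- activations[activations$cluster == k, , drop = FALSE]
      if (nrow(act) == 0L) next
      on <- rep(0, nf)
      for (r in seq_len(nrow(act))) {
        on[times >= act$start_s[r] & times <= act$end_s[r]] <- 1
      }
      traces[, k] <- baseline + amplitude * causal_conv(on, kern)
    }
    frames <- array(rnorm(length(label_image) * nf, sd = noise_sd),
                    dim = c(nrow(label_image), ncol(label_image), nf))
    members <- lapply(seq_len(kmax), function(k) which(label_image == k))
    npx <- prod(dim(label_image))
    for (f in seq_len(nf)) {
      fr <- frames[, , f]
      for (k in seq_len(kmax)) fr[members[[k]]] <- fr[members[[k]]] + traces[f, k]
      frames[, , f] <- fr
    }
    occl <- NULL
    if (!is.null(occluder)) {
      if (!all(dim(occluder) == dim(frames))) {
        abort("`occluder` must match the movie dimensions.")
      }
      frames[occluder] <- 0
      occl <- purrr::map_dfr(seq_len(nf), function(f) {
        m <- occluder[, , f]
        tibble::tibble(
          frame = f, cluster = seq_len(kmax),
          fraction = vapply(members, function(px) mean(m[px]), numeric(1))
        )
      })
    } else {
      occl <- tidyr::expand_grid(frame = seq_len(nf), cluster = seq_len(kmax))
      occl$fraction <- 0
    }
    structure(
      list(
        frames = frames, times_s = times, fps = fps,
        label_image = label_image,
        truth = list(
          activations = tibble::as_tibble(activations),
          cluster_traces = tibble::tibble(
            frame = rep(seq_len(nf), kmax),
            cluster = rep(seq_len(kmax), each = nf),
            f = as.vector(traces)
          ),
          occlusion = occl
        )
      ),
      class = "fm_movie"
    )
  })
}

#' @export
print.fm_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<fm_movie> %d x %d px, %d frames at %g Hz, %d clusters\n",
              d[1], d[2], d[3], x$fps, max(x$label_image)))
  invisible(x)
}

#' Two-band femur-like label image
#'
#' Convenience label image for planted-cluster experiments: a rows x cols
#' field split into `k` horizontal bands (ventral to dorsal), with an
#' optional margin of background around the edge.
#'
#' @param rows,cols Image size in pixels.
#' @param k Number of clusters.
#' @param margin Background margin width (px).
#' @return Integer label matrix.
#' @export
band_label_image <- function(rows = 40, cols = 60, k = 2, margin = 2) {
  lab <- matrix(0L, rows, cols)
  usable <- rows - 2 * margin
  for (i in seq_len(k)) {
    r0 <- margin + floor((i - 1) * usable / k) + 1L
    r1 <- margin + floor(i * usable / k)
    lab[r0:r1, (margin + 1L):(cols - margin)] <- i
  }
  lab
}
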