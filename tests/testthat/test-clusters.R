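planted_movie <- function(seed = 2) {
  lab <- band_label_image(30, 40, k = 2)
  acts <- rbind(
    data.frame(cluster = 1, start_s = c(1, 5), end_s = c(2, 6)),
    data.frame(cluster = 2, start_s = c(3, 7), end_s = c(4, 8))
  )
  simulate_muscle_movie(lab, acts, duration_s = 10, fps = 50, seed = seed)
}

test_that("planted two-cluster movies are recovered perfectly", {
  skip_if_not_installed("mclust")
  mv <- planted_movie()
  cm <- cluster_pixels(mv, k = 2, seed = 1)
  ari <- mclust::adjustedRandIndex(mv$label_image[mv$label_image > 0],
                                   cm$labels[mv$label_image > 0])
  expect_equal(ari, 1)
})

test_that("k = 1 labels the whole roi and degenerate movies are refused", {
  mv <- planted_movie()
  cm1 <- cluster_pixels(mv, k = 1, seed = 1)
  expect_true(all(cm1$labels[mv$label_image > 0] == 1))
  const <- array(5, dim = c(10, 10, 60))
  expect_warning(cm0 <- cluster_pixels(const, k = 2, seed = 1), "zero variance")
  expect_identical(sum(cm0$labels), 0L)
  expect_error(cluster_pixels(mv, k = 1e6, seed = 1), "exceeds")
})

test_that("map refinement drops isolated pixels but keeps solid interiors", {
  labels <- matrix(0L, 40, 40)
  labels[11:30, 11:30] <- 1L
  labels[20, 20] <- 2L       # isolated pixel of another cluster
  map <- structure(list(labels = labels, k = 2L,
                        roi = labels > 0,
                        pixel_counts = tabulate(labels[labels > 0], 2L)),
                   class = "fm_cluster_map")
  ref <- refine_cluster_map(map)
  expect_identical(ref$labels[20, 20], 0L)      # isolated pixel removed
  expect_identical(ref$labels[21, 21], 1L)      # interior survives
  # retained pixels are a subset of the raw assignment (partition conserved)
  expect_true(all(ref$labels[ref$labels > 0] ==
                    labels[ref$labels > 0]))
  expect_equal(sum(ref$pixel_counts) + sum(ref$labels == 0 & labels > 0),
               sum(labels > 0))
})

test_that("a one-pixel checkerboard has insufficient support everywhere", {
  labels <- matrix(rep_len(c(1L, 2L), 400), 20, 20)
  map <- structure(list(labels = labels, k = 2L, roi = labels > 0,
                        pixel_counts = tabulate(labels, 2L)),
                   class = "fm_cluster_map")
  ref <- refine_cluster_map(map)
  expect_true(all(ref$labels == 0L))
})

test_that("dF/F is zero for a constant movie and invariant to gain", {
  lab <- band_label_image(20, 30, k = 2)
  quiet <- simulate_muscle_movie(
    lab, data.frame(cluster = integer(), start_s = numeric(), end_s = numeric()),
    duration_s = 2, fps = 50, noise_sd = 0, seed = 1)
  map <- cluster_pixels(planted_movie(), k = 2, seed = 1)
  # constant movie: use the label image directly as the map
  cmap <- structure(list(labels = lab, k = 2L, roi = lab > 0,
                         pixel_counts = tabulate(lab[lab > 0], 2L)),
                    class = "fm_cluster_map")
  tr <- extract_cluster_traces(quiet, cmap)
  expect_true(all(abs(tr$dff) < 1e-12))
  mv <- planted_movie()
  tr1 <- extract_cluster_traces(mv, cmap)
  mv2 <- mv
  mv2$frames <- mv$frames * 2
  tr2 <- extract_cluster_traces(mv2, cmap)
  expect_equal(tr1$dff, tr2$dff, tolerance = 1e-10)
})

test_that("frames with more than 40% occlusion are excluded, others kept", {
  lab <- band_label_image(20, 30, k = 2, margin = 0)
  cl1 <- which(lab == 1)
  occ <- array(FALSE, dim = c(20, 30, 101))
  for (f in 10:20) {
    m <- matrix(FALSE, 20, 30)
    m[cl1[seq_len(ceiling(length(cl1) * 0.5))]] <- TRUE
    occ[, , f] <- m
  }
  mv <- simulate_muscle_movie(lab, data.frame(cluster = 1, start_s = 0.5,
                                              end_s = 1.0),
                              duration_s = 2, fps = 50, occluder = occ, seed = 2)
  cmap <- structure(list(labels = lab, k = 2L, roi = lab > 0,
                         pixel_counts = tabulate(lab[lab > 0], 2L)),
                    class = "fm_cluster_map")
  tr <- extract_cluster_traces(mv, cmap, occluder = occ)
  c1 <- tr[tr$cluster == 1, ]
  expect_true(all(!c1$valid[10:20]))
  expect_true(all(c1$valid[-(10:20)]))
  expect_true(all(tr$valid[tr$cluster == 2]))
})

make_traces <- function(dff, fps = 50) {
  nf <- length(dff)
  tr <- tibble::tibble(
    frame = seq_len(nf), time_s = (seq_len(nf) - 1) / fps,
    cluster = 1L, f = dff + 1, dff = dff,
    occlusion = 0, valid = TRUE
  )
  class(tr) <- c("fm_cluster_traces", class(tr))
  attr(tr, "fps") <- fps
  tr
}

test_that("a monotonically decaying trace yields zero activations", {
  tr <- make_traces(2 * exp(-(0:199) / 40))
  acts <- detect_activations(tr)
  expect_equal(nrow(acts), 0)
})

test_that("a single step rise yields one activation containing the step", {
  set.seed(7)
  dff <- 1 / (1 + exp(-((0:299) - 150) / 4)) + rnorm(300, sd = 0.01)
  acts <- detect_activations(make_traces(dff))
  expect_gte(nrow(acts), 1)
  main <- acts[which.max(acts$end_s - acts$start_s), ]
  expect_lt(main$start_s, 3.0)   # step at frame 150 = 3 s
  expect_gt(main$end_s, 3.0)
  # activation is confined to the vicinity of the rise
  expect_lt(sum(acts$end_s - acts$start_s), 1.5)
})

test_that("activation detection flags the planted rise in a noisy movie", {
  lab <- band_label_image(20, 30, k = 2)
  cmap <- structure(list(labels = lab, k = 2L, roi = lab > 0,
                         pixel_counts = tabulate(lab[lab > 0], 2L)),
                    class = "fm_cluster_map")
  mv <- simulate_muscle_movie(lab, data.frame(cluster = 1, start_s = 2,
                                              end_s = 2.5),
                              duration_s = 6, fps = 50, noise_sd = 2, seed = 4)
  tr <- extract_cluster_traces(mv, cmap)
  acts <- detect_activations(tr)
  a1 <- acts[acts$cluster == 1, ]
  expect_gte(nrow(a1), 1)
  # the detected activation covers the true rise onset
  expect_true(any(a1$start_s < 2.2 & a1$end_s > 2.0))
  # the silent cluster carries far less activation than the driven one
  dur <- function(a) sum(a$end_s - a$start_s)
  expect_lt(dur(acts[acts$cluster == 2, ]), 0.5 * dur(a1))
})

test_that("raising the activation threshold never lengthens activations", {
  mv <- planted_movie(seed = 6)
  lab <- mv$label_image
  cmap <- structure(list(labels = lab, k = 2L, roi = lab > 0,
                         pixel_counts = tabulate(lab[lab > 0], 2L)),
                    class = "fm_cluster_map")
  tr <- extract_cluster_traces(mv, cmap)
  total_dur <- function(mult) {
    a <- detect_activations(tr, threshold_mult = mult)
    if (nrow(a) == 0) 0 else sum(a$end_s - a$start_s)
  }
  durs <- vapply(c(1, 2, 3, 5), total_dur, numeric(1))
  expect_true(all(diff(durs) <= 1e-12))
})

test_that("posture contrast separates flexion-driven activity", {
  mv <- planted_movie(seed = 8)
  lab <- mv$label_image
  cmap <- structure(list(labels = lab, k = 2L, roi = lab > 0,
                         pixel_counts = tabulate(lab[lab > 0], 2L)),
                    class = "fm_cluster_map")
  tr <- extract_cluster_traces(mv, cmap)
  nf <- max(tr$frame)
  # cluster 1 is active in seconds 1-2 and 5-6: label those frames flexed
  ang <- rep(150, nf)
  t_s <- (seq_len(nf) - 1) / 50
  ang[(t_s >= 1 & t_s <= 2.8) | (t_s >= 5 & t_s <= 6.8)] <- 20
  pc <- posture_contrast(tr, ang)
  expect_gt(pc$mean_dff_flexed[pc$cluster == 1],
            pc$mean_dff_extended[pc$cluster == 1])
  expect_error(posture_contrast(tr, rep(90, nf)), "extended")
})
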