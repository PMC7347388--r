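sweep_angles <- function(n = 300) 90 + 80 * sin(seq(0, 4 * pi, length.out = n))

test_that("clean frames pass through with only the median filter applied", {
  lp <- simulate_leg_points(sweep_angles(), azimuth_deg = 55, noise_px = 0.5,
                            outlier_rate = 0, seed = 2)
  cl <- clean_points(lp)
  expect_equal(nrow(cl$fills), 0)
  expect_equal(nrow(cl$excluded), 0)
  # median-filtered input equals the output for an interior frame/point
  tib <- lp$points[lp$points$role == "tibia" & lp$points$idx == 3, ]
  med_x <- as.numeric(runmed(tib$x, 5, endrule = "keep"))
  out <- cl$points[cl$points$role == "tibia" & cl$points$idx == 3, ]
  expect_equal(out$x, med_x, tolerance = 1e-12)
})

test_that("a single displaced point is filled and the frame kept", {
  lp <- simulate_leg_points(sweep_angles(), azimuth_deg = 55, noise_px = 0.5,
                            seed = 3)
  pts <- lp$points
  sel <- pts$frame == 150 & pts$role == "tibia" & pts$idx == 4
  pts$x[sel] <- pts$x[sel] + 50
  cl <- clean_points(pts)
  expect_true(any(cl$fills$frame == 150 & cl$fills$idx == 4))
  expect_false(150 %in% cl$excluded$frame)
  filled <- cl$points[cl$points$frame == 150 & cl$points$role == "tibia" &
                        cl$points$idx == 4, ]
  true_pt <- lp$points[sel, ]
  expect_lt(abs(filled$x - true_pt$x), 15)  # back near the genuine location
})

test_that("two displaced points exclude the frame as multi-point", {
  lp <- simulate_leg_points(sweep_angles(), azimuth_deg = 55, noise_px = 0.5,
                            seed = 4)
  pts <- lp$points
  for (k in c(2, 5)) {
    sel <- pts$frame == 100 & pts$role == "tibia" & pts$idx == k
    pts$x[sel] <- pts$x[sel] + 60 * (if (k == 2) 1 else -1)
  }
  cl <- clean_points(pts)
  expect_true(100 %in% cl$excluded$frame)
  expect_equal(cl$excluded$reason[cl$excluded$frame == 100], "multi-point")
  expect_false(100 %in% cl$points$frame)
})

test_that("too few frames are refused", {
  lp <- simulate_leg_points(sweep_angles(50), seed = 1)
  expect_error(clean_points(lp), "100 frames")
})

test_that("arc fitting recovers azimuth across the physiological range", {
  for (az in c(50, 55, 60, 65)) {
    lp <- simulate_leg_points(sweep_angles(), azimuth_deg = az, noise_px = 1,
                              seed = az)
    arc <- fit_arc(clean_points(lp))
    expect_lt(abs(arc$azimuth_deg - az), 1)
  }
})

test_that("arc fit is invariant to rotation, translation and scale", {
  lp <- simulate_leg_points(sweep_angles(), azimuth_deg = 60, noise_px = 0,
                            seed = 5)
  cent <- clean_points(lp)$points
  cent <- cent[cent$role == "centroid", ]
  arc0 <- fit_arc(cent)
  th <- 25 * pi / 180
  rot <- tibble::tibble(
    x = cos(th) * cent$x - sin(th) * cent$y + 300,
    y = sin(th) * cent$x + cos(th) * cent$y - 120
  )
  arc1 <- fit_arc(rot)
  expect_equal(arc1$azimuth_deg, arc0$azimuth_deg, tolerance = 0.1)
  sc <- tibble::tibble(x = cent$x * 2.7, y = cent$y * 2.7)
  arc2 <- fit_arc(sc)
  expect_equal(arc2$azimuth_deg, arc0$azimuth_deg, tolerance = 1e-6)
  expect_equal(arc2$a, arc0$a * 2.7, tolerance = 1e-6)
})

test_that("collinear centroids raise a degenerate-geometry error", {
  line <- tibble::tibble(x = seq_len(30), y = 2 * seq_len(30) + 1)
  expect_error(fit_arc(line))
})

test_that("joint angles and posture labels are recovered exactly at zero noise", {
  gen <- c(rep(10, 40), rep(90, 40), rep(150, 40), sweep_angles(200))
  lp <- simulate_leg_points(gen, azimuth_deg = 60, noise_px = 0, seed = 6)
  cl <- clean_points(lp)
  arc <- fit_arc(cl)
  ja <- joint_angles(cl, arc)
  expect_equal(ja$angle_deg[1:40], rep(10, 40), tolerance = 0.5)
  expect_equal(ja$angle_deg[41:80], rep(90, 40), tolerance = 0.5)
  expect_equal(ja$angle_deg[81:120], rep(150, 40), tolerance = 0.5)
  expect_true(all(ja$label[ja$angle_deg > 120] == "extended"))
  expect_true(all(ja$label[ja$angle_deg < 30] == "flexed"))
  # azimuth 0: unprojection is the identity
  lp0 <- simulate_leg_points(gen, azimuth_deg = 0, noise_px = 0, seed = 6)
  cl0 <- clean_points(lp0)
  ja0 <- joint_angles(cl0, fit_arc(cl0))
  expect_equal(ja0$angle_deg[1:40], rep(10, 40), tolerance = 0.5)
})

test_that("full round trip stays within one degree RMS at 1 px noise", {
  gen <- sweep_angles(600)
  lp <- simulate_leg_points(gen, azimuth_deg = 58, noise_px = 1, seed = 7)
  cl <- clean_points(lp)
  arc <- fit_arc(cl)
  ja <- joint_angles(cl, arc)
  kept <- ja$frame
  rms <- sqrt(mean((ja$angle_deg - gen[kept])^2))
  expect_lt(rms, 1)
})
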