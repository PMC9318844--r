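# Segmentation, circle fitting and the radius time series.

test_that("Otsu segmentation separates a disk from its background exactly", {
  mask_true <- disk_mask(c(60, 60), c(30, 30), 12)
  heat <- ifelse(mask_true, 0.9, 0.1)
  thr <- otsu_threshold(heat)
  expect_gt(thr, 0.1); expect_lt(thr, 0.9)
  seg <- segment_heatmap(heat)
  expect_identical(seg, mask_true)
  expect_true(is.logical(seg))
  expect_equal(dim(seg), dim(heat))

  # brute-force check of the between-class-variance maximizer
  v <- as.vector(heat)
  edges <- seq(0, 1, length.out = 257)
  best <- -Inf; bt <- NA
  for (t in edges[2:256]) {
    w0 <- mean(v < t); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    sb <- w0 * w1 * (mean(v[v >= t]) - mean(v[v < t]))^2
    if (sb > best) { best <- sb; bt <- t }
  }
  expect_equal(thr, bt, tolerance = 1 / 256)
})

test_that("constant heatmaps segment to an empty mask", {
  expect_true(is.na(otsu_threshold(matrix(0.4, 5, 5))))
  expect_equal(sum(segment_heatmap(matrix(0.4, 5, 5))), 0)
  expect_error(segment_heatmap(matrix(2, 3, 3)), "0, 1")
})

test_that("circle fitting recovers rasterized disks within half a pixel", {
  mask <- disk_mask(c(90, 100), c(40, 50), 15)
  circ <- fit_circle(mask)
  expect_lt(abs(circ$center[1] - 40), 0.5)
  expect_lt(abs(circ$center[2] - 50), 0.5)
  expect_lt(abs(circ$radius - 15), 0.5)
  expect_gt(circ$circularity, 0.85)
  expect_lte(circ$circularity, 1.1)
  expect_gte(circ$n_boundary_points, 20)

  # exact circle points -> essentially zero fit rms
  th <- seq(0, 2 * pi, length.out = 200)[-1]
  pts <- cbind(40 + 20 * cos(th), 50 + 20 * sin(th))
  A <- cbind(pts[, 2], pts[, 1], 1)
  coef <- qr.solve(A, -(pts[, 2]^2 + pts[, 1]^2))
  r <- sqrt(sum(coef[1:2]^2) / 4 - coef[3])
  expect_equal(r, 20, tolerance = 1e-6)
})

test_that("noisy circular boundaries fit within 5% of the true radius", {
  set.seed(81)
  # build a mask whose boundary has ~1 px radial noise around radius 20
  th <- atan2(rep(seq(-45, 45), 91), rep(seq(-45, 45), each = 91))
  rr <- sqrt(outer(seq(-45, 45)^2, rep(1, 91)) +
             outer(rep(1, 91), seq(-45, 45)^2))
  noise <- rnorm(36, sd = 1)
  bins <- pmin(floor((th + pi) / (2 * pi) * 36) + 1, 36)
  redge <- 20 + noise[bins]
  mask <- matrix(rr <= redge, 91, 91)
  circ <- fit_circle(mask)
  expect_lt(abs(circ$radius - 20) / 20, 0.05)
  expect_lt(sqrt(sum((circ$center - c(46, 46))^2)), 1.5)
})

test_that("elongated components are rejected as not quasi-circular", {
  mask <- matrix(FALSE, 40, 80)
  mask[18:22, 5:75] <- TRUE  # 5 x 71 bar
  expect_error(fit_circle(mask), "quasi-circular")
  expect_error(fit_circle(matrix(FALSE, 5, 5)), "empty mask")
  # the largest component wins
  mask2 <- disk_mask(c(80, 80), c(30, 30), 14)
  mask2[70:72, 70:72] <- TRUE
  circ <- fit_circle(mask2)
  expect_lt(abs(circ$radius - 14), 0.6)
})

test_that("tiny components fall back to centroid and equivalent radius", {
  mask <- matrix(FALSE, 30, 30)
  mask[14:16, 14:16] <- TRUE
  circ <- fit_circle(mask, min_circularity = 0.3, min_boundary = 20)
  expect_equal(circ$center, c(15, 15), tolerance = 1e-8)
  expect_equal(circ$radius, sqrt(9 / pi), tolerance = 1e-8)
})

test_that("segmentation plus fitting is translation-equivariant", {
  base <- matrix(0.05, 120, 120)
  rr <- disk_mask(c(120, 120), c(40, 45), 16)
  heat1 <- base; heat1[rr] <- 0.95
  c1 <- fit_circle(segment_heatmap(heat1))
  shift <- c(25, 18)
  heat2 <- base
  rr2 <- disk_mask(c(120, 120), c(40, 45) + shift, 16)
  heat2[rr2] <- 0.95
  c2 <- fit_circle(segment_heatmap(heat2))
  expect_equal(c2$center, c1$center + shift, tolerance = 1e-8)
  expect_equal(c2$radius, c1$radius, tolerance = 1e-8)
})

test_that("radius series orders by date and reports the mean radius", {
  mk <- function(r) structure(list(center = c(1, 1), radius = r, fit_rms = 0,
                                   circularity = 1, n_boundary_points = 30),
                              class = "stress_circle")
  one <- radius_series("2019-06-01", list(mk(12)))
  expect_equal(one$mean_radius, 12)
  rs <- radius_series(c("2019-06-01", "2019-06-10", "2019-06-20"),
                      lapply(c(10, 20, 30), mk))
  expect_equal(rs$mean_radius, 20)
  expect_equal(rs$series$radius_px, c(10, 20, 30))
  expect_error(radius_series(c("2019-06-10", "2019-06-01"),
                             lapply(c(1, 2), mk)), "increasing")
  expect_error(radius_series(rep("2019-06-01", 2), lapply(c(1, 2), mk)),
               "duplicate")
})

test_that("end-to-end detection recovers a growing radius sequence", {
  model <- localizer_model()
  radii <- c(14, 20, 26, 32)
  est <- numeric(0); circles <- list()
  for (k in seq_along(radii)) {
    tr <- scene_truth(c(48, 48), radii[k] / sqrt(2 * log(2)),
                      peak_concentration = 0.6, coupling_slope = 10,
                      background_mean = 27.53, background_sd = 0.67,
                      sensor_sd = 0.1, species = "grass")
    sc <- render_scene(c(96, 96), tr, seed = 700 + k)
    det <- detect_leak(model, sc$image)
    expect_equal(det$predicted, 1L)
    expect_false(is.null(det$circle))
    circles[[k]] <- det$circle
    est[k] <- det$circle$radius
  }
  # recovered radii increase with the truth radii
  expect_true(all(diff(est) > -1))
  rs <- radius_series(as.Date("2019-06-01") + seq(0, 30, 10), circles)
  expect_equal(rs$mean_radius, mean(est))

  # control scene: classified control, no circle emitted
  trc <- scene_truth(c(48, 48), 1, background_mean = 27.53,
                     background_sd = 0.67, sensor_sd = 0.1,
                     species = "grass", condition = "control")
  scc <- render_scene(c(96, 96), trc, seed = 710)
  detc <- detect_leak(model, scc$image)
  expect_equal(detc$predicted, 2L)
  expect_null(detc$circle)
})
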