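# Cross-sections, profile statistics, stress contrasts, regression and IDW
# contouring.

test_that("diagonal cross-sections rasterize one pixel per step", {
  const <- matrix(25, 8, 8)
  expect_true(all(cross_section(const, "NW-SE") == 25))
  expect_length(cross_section(const, "NE-SW"), 8)

  # value = row index: the NW-SE diagonal visits each row once
  n <- 12
  img <- matrix(rep(0:(n - 1), n), n, n)
  expect_equal(cross_section(img, "NW-SE"), 0:(n - 1))

  # NE-SW on a left-right mirrored image equals NW-SE on the original
  set.seed(101)
  x <- matrix(runif(15 * 23), 15, 23)
  expect_equal(cross_section(x[, ncol(x):1], "NE-SW"),
               cross_section(x, "NW-SE"))
  expect_error(cross_section(matrix(1, 1, 5)), "at least 2 x 2")
})

test_that("profile statistics use the sample (n-1) standard deviation", {
  st <- profile_stats(c(1, 2, 3))
  expect_equal(st$mean, 2); expect_equal(st$sd, 1)
  expect_equal(st$min, 1); expect_equal(st$max, 3)
  expect_error(profile_stats(numeric(0)), "empty")
  expect_error(profile_stats(5), "single-sample")

  set.seed(102)
  z <- rnorm(1000, 27.53, 0.67)
  st2 <- profile_stats(z)
  expect_equal(st2$mean, 27.53, tolerance = 0.1)
  expect_equal(st2$sd, 0.67, tolerance = 0.1)
})

test_that("stress contrasts reproduce the published table arithmetic", {
  ref <- reference_canopy_stats()
  ct <- stress_contrasts(ref)
  corn <- ct$contrasts$mean_diff[ct$contrasts$species == "corn"]
  expect_equal(corn, 30.56 - 27.46)
  expect_equal(ct$min_diff, 3.10)
  expect_equal(ct$max_diff, 31.07 - 27.53)  # grass, 3.54
  # every experimental span exceeds 10 degC; grass is the smallest
  expect_true(all(ct$contrasts$span > 10))
  expect_equal(ct$min_span, 37.13 - 26.00)

  same <- ref
  same[same$condition == "experimental", c("mean", "sd", "min", "max")] <-
    same[same$condition == "control", c("mean", "sd", "min", "max")]
  expect_true(all(stress_contrasts(same)$contrasts$mean_diff == 0))
  expect_error(stress_contrasts(ref[ref$condition == "control", ]),
               "both conditions")
})

test_that("concentration regression matches hand least squares", {
  out <- correlate_concentration(c(0, 1, 2), c(0, 2, 4))
  expect_equal(out$slope, 2); expect_equal(out$pearson_r, 1)
  expect_equal(out$rmse, 0)

  flat <- correlate_concentration(c(0, 1, 2), c(0, 1, 0))
  expect_equal(flat$slope, 0)
  expect_equal(flat$pearson_r, 0)

  set.seed(103)
  xc <- runif(236, 0, 0.6)
  y <- 3.5 * xc + rnorm(236, sd = 0.5)
  fit <- correlate_concentration(xc, y)
  expect_gt(fit$slope, 3.3); expect_lt(fit$slope, 3.7)
  expect_gt(fit$pearson_r, 0.7)
  expect_error(correlate_concentration(rep(0.2, 5), rnorm(5)), "constant")
  expect_error(correlate_concentration(1:2, 1:2), "3 points")
})

test_that("regression recovers the simulator's coupling slope", {
  tr <- scene_truth(c(48, 48), sigma = 14, peak_concentration = 0.6,
                    coupling_slope = 10, background_mean = 27.53,
                    background_sd = 0.67, sensor_sd = 0.1)
  # white background noise so the OLS standard error is exact
  sc <- render_scene(c(96, 96), tr, seed = 104, smooth_px = 0)
  pts <- sample_correlation_points(sc$image, sc$concentration, n = 236,
                                   seed = 105)
  fit <- correlate_concentration(pts$concentration, pts$temperature)
  expect_gt(fit$pearson_r, 0)
  expect_lt(abs(fit$slope - 10), 3 * fit$slope_se)
})

test_that("IDW contouring is exact at samples and bounded by their range", {
  samples <- data.frame(x = c(2, 8, 5), y = c(2, 3, 9),
                        concentration = c(0.2, 0.4, 0.6))
  grid <- contour_field(samples, c(10, 10))
  expect_equal(grid[2, 2], 0.2)
  expect_equal(grid[3, 8], 0.4)
  expect_equal(grid[9, 5], 0.6)
  expect_true(all(grid >= 0.2 & grid <= 0.6))

  # two equidistant samples average at the midpoint
  s2 <- data.frame(x = c(3, 7, 5), y = c(5, 5, 1),
                   concentration = c(0.2, 0.4, 0.3))
  g2 <- contour_field(s2, c(9, 9))
  # midpoint of the first two samples: distances equal, third far -> near 0.3
  expect_equal(g2[5, 5],
               sum(c(0.2, 0.4, 0.3) / c(4, 4, 16)) / sum(1 / c(4, 4, 16)))

  expect_error(contour_field(samples[1:2, ], c(5, 5)), "3 sample")
  coll <- data.frame(x = 1:5, y = 1:5, concentration = runif(5))
  expect_error(contour_field(coll, c(6, 6)), "collinear")
})

test_that("stressed profiles are center-high and controls are flat", {
  ds <- small_dataset()
  for (i in seq_along(ds$images)) {
    for (sec in c("NE-SW", "NW-SE")) {
      prof <- cross_section(ds$images[[i]], sec,
                            center = if (ds$labels[i] == "experimental")
                              ds$truths[[i]]$leak_center)
      n <- length(prof)
      mid <- prof[round(n * 0.4):round(n * 0.6)]
      flank <- prof[c(1:round(n * 0.15), round(n * 0.85):n)]
      if (ds$labels[i] == "experimental") {
        expect_gt(mean(mid), mean(flank))
      }
    }
  }
  tab <- dataset_profile_table(ds)
  expect_equal(nrow(tab), 8)
  agg <- stress_contrasts(tab)
  expect_true(all(agg$contrasts$mean_diff > 0))
  # control sections fluctuate less than stressed ones
  for (sp in unique(tab$species)) {
    expect_lt(tab$sd[tab$species == sp & tab$condition == "control"],
              tab$sd[tab$species == sp & tab$condition == "experimental"])
  }
})
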