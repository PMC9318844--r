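# Synthetic scene simulator: concentration kernel, thermal rendering against
# its analytic expectations, and dataset bookkeeping.

test_that("concentration field is the Gaussian plume with exact anchors", {
  tr <- scene_truth(c(40, 50), sigma = 20, peak_concentration = 0.6)
  C <- simulate_concentration(c(96, 96), tr)
  expect_equal(C[40, 50], 0.6)
  expect_true(all(C >= 0 & C <= 1))

  # radial monotonicity: closer pixel never has lower concentration
  set.seed(5)
  for (i in 1:200) {
    p1 <- c(sample(96, 1), sample(96, 1)); p2 <- c(sample(96, 1), sample(96, 1))
    r1 <- sum((p1 - c(40, 50))^2); r2 <- sum((p2 - c(40, 50))^2)
    if (r1 <= r2) expect_gte(C[p1[1], p1[2]], C[p2[1], p2[2]])
  }

  # the 30% contour: solve 0.6 exp(-r^2/2s^2) = 0.3 -> r = s sqrt(2 ln 2)
  r30 <- 20 * sqrt(2 * log(2))
  expect_equal(stress_radius(tr), r30)
  expect_equal(r30, 23.548, tolerance = 1e-3)
  # field crosses 0.30 at that radius along a row through the center
  row <- C[40, ]
  expect_gt(row[50 + floor(r30)], 0.3)
  expect_lt(row[50 + ceiling(r30) + 1], 0.3)

  expect_equal(stress_radius(scene_truth(c(5, 5), 10,
                                         peak_concentration = 0.25)), 0)
  expect_error(scene_truth(c(5, 5), 10, peak_concentration = 1.5), "0, 1")
  expect_error(simulate_concentration(c(10, 10), scene_truth(c(50, 5), 3)),
               "outside")
})

test_that("rendered control scenes reproduce the configured field statistics", {
  # grass control parameterization at the imager's native array size
  tr <- scene_truth(c(120, 160), sigma = 1, background_mean = 27.53,
                    background_sd = 0.67, sensor_sd = 0.05,
                    species = "grass", condition = "control")
  sc <- render_scene(c(240, 320), tr, seed = 42)
  expect_equal(mean(sc$image$values), 27.53, tolerance = 0.2)
  expect_equal(sd(as.vector(sc$image$values)), 0.67, tolerance = 0.1)
  expect_true(all(sc$concentration == 0))

  # deterministic for a fixed seed
  sc2 <- render_scene(c(240, 320), tr, seed = 42)
  expect_identical(sc$image$values, sc2$image$values)
})

test_that("stressed minus control mean matches slope x mean concentration", {
  tr <- scene_truth(c(48, 48), sigma = 15, peak_concentration = 0.6,
                    coupling_slope = 10, background_mean = 27.53,
                    background_sd = 0.67, sensor_sd = 0.1)
  trc <- tr; trc$condition <- "control"
  diffs <- vapply(1:6, function(k) {
    s <- render_scene(c(96, 96), tr, seed = 100 + k)
    c0 <- render_scene(c(96, 96), trc, seed = 200 + k)
    mean(s$image$values) - mean(c0$image$values)
  }, numeric(1))
  expected <- 10 * mean(simulate_concentration(c(96, 96), tr))
  # background mean is imposed exactly, so only sensor noise perturbs this
  expect_equal(mean(diffs), expected, tolerance = 0.05)

  # slope-zero degeneracy: stressed and control drawn from one distribution
  tr0 <- tr; tr0$coupling_slope <- 0
  s0 <- render_scene(c(96, 96), tr0, seed = 301)
  c0 <- render_scene(c(96, 96), trc, seed = 302)
  # background mean is imposed; residual difference is sensor noise only
  expect_lt(abs(mean(s0$image$values) - mean(c0$image$values)), 0.05)
})

test_that("stressed scenes are hot inside the truth stress region", {
  ds <- small_dataset()
  stressed <- which(ds$labels == "experimental")
  for (i in stressed) {
    conc <- simulate_concentration(dim(ds$images[[i]]$values), ds$truths[[i]])
    region <- stress_region(conc)
    vals <- ds$images[[i]]$values
    expect_gt(mean(vals[region]), mean(vals[!region]))
  }
})

test_that("concentration-temperature coupling is positive on stressed scenes", {
  ds <- small_dataset()
  i <- which(ds$labels == "experimental")[1]
  conc <- simulate_concentration(dim(ds$images[[i]]$values), ds$truths[[i]])
  region <- stress_region(conc)
  r <- cor(conc[region], ds$images[[i]]$values[region])
  expect_gt(r, 0)
})

test_that("dataset generation is balanced, deterministic, and serializable", {
  expect_equal(length(generate_dataset(0, species = "grass")$images), 0)
  expect_error(generate_dataset(2, species = character(0)), "non-empty")

  ds <- generate_dataset(4, shape = c(48, 48), seed = 77)
  expect_equal(length(ds$images), 32)
  expect_equal(sum(ds$labels == "experimental"), 16)
  expect_equal(unname(table(ds$species)), rep(8L, 4), ignore_attr = TRUE)

  ds2 <- generate_dataset(4, shape = c(48, 48), seed = 77)
  expect_identical(lapply(ds$images, `[[`, "values"),
                   lapply(ds2$images, `[[`, "values"))

  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(length(back$images), 32)
  expect_equal(as.character(back$labels), as.character(ds$labels))
  expect_equal(back$images[[5]]$values, ds$images[[5]]$values,
               tolerance = 1e-4)
  expect_equal(back$truths[[1]]$sigma, ds$truths[[1]]$sigma)
})

test_that("per-species control scenes track their configured means", {
  ds <- small_dataset()
  ref <- reference_canopy_stats()
  for (sp in unique(ds$species)) {
    ctrl <- which(ds$species == sp & ds$labels == "control")
    m <- mean(vapply(ctrl, function(i) mean(ds$images[[i]]$values), numeric(1)))
    want <- ref$mean[ref$species == sp & ref$condition == "control"]
    expect_equal(m, want, tolerance = 0.2)
  }
})
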