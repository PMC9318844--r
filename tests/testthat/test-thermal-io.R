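# Reading/writing temperature matrices, marker-artifact cleaning, and the
# model-input encodings.

test_that("csv matrices parse, round-trip, and reject malformed input", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("20.0,21.0", "22.0,23.0"), p)
  img <- read_thermal(p, species = "grass", condition = "control")
  expect_equal(img$values, matrix(c(20, 22, 21, 23), 2, 2))
  expect_equal(dim(img), c(2L, 2L))

  # round trip at written precision
  set.seed(11)
  img2 <- thermal_image(matrix(runif(30, 20, 35), 5, 6))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_thermal(img2, p2, digits = 4)
  back <- read_thermal(p2)
  expect_equal(back$values, img2$values, tolerance = 1e-4)

  writeLines(c("1,2,3", "4,5"), p)
  expect_error(read_thermal(p), "row 2")
  writeLines(c("1,2", "x,4"), p)
  expect_error(read_thermal(p), "non-numeric")
  expect_error(read_thermal(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("tiff16 decoding applies the linear scale/offset", {
  skip_if_not_installed("tiff")
  p <- withr::local_tempfile(fileext = ".tif")
  raw <- matrix(c(4500L, 0L, 100L, 60000L), 2, 2)
  tiff::writeTIFF(raw / 65535, p, bits.per.sample = 16)
  img <- read_thermal(p, "tiff16", scale = 0.01, offset = -20)
  expect_equal(img$values[1, 1], 25.00)  # 4500 * 0.01 - 20
  expect_equal(img$values[2, 1], -20)

  # write + sidecar round trip
  img2 <- thermal_image(matrix(seq(20, 30, length.out = 12), 3, 4))
  p2 <- withr::local_tempfile(fileext = ".tif")
  write_thermal(img2, p2, "tiff16")
  expect_true(file.exists(paste0(p2, ".json")))
  back <- read_thermal(p2, "tiff16")
  expect_equal(back$values, img2$values, tolerance = 0.02)
})

test_that("temperatures outside the imager range are rejected with location", {
  expect_error(thermal_image(matrix(c(25, 700, 25, 25), 2, 2)),
               "row 2, col 1")
  expect_error(thermal_image(matrix(c(25, NA, 25, 25), 2, 2)), "row 2")
  expect_silent(thermal_image(matrix(c(-20, 600), 1, 2)))
})

test_that("singular-value removal matches the brute-force local-median rule", {
  # constant image untouched
  img <- thermal_image(matrix(25, 5, 5))
  expect_equal(remove_singular_values(img)$values, img$values)

  # single hot marker pixel replaced by the local median
  x <- matrix(25, 5, 5); x[3, 3] <- 80
  cleaned <- remove_singular_values(thermal_image(x), window = 5, k = 5)
  expect_equal(cleaned$values, brute_despike(x, 5, 5))
  expect_equal(cleaned$values[3, 3], 25)
  expect_equal(sum(cleaned$values != x), 1)

  # smooth field within [24, 26]: max robust z below k, nothing changes
  set.seed(3)
  y <- matrix(runif(100, 24, 26), 10, 10)
  expect_equal(remove_singular_values(thermal_image(y), 5, 5)$values,
               brute_despike(y, 5, 5))
  expect_equal(remove_singular_values(thermal_image(y), 5, 5)$values, y)

  expect_error(remove_singular_values(thermal_image(matrix(25, 3, 3)),
                                      window = 5), "window")
})

test_that("despiking is idempotent and changes only robust-z violations", {
  set.seed(9)
  x <- matrix(rnorm(400, 27, 0.5), 20, 20)
  spikes <- cbind(c(3, 10, 17), c(5, 12, 2))
  x[spikes] <- x[spikes] + 30
  once <- remove_singular_values(thermal_image(x), 5, 5)
  twice <- remove_singular_values(once, 5, 5)
  expect_equal(once$values, twice$values)
  # exactly the brute-force rule: changed pixels == robust-z violations
  oracle <- brute_despike(x, 5, 5)
  expect_equal(once$values, oracle)
  expect_equal(sum(once$values != x), sum(oracle != x))
  # all injected spikes are among the changed pixels
  expect_true(all(once$values[spikes] != x[spikes]))
})

test_that("model-input encodings map to [0,1] with the documented anchors", {
  img <- thermal_image(matrix(25, 4, 4))
  enc <- to_model_input(img, "minmax_gray")
  expect_equal(dim(enc), c(4, 4, 3))
  expect_true(all(enc == 0.5))

  img2 <- thermal_image(matrix(c(20, 30), 2, 2))
  enc2 <- to_model_input(img2, "minmax_gray")
  expect_equal(sort(unique(as.vector(enc2))), c(0, 1))

  enc3 <- to_model_input(thermal_image(matrix(25, 2, 2)), "fixed_range",
                         range = c(20, 30))
  expect_true(all(enc3 == 0.5))
  expect_error(to_model_input(img, "fixed_range", range = c(30, 20)), "lo < hi")

  # all encodings bounded for arbitrary images
  set.seed(4)
  img4 <- thermal_image(matrix(runif(64, -5, 50), 8, 8))
  for (mode in c("minmax_gray", "fixed_range", "anomaly")) {
    e <- to_model_input(img4, mode)
    expect_true(all(e >= 0 & e <= 1), info = mode)
    expect_equal(e[, , 1], e[, , 3])
  }
})
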