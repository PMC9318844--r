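# Seeded synthetic thermal scenes with known ground truth.
#
# A scene is a background canopy temperature field (spatially correlated
# texture around a species-specific mean) plus, for stressed plots, a
# quasi-circular methane plume that couples linearly into temperature, plus
# white sensor noise. Ground truth (leak center, plume spread, peak
# concentration, coupling slope) is kept alongside every scene so detection
# and localization can be scored exactly.

# Per-species control-plot canopy statistics used as simulator defaults
# (mean and sd of canopy temperature, degC).
SPECIES_BACKGROUND <- list(
  grass   = c(mean = 27.53, sd = 0.67),
  soybean = c(mean = 32.02, sd = 0.96),
  corn    = c(mean = 27.46, sd = 0.52),
  wheat   = c(mean = 27.58, sd = 1.48)
)

# Soil-gas volume fraction above which vegetation shows stress symptoms.
STRESS_CONCENTRATION <- 0.30

#' Ground truth for a simulated leak scene
#'
#' @param leak_center `(row, col)` of the leak in px.
#' @param sigma plume spread of the Gaussian concentration kernel, px.
#' @param peak_concentration methane volume fraction at the leak center,
#'   in `(0, 1]`.
#' @param coupling_slope canopy warming per unit volume fraction,
#'   degC (must be > 0 for stressed scenes: concentration and temperature
#'   are positively coupled).
#' @param background_mean,background_sd canopy background statistics, degC.
#' @param sensor_sd white sensor noise sd, degC (imager sensitivity floor
#'   0.05 degC).
#' @param species,condition plot metadata.
#' @param axis_ratio optional plume ellipticity (>= 1, quasi-circular up to
#'   1.3); 1 gives an isotropic plume.
#' @param axis_angle plume major-axis angle, degrees.
#' @return an object of class `scene_truth`.
#' @export
scene_truth <- function(leak_center, sigma, peak_concentration = 0.6,
                        coupling_slope = 10, background_mean = 27.53,
                        background_sd = 0.67, sensor_sd = 0.05,
                        species = "grass", condition = "experimental",
                        axis_ratio = 1, axis_angle = 0) {
  stopifnot(sigma > 0, sensor_sd >= 0.05, background_sd >= 0)
  if (peak_concentration <= 0 || peak_concentration > 1)
    stop("peak_concentration must lie in (0, 1]")
  if (coupling_slope < 0)
    stop("coupling_slope must be non-negative (gas warms the canopy)")
  if (axis_ratio < 1 || axis_ratio > 1.3)
    stop("axis_ratio must lie in [1, 1.3] (quasi-circular plumes)")
  structure(list(leak_center = as.numeric(leak_center), sigma = sigma,
                 peak_concentration = peak_concentration,
                 coupling_slope = coupling_slope,
                 background_mean = background_mean,
                 background_sd = background_sd, sensor_sd = sensor_sd,
                 species = species, condition = condition,
                 axis_ratio = axis_ratio, axis_angle = axis_angle),
            class = "scene_truth")
}

#' Stress radius implied by a scene truth
#'
#' The stressed area is where concentration exceeds 30 percent; for the
#' Gaussian plume this is the circle of radius
#' `sigma * sqrt(2 * log(peak / 0.30))` (0 when the peak never reaches 30
#' percent).
#'
#' @param truth a [scene_truth()].
#' @return radius in px.
#' @export
stress_radius <- function(truth) {
  if (truth$peak_concentration <= STRESS_CONCENTRATION) return(0)
  truth$sigma * sqrt(2 * log(truth$peak_concentration / STRESS_CONCENTRATION))
}

#' Simulate a methane concentration field
#'
#' Gas diffusing from a point leak yields a quasi-circular concentration
#' footprint; the simulator uses a (optionally slightly elliptic) Gaussian
#' kernel `C(r) = peak * exp(-r^2 / (2 sigma^2))`.
#'
#' @param shape `(n_rows, n_cols)`.
#' @param truth a [scene_truth()]; its center must lie inside the grid.
#' @return a matrix of volume fractions in `[0, 1]` with class
#'   `concentration_field`.
#' @export
simulate_concentration <- function(shape, truth) {
  H <- shape[1]; W <- shape[2]
  ctr <- truth$leak_center
  if (ctr[1] < 1 || ctr[1] > H || ctr[2] < 1 || ctr[2] > W)
    stop("leak_center outside the grid")
  dr <- matrix(rep(seq_len(H) - ctr[1], W), H, W)
  dc <- matrix(rep(seq_len(W) - ctr[2], each = H), H, W)
  if (truth$axis_ratio > 1) {
    th <- truth$axis_angle * pi / 180
    u <- dr * cos(th) + dc * sin(th)
    v <- -dr * sin(th) + dc * cos(th)
    r2 <- (u / truth$axis_ratio)^2 + v^2
  } else {
    r2 <- dr^2 + dc^2
  }
  C <- truth$peak_concentration * exp(-r2 / (2 * truth$sigma^2))
  structure(C, class = c("concentration_field", "matrix", "array"))
}

# Spatially correlated zero-mean unit-sd noise field: white noise smoothed by
# a Gaussian kernel (circular convolution via FFT), then standardized so the
# per-scene sample mean is exactly 0 and sample sd exactly 1.
correlated_noise <- function(H, W, smooth_px = 8) {
  z <- matrix(stats::rnorm(H * W), H, W)
  if (smooth_px > 0) {
    gr <- stats::dnorm(pmin(0:(H - 1), H - (0:(H - 1))), sd = smooth_px)
    gc <- stats::dnorm(pmin(0:(W - 1), W - (0:(W - 1))), sd = smooth_px)
    ker <- outer(gr, gc)
    z <- Re(stats::fft(stats::fft(z) * stats::fft(ker), inverse = TRUE)) / (H * W)
  }
  (z - mean(z)) / stats::sd(z)
}

#' Render a synthetic thermal scene
#'
#' Temperature is the sum of a correlated background (exact per-scene mean
#' `background_mean`, sd `background_sd`), `coupling_slope` times the methane
#' concentration (zero for control scenes), and white sensor noise.
#' Deterministic for a fixed seed.
#'
#' @param shape `(n_rows, n_cols)`.
#' @param truth a [scene_truth()].
#' @param seed integer seed.
#' @param smooth_px background texture correlation length, px.
#' @return `list(image = thermal_image, concentration = concentration_field)`.
#' @export
render_scene <- function(shape, truth, seed = 1, smooth_px = 8) {
  H <- shape[1]; W <- shape[2]
  with_seed(seed, {
    bg <- truth$background_mean +
      truth$background_sd * correlated_noise(H, W, smooth_px)
    conc <- if (truth$condition == "control")
      structure(matrix(0, H, W), class = c("concentration_field", "matrix", "array"))
    else simulate_concentration(shape, truth)
    temp <- bg + truth$coupling_slope * conc +
      matrix(stats::rnorm(H * W, sd = truth$sensor_sd), H, W)
    img <- thermal_image(temp, species = truth$species,
                         condition = truth$condition)
    list(image = img, concentration = conc, truth = truth)
  })
}

#' Binary stressed-area mask implied by a concentration field
#'
#' @param conc a `concentration_field`.
#' @return logical matrix, `TRUE` where volume fraction exceeds 0.30.
#' @export
stress_region <- function(conc) unclass(conc) > STRESS_CONCENTRATION

#' Generate a balanced synthetic dataset
#'
#' For each species, `n_per_cell` stressed and `n_per_cell` control scenes
#' are rendered with per-scene seeds derived from `seed`; identical calls are
#' bit-reproducible. Stressed scenes draw a truth stress radius uniformly in
#' `radius_range` and a leak center placed so the stressed circle stays
#' inside the grid.
#'
#' @param n_per_cell scenes per species x condition cell (>= 0).
#' @param species character vector of species names.
#' @param shape scene shape `(n_rows, n_cols)`; the imager's native array is
#'   `c(240, 320)`.
#' @param seed integer seed.
#' @param radius_range truth stress radius bounds, px.
#' @param peak_concentration,coupling_slope,sensor_sd,smooth_px simulator
#'   parameters shared by all stressed scenes.
#' @param dir optional directory; when given, scenes are written as
#'   `csv_matrix` files plus `labels.csv` and `truths.json`.
#' @return an object of class `thermal_dataset`: list with `images` (list of
#'   [thermal_image()]), `labels` (condition factor), `species`, `truths`.
#' @export
generate_dataset <- function(n_per_cell, species = SPECIES_LEVELS,
                             shape = c(96, 96), seed = 1,
                             radius_range = c(10, 30),
                             peak_concentration = 0.6, coupling_slope = 10,
                             sensor_sd = 0.1, smooth_px = 8, dir = NULL) {
  if (!length(species)) stop("species_list must be non-empty")
  if (n_per_cell < 0) stop("n_per_cell must be >= 0")
  images <- list(); truths <- list()
  labels <- character(0); spp <- character(0)
  idx <- 0
  for (sp in species) {
    bgp <- SPECIES_BACKGROUND[[sp]] %||% c(mean = 27.5, sd = 0.8)
    for (cond in c("experimental", "control")) {
      for (i in seq_len(n_per_cell)) {
        idx <- idx + 1
        sseed <- derive_seed(seed, paste("scene", sp, cond, i))
        truth <- with_seed(sseed, {
          if (cond == "experimental") {
            radius <- stats::runif(1, radius_range[1], radius_range[2])
            sigma <- radius / sqrt(2 * log(peak_concentration / STRESS_CONCENTRATION))
            margin <- min(radius + 5, (min(shape) - 1) / 2)
            ctr <- c(stats::runif(1, 1 + margin, shape[1] - margin),
                     stats::runif(1, 1 + margin, shape[2] - margin))
            scene_truth(ctr, sigma, peak_concentration, coupling_slope,
                        background_mean = bgp[["mean"]],
                        background_sd = bgp[["sd"]], sensor_sd = sensor_sd,
                        species = sp, condition = cond)
          } else {
            scene_truth(c(shape[1] / 2, shape[2] / 2), sigma = 1,
                        peak_concentration = peak_concentration,
                        coupling_slope = coupling_slope,
                        background_mean = bgp[["mean"]],
                        background_sd = bgp[["sd"]], sensor_sd = sensor_sd,
                        species = sp, condition = cond)
          }
        })
        sc <- render_scene(shape, truth, seed = derive_seed(sseed, "render"),
                           smooth_px = smooth_px)
        images[[idx]] <- sc$image
        truths[[idx]] <- truth
        labels <- c(labels, cond)
        spp <- c(spp, sp)
      }
    }
  }
  ds <- structure(list(images = images,
                       labels = factor(labels, levels = CONDITION_LEVELS),
                       species = spp, truths = truths),
                  class = "thermal_dataset")
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' @export
print.thermal_dataset <- function(x, ...) {
  cat(sprintf("<thermal_dataset: %d scenes (%d stressed, %d control)>\n",
              length(x$images), sum(x$labels == "experimental"),
              sum(x$labels == "control")))
  invisible(x)
}

#' @export
length.thermal_dataset <- function(x) length(x$images)

#' Write a dataset to a directory
#'
#' Scenes go to `scene_<i>.csv` (csv_matrix), labels to `labels.csv`
#' (`path,species,condition,date`), truths to `truths.json`.
#'
#' @param ds a `thermal_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- sprintf("scene_%03d.csv", seq_along(ds$images))
  for (i in seq_along(ds$images))
    write_thermal(ds$images[[i]], file.path(dir, paths[i]))
  utils::write.csv(
    data.frame(path = paths, species = ds$species,
               condition = as.character(ds$labels),
               date = NA_character_),
    file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  tr <- lapply(ds$truths, function(t) {
    if (is.null(t)) return(NULL)
    c(unclass(t), list(stress_radius = stress_radius(t)))
  })
  jsonlite::write_json(tr, file.path(dir, "truths.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing `labels.csv` and scene files.
#' @return a `thermal_dataset` (truths restored when `truths.json` exists).
#' @export
read_dataset <- function(dir) {
  lab <- utils::read.csv(file.path(dir, "labels.csv"),
                         stringsAsFactors = FALSE)
  images <- lapply(seq_len(nrow(lab)), function(i)
    read_thermal(file.path(dir, lab$path[i]), species = lab$species[i],
                 condition = lab$condition[i]))
  truths <- NULL
  tj <- file.path(dir, "truths.json")
  if (file.exists(tj)) {
    raw <- jsonlite::read_json(tj, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    truths <- lapply(raw, function(t) {
      if (is.null(t)) return(NULL)
      do.call(scene_truth, t[setdiff(names(t), "stress_radius")])
    })
  }
  structure(list(images = images,
                 labels = factor(lab$condition, levels = CONDITION_LEVELS),
                 species = lab$species, truths = truths),
            class = "thermal_dataset")
}
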