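# Canopy temperature cross-sections and statistics, the concentration -
# temperature correlation, and inverse-distance contouring of point gas
# samples.

#' Diagonal temperature cross-section
#'
#' Extracts the pixel temperatures along a corner-to-corner diagonal:
#' `"NW-SE"` runs top-left to bottom-right, `"NE-SW"` top-right to
#' bottom-left. The line is rasterized to one pixel per step along the
#' longer image dimension.
#'
#' @param img a [thermal_image()] or matrix, at least 2 x 2.
#' @param section `"NE-SW"` or `"NW-SE"`.
#' @param center optional `(row, col)`: draw the diagonals through this
#'   point (e.g. a fitted leak center) instead of the full-image corners;
#'   the line keeps the same slope and is clipped to the image.
#' @return numeric vector of temperatures along the line.
#' @export
cross_section <- function(img, section = c("NW-SE", "NE-SW"), center = NULL) {
  section <- match.arg(section)
  x <- if (inherits(img, "thermal_image")) img$values else as.matrix(img)
  H <- nrow(x); W <- ncol(x)
  if (H < 2 || W < 2) stop("image must be at least 2 x 2")
  n <- max(H, W)
  rows <- seq(1, H, length.out = n)
  cols <- if (section == "NW-SE") seq(1, W, length.out = n)
          else seq(W, 1, length.out = n)
  if (!is.null(center)) {
    rows <- rows - mean(rows) + center[1]
    cols <- cols - mean(cols) + center[2]
    keep <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
    rows <- rows[keep]; cols <- cols[keep]
  }
  x[cbind(round(rows), round(cols))]
}

#' Summary statistics of a temperature profile
#'
#' @param profile numeric vector (length >= 1; sd needs >= 2).
#' @param section optional section label carried through.
#' @return list with `mean`, `sd` (sample, n-1), `min`, `max`, `n`,
#'   `section`.
#' @export
profile_stats <- function(profile, section = NA_character_) {
  if (!length(profile)) stop("empty profile")
  if (length(profile) < 2) stop("sd undefined for a single-sample profile")
  list(mean = mean(profile), sd = stats::sd(profile), min = min(profile),
       max = max(profile), n = length(profile), section = section)
}

#' Stress contrasts from a per-species statistics table
#'
#' Given per-species profile statistics for experimental and control plots,
#' computes each species' mean-temperature contrast (experimental minus
#' control), the range of those contrasts, and each experimental plot's
#' temperature span (max minus min).
#'
#' @param stats_table data frame with columns `species`, `condition`
#'   (`"experimental"`/`"control"`), `mean`, `sd`, `min`, `max`.
#' @return list with `contrasts` (data frame: species, mean_diff, span),
#'   `min_diff`, `max_diff`, `min_span`.
#' @export
stress_contrasts <- function(stats_table) {
  sp <- unique(stats_table$species)
  rows <- lapply(sp, function(s) {
    e <- stats_table[stats_table$species == s &
                       stats_table$condition == "experimental", ]
    c0 <- stats_table[stats_table$species == s &
                        stats_table$condition == "control", ]
    if (nrow(e) != 1 || nrow(c0) != 1)
      stop("both conditions required for species ", s)
    data.frame(species = s, mean_diff = e$mean - c0$mean,
               span = e$max - e$min)
  })
  ct <- do.call(rbind, rows)
  list(contrasts = ct, min_diff = min(ct$mean_diff),
       max_diff = max(ct$mean_diff), min_span = min(ct$span))
}

#' Concentration-temperature correlation
#'
#' Ordinary least-squares regression of canopy temperature on methane volume
#' fraction, with the Pearson correlation and the root-mean-squared residual
#' of the fit.
#'
#' @param concentration,temperature paired numeric vectors (n >= 3).
#' @return list with `slope` (degC per unit volume fraction), `intercept`,
#'   `pearson_r`, `rmse`, `n`, and `slope_se` (standard error of the slope).
#' @export
correlate_concentration <- function(concentration, temperature) {
  n <- length(concentration)
  if (n != length(temperature)) stop("length mismatch")
  if (n < 3) stop("at least 3 points required")
  if (stats::sd(concentration) == 0) stop("constant concentration")
  fit <- stats::lm(temperature ~ concentration)
  res <- stats::residuals(fit)
  # exact fits make lm's summary warn; the se is 0 there anyway
  se <- suppressWarnings(unname(summary(fit)$coefficients[2, 2]))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       pearson_r = stats::cor(concentration, temperature),
       rmse = sqrt(mean(res^2)),
       slope_se = se,
       n = n)
}

#' Sample paired concentration/temperature points from a scene
#'
#' Draws `n` random pixels (seeded) from the overlap of a thermal image and a
#' concentration field and returns the paired values, the sampling protocol
#' behind the correlation analysis.
#'
#' @param img a [thermal_image()].
#' @param conc a `concentration_field` of the same shape.
#' @param n number of points.
#' @param seed integer seed.
#' @return data frame with `row`, `col`, `concentration`, `temperature`.
#' @export
sample_correlation_points <- function(img, conc, n = 236, seed = 1) {
  stopifnot(all(dim(img$values) == dim(conc)))
  idx <- with_seed(seed, sample.int(length(conc), n, replace = n > length(conc)))
  rc <- arrayInd(idx, dim(conc))
  data.frame(row = rc[, 1], col = rc[, 2],
             concentration = as.vector(unclass(conc))[idx],
             temperature = as.vector(img$values)[idx])
}

#' Inverse-distance-weighted concentration contour grid
#'
#' Interpolates scattered `(x, y, concentration)` gas samples onto a grid by
#' inverse-distance weighting (power 2). Exact at sample locations; all
#' interpolated values lie within the sample range.
#'
#' @param samples data frame with columns `x` (col), `y` (row),
#'   `concentration`.
#' @param grid_shape `(n_rows, n_cols)`.
#' @param power IDW exponent.
#' @return a `concentration_field` matrix.
#' @export
contour_field <- function(samples, grid_shape, power = 2) {
  if (nrow(samples) < 3) stop("at least 3 sample points required")
  xy <- cbind(samples$x, samples$y)
  if (qr(cbind(1, xy))$rank < 3) stop("sample points are collinear")
  H <- grid_shape[1]; W <- grid_shape[2]
  gr <- rep(seq_len(H), W); gc <- rep(seq_len(W), each = H)
  out <- numeric(H * W)
  d2 <- outer(gr, samples$y, "-")^2 + outer(gc, samples$x, "-")^2
  hit <- d2 < 1e-12
  w <- 1 / (sqrt(d2)^power)
  w[hit] <- NA
  num <- rowSums(sweep(w, 2, samples$concentration, "*"), na.rm = TRUE)
  den <- rowSums(w, na.rm = TRUE)
  out <- num / den
  exact <- which(rowSums(hit) > 0)
  for (i in exact) out[i] <- samples$concentration[which(hit[i, ])[1]]
  structure(matrix(out, H, W),
            class = c("concentration_field", "matrix", "array"))
}

#' Per-species profile statistics table for a dataset
#'
#' Computes cross-section statistics (both diagonals pooled) per species and
#' condition, the simulated analogue of the field statistics table.
#'
#' @param ds a `thermal_dataset`.
#' @return data frame with `species`, `condition`, `mean`, `sd`, `min`,
#'   `max`, `n_scenes`.
#' @export
dataset_profile_table <- function(ds) {
  key <- paste(ds$species, ds$labels, sep = ".")
  rows <- lapply(split(seq_along(ds$images), key), function(ii) {
    vals <- unlist(lapply(ii, function(i) c(
      cross_section(ds$images[[i]], "NE-SW"),
      cross_section(ds$images[[i]], "NW-SE"))))
    data.frame(species = ds$species[ii[1]],
               condition = as.character(ds$labels[ii[1]]),
               mean = mean(vals), sd = stats::sd(vals), min = min(vals),
               max = max(vals), n_scenes = length(ii))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
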