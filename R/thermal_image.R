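# Thermal image container and I/O.
#
# A thermal image is a plain 2-D matrix of canopy temperatures in degrees
# Celsius plus plot metadata. Two on-disk forms are supported: a headerless
# CSV matrix (one pixel per cell, row-major, '.' decimal separator) and a
# single-channel 16-bit TIFF with a JSON sidecar giving the linear decoding
# temperature = raw * scale + offset.

SPECIES_LEVELS <- c("grass", "soybean", "corn", "wheat")
CONDITION_LEVELS <- c("experimental", "control")
TEMP_RANGE <- c(-20, 600) # operating range of the thermal imager, degC

#' Create a thermal image
#'
#' @param values numeric matrix of temperatures in degrees Celsius,
#'   `(row, col)` indexed with row 1 at the top.
#' @param species vegetation type, one of `"grass"`, `"soybean"`, `"corn"`,
#'   `"wheat"`, or `NA`.
#' @param condition `"experimental"` (gas-stressed plot) or `"control"`, or `NA`.
#' @param date acquisition date (`Date` or string), optional.
#' @param pixel_size ground sampling distance in m/px, optional.
#' @param validate check finiteness and the imager temperature range.
#' @return an object of class `thermal_image`.
#' @export
thermal_image <- function(values, species = NA_character_,
                          condition = NA_character_, date = NULL,
                          pixel_size = NULL, validate = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1 || ncol(values) < 1)
    stop("thermal image must have at least one pixel")
  if (!is.na(species)) species <- match.arg(species, SPECIES_LEVELS)
  if (!is.na(condition)) condition <- match.arg(condition, CONDITION_LEVELS)
  if (validate) {
    bad <- which(!is.finite(values) | values < TEMP_RANGE[1] | values > TEMP_RANGE[2])
    if (length(bad)) {
      rc <- arrayInd(bad[1], dim(values))
      stop(sprintf("temperature out of range or non-finite at (row %d, col %d): %s",
                   rc[1], rc[2], format(values[bad[1]])))
    }
  }
  structure(list(values = values, n_rows = nrow(values), n_cols = ncol(values),
                 meta = list(species = species, condition = condition,
                             date = date, pixel_size = pixel_size)),
            class = "thermal_image")
}

#' @export
print.thermal_image <- function(x, ...) {
  cat(sprintf("<thermal_image %d x %d px, %s / %s>\n", x$n_rows, x$n_cols,
              x$meta$species, x$meta$condition))
  cat(sprintf("  temperature: %.2f .. %.2f degC (mean %.2f)\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' @export
dim.thermal_image <- function(x) dim(x$values)

#' Read a thermal image from disk
#'
#' @param path file path. For `tiff16`, a JSON sidecar `<path>.json` with
#'   fields `scale` and `offset` must exist unless both are given explicitly.
#' @param format `"csv_matrix"` or `"tiff16"`.
#' @param scale,offset linear decoding for `tiff16`:
#'   `temperature = raw * scale + offset`. Read from the sidecar when `NULL`.
#' @param ... metadata passed to [thermal_image()].
#' @return a [thermal_image()].
#' @export
read_thermal <- function(path, format = c("csv_matrix", "tiff16"),
                         scale = NULL, offset = NULL, ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv_matrix") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty csv matrix: ", path)
    rows <- strsplit(lines, ",", fixed = TRUE)
    ncols <- lengths(rows)
    if (any(ncols != ncols[1])) {
      bad <- which(ncols != ncols[1])[1]
      stop(sprintf("ragged csv matrix: row %d has %d cells, expected %d",
                   bad, ncols[bad], ncols[1]))
    }
    vals <- suppressWarnings(vapply(rows, function(r) as.numeric(r), numeric(ncols[1])))
    vals <- if (is.matrix(vals)) t(vals) else matrix(vals, nrow = length(rows))
    if (anyNA(vals)) {
      bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
      stop(sprintf("non-numeric cell at (row %d, col %d)", bad[1], bad[2]))
    }
    thermal_image(vals, ...)
  } else {
    if (is.null(scale) || is.null(offset)) {
      sidecar <- paste0(path, ".json")
      if (!file.exists(sidecar))
        stop("tiff16 requires scale/offset or sidecar ", sidecar)
      sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      scale <- scale %||% sc$scale
      offset <- offset %||% sc$offset
    }
    raw <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(raw)) == 3) raw <- raw[, , 1]
    thermal_image(raw * scale + offset, ...)
  }
}

#' Write a thermal image to disk
#'
#' @param img a [thermal_image()].
#' @param path output path; for `tiff16` a sidecar `<path>.json` is written.
#' @param format `"csv_matrix"` or `"tiff16"`.
#' @param digits decimal places kept in CSV output.
#' @param scale,offset linear encoding used for `tiff16`
#'   (`raw = round((temperature - offset) / scale)`).
#' @return `path`, invisibly.
#' @export
write_thermal <- function(img, path, format = c("csv_matrix", "tiff16"),
                          digits = 4, scale = 0.01, offset = -20) {
  format <- match.arg(format)
  stopifnot(inherits(img, "thermal_image"))
  if (format == "csv_matrix") {
    txt <- apply(img$values, 1, function(r)
      paste(formatC(r, digits = digits, format = "f"), collapse = ","))
    writeLines(txt, path)
  } else {
    raw <- round((img$values - offset) / scale)
    if (any(raw < 0 | raw > 65535))
      stop("temperature not representable with given tiff16 scale/offset")
    tiff::writeTIFF(raw / 65535, path, bits.per.sample = 16)
    jsonlite::write_json(list(scale = scale, offset = offset),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Remove singular pixel values (marker artifacts)
#'
#' Field thermal images carry isolated hot/cold pixels from metal marker
#' points. A pixel is replaced by its window-local median when its absolute
#' deviation from that median exceeds `k` robust standard deviations
#' (1.4826 times the local median absolute deviation); all other pixels are
#' untouched. Borders use replicated-edge padding.
#'
#' @param img a [thermal_image()].
#' @param window odd window side length (>= 3).
#' @param k robust z-score threshold (> 0).
#' @return a cleaned [thermal_image()].
#' @export
remove_singular_values <- function(img, window = 5, k = 5) {
  stopifnot(inherits(img, "thermal_image"), window >= 3, window %% 2 == 1, k > 0)
  x <- img$values
  H <- nrow(x); W <- ncol(x)
  if (window > H || window > W)
    stop("window larger than image dimension")
  p <- (window - 1) %/% 2
  ri <- clamp(seq(1 - p, H + p), 1, H)
  ci <- clamp(seq(1 - p, W + p), 1, W)
  xp <- x[ri, ci, drop = FALSE]
  nb <- neighborhood_matrix(xp, window)        # (H*W) x window^2
  med <- apply(nb, 1, stats::median)
  mad_ <- 1.4826 * apply(abs(nb - med), 1, stats::median)
  dev <- abs(as.vector(x) - med)
  out <- as.vector(x)
  # zero local MAD (flat neighborhood): any real deviation counts as singular
  bad <- dev > pmax(k * mad_, 1e-9)
  out[bad] <- med[bad]
  img$values <- matrix(out, H, W)
  img
}

# Extract all window x window neighborhoods of the padded matrix xp,
# one row per interior pixel (column-major pixel order).
neighborhood_matrix <- function(xp, window) {
  Hp <- nrow(xp); Wp <- ncol(xp)
  H <- Hp - window + 1; W <- Wp - window + 1
  pos <- rep(seq_len(H), times = W) + Hp * (rep(seq_len(W), each = H) - 1)
  off <- as.vector(outer(0:(window - 1), 0:(window - 1) * Hp, "+"))
  matrix(xp[outer(pos - 1, off, "+") + 1], nrow = H * W)
}

#' Encode a thermal image as a 3-channel model input
#'
#' Maps temperatures to `[0, 1]` and replicates the result to 3 channels for
#' the convolutional network.
#'
#' @param img a [thermal_image()] or a plain matrix.
#' @param mode `"minmax_gray"` scales the image's own `[min, max]` to
#'   `[0, 1]` (a constant image maps to 0.5); `"fixed_range"` scales the
#'   configured `range` window, clamping outside values; `"anomaly"` encodes
#'   the temperature elevation above the plot's own background canopy
#'   temperature (estimated as the 20th percentile, robust to hotspots
#'   covering up to ~three quarters of the plot) on the absolute span
#'   `range` (degC above background), so an unstressed canopy maps to ~0
#'   regardless of species or weather while hotspot contrast keeps its
#'   absolute scale.
#' @param range temperature window (degC) for `fixed_range`, or the
#'   above-median span for `anomaly`.
#' @return an `H x W x 3` array in `[0, 1]`.
#' @export
to_model_input <- function(img, mode = c("minmax_gray", "fixed_range",
                                         "anomaly"),
                           range = c(20, 40)) {
  mode <- match.arg(mode)
  x <- if (inherits(img, "thermal_image")) img$values else as.matrix(img)
  if (mode == "minmax_gray") {
    lo <- min(x); hi <- max(x)
    g <- if (hi > lo) (x - lo) / (hi - lo) else array(0.5, dim(x))
  } else if (mode == "fixed_range") {
    if (range[1] >= range[2]) stop("fixed_range requires lo < hi")
    g <- clamp((x - range[1]) / (range[2] - range[1]), 0, 1)
  } else {
    if (range[1] >= range[2]) stop("anomaly requires lo < hi")
    bg <- stats::quantile(x, 0.1, names = FALSE)
    g <- clamp((x - bg - range[1]) / (range[2] - range[1]), 0, 1)
  }
  array(g, c(nrow(x), ncol(x), 3))
}
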