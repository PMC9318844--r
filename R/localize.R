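# Leak-area localization: adaptive-threshold segmentation of a heatmap,
# connected-component selection, least-squares circle fitting, and the
# stress-radius time series.

#' Otsu threshold of a heatmap
#'
#' Global Otsu's method on a 256-bin histogram over `[0, 1]`: the threshold
#' maximizing between-class variance.
#'
#' @param x numeric matrix/vector with values in `[0, 1]`.
#' @param levels number of histogram bins.
#' @return threshold value in `(0, 1)`, or `NA` for a constant input.
#' @export
otsu_threshold <- function(x, levels = 256) {
  v <- as.vector(x)
  if (max(v) - min(v) < 1e-12) return(NA_real_)
  edges <- seq(0, 1, length.out = levels + 1)
  counts <- tabulate(pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE),
                               1), levels), nbins = levels)
  n <- sum(counts)
  mids <- (edges[-1] + edges[-(levels + 1)]) / 2
  w0 <- cumsum(counts) / n
  mu0 <- cumsum(counts * mids) / n
  muT <- mu0[levels]
  sb2 <- (muT * w0 - mu0)^2 / (w0 * (1 - w0))
  sb2[!is.finite(sb2)] <- -Inf
  t <- which.max(sb2[-levels])
  edges[t + 1]
}

#' Segment a heatmap into a binary stress mask
#'
#' Pixels at or above the Otsu threshold are foreground. A constant heatmap
#' has no informative threshold and yields an empty mask.
#'
#' @param heatmap matrix with values in `[0, 1]`.
#' @param levels histogram bins for the threshold.
#' @return logical matrix of the same shape.
#' @export
segment_heatmap <- function(heatmap, levels = 256) {
  heatmap <- as.matrix(heatmap)
  if (min(heatmap) < -1e-9 || max(heatmap) > 1 + 1e-9)
    stop("heatmap values must lie in [0, 1]")
  thr <- otsu_threshold(heatmap, levels)
  if (is.na(thr)) return(matrix(FALSE, nrow(heatmap), ncol(heatmap)))
  heatmap >= thr
}

# 8-connected component labelling by vectorized frontier expansion.
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nbr_off <- c(-1, 1, -H, H, -H - 1, -H + 1, H - 1, H + 1)
  rowpos <- matrix(rep(seq_len(H), W), H, W)
  current <- 0L
  todo <- which(mask & lab == 0L)
  while (length(todo)) {
    current <- current + 1L
    frontier <- todo[1]
    lab[frontier] <- current
    while (length(frontier)) {
      cand <- rep(frontier, each = 8) + rep(nbr_off, times = length(frontier))
      # drop wrap-arounds across the top/bottom edge
      fr <- rep(rowpos[frontier], each = 8)
      dr <- rep(c(-1, 1, 0, 0, -1, 1, -1, 1), times = length(frontier))
      ok <- cand >= 1 & cand <= H * W & (fr + dr) >= 1 & (fr + dr) <= H &
        ((cand - 1) %% H + 1) == (fr + dr)
      cand <- unique(cand[ok])
      cand <- cand[mask[cand] & lab[cand] == 0L]
      lab[cand] <- current
      frontier <- cand
    }
    todo <- which(mask & lab == 0L)
  }
  lab
}

# Boundary pixels: foreground with at least one 4-neighbor outside the
# component (image border counts as outside).
boundary_pixels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  core <- pad[2:(H + 1), 2:(W + 1)]
  up <- pad[1:H, 2:(W + 1)]; dn <- pad[3:(H + 2), 2:(W + 1)]
  lf <- pad[2:(H + 1), 1:W]; rt <- pad[2:(H + 1), 3:(W + 2)]
  core & !(up & dn & lf & rt)
}

# Perimeter by Moore-neighbor contour tracing with Jacob's stopping
# criterion (orthogonal step 1, diagonal step sqrt(2)). Single-pixel
# components return 4 (their unit-square outline).
trace_perimeter <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  if (sum(mask) == 1) return(4)
  # clockwise Moore neighborhood in (row-down, col-right) coordinates
  dirs <- matrix(c(0, 1,  1, 1,  1, 0,  1, -1,
                   0, -1, -1, -1, -1, 0, -1, 1),
                 ncol = 2, byrow = TRUE)  # E SE S SW W NW N NE
  fg <- function(p) p[1] >= 1 && p[1] <= H && p[2] >= 1 && p[2] <= W &&
    mask[p[1], p[2]]
  # start: topmost, then leftmost foreground pixel; entered from the west
  sr <- which(rowSums(mask) > 0)[1]
  sc <- which(mask[sr, ])[1]
  start <- c(sr, sc)
  back0 <- c(sr, sc - 1)
  cur <- start; back <- back0
  per <- 0
  steps <- 0
  repeat {
    # index of the backtrack cell in cur's clockwise neighborhood
    db <- back - cur
    b <- which(dirs[, 1] == db[1] & dirs[, 2] == db[2])
    nxt <- NULL
    for (i in 1:8) {
      d <- ((b - 1 + i - 1) %% 8) + 1
      cand <- cur + dirs[d, ]
      if (fg(cand)) {
        nxt <- cand
        prev <- cur + dirs[((b - 1 + i - 2) %% 8) + 1, ]
        break
      }
    }
    if (is.null(nxt)) return(4)  # isolated pixel
    per <- per + sqrt(sum((nxt - cur)^2))
    back <- prev   # last background cell checked before nxt
    cur <- nxt
    steps <- steps + 1
    if ((all(cur == start) && all(back == back0)) || steps > 4 * H * W) break
  }
  per
}

#' Fit a circle to the stressed region of a binary mask
#'
#' Selects the largest 8-connected component, extracts its boundary pixels
#' (foreground pixels with a 4-neighbor outside), and fits them with the
#' algebraic least-squares (Kasa) circle: minimize
#' `sum (x^2 + y^2 + D x + E y + F)^2`. Components whose circularity
#' `4 pi A / P^2` falls below `min_circularity` are rejected; components with
#' fewer than `min_boundary` boundary points fall back to the centroid and
#' equivalent radius `sqrt(A / pi)`.
#'
#' @param mask logical matrix (TRUE = stressed).
#' @param min_circularity circularity acceptance threshold.
#' @param min_boundary minimum boundary points for the algebraic fit.
#' @return an object of class `stress_circle`: `center` (row, col), `radius`
#'   (px), `fit_rms` (px), `circularity`, `n_boundary_points`, `area`.
#' @export
fit_circle <- function(mask, min_circularity = 0.4, min_boundary = 20) {
  mask <- as.matrix(mask) > 0
  if (!any(mask)) stop("empty mask: no stressed region to fit")
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  comp <- lab == which.max(sizes)
  area <- sum(comp)
  per <- trace_perimeter(comp)
  circ <- min(4 * pi * area / per^2, 1.1) # clamp discretization overshoot
  if (circ < min_circularity)
    stop(sprintf("largest component circularity %.3f below %.2f: not quasi-circular",
                 circ, min_circularity))
  bnd <- which(boundary_pixels(comp), arr.ind = TRUE)
  # pixels on the image frame are clipping artifacts, not circle boundary;
  # drop them unless nothing else remains
  interior <- bnd[, 1] > 1 & bnd[, 1] < nrow(mask) &
    bnd[, 2] > 1 & bnd[, 2] < ncol(mask)
  if (any(interior)) bnd <- bnd[interior, , drop = FALSE]
  nb <- nrow(bnd)
  if (nb < min_boundary) {
    ctr <- colMeans(which(comp, arr.ind = TRUE))
    radius <- sqrt(area / pi)
    rms <- if (nb > 0)
      sqrt(mean((sqrt((bnd[, 1] - ctr[1])^2 + (bnd[, 2] - ctr[2])^2) - radius)^2))
    else 0
  } else {
    x <- bnd[, 2]; y <- bnd[, 1]
    A <- cbind(x, y, 1)
    rhs <- -(x^2 + y^2)
    coef <- qr.solve(A, rhs)
    cx <- -coef[1] / 2; cy <- -coef[2] / 2
    radius <- sqrt(max(cx^2 + cy^2 - coef[3], 0))
    ctr <- c(cy, cx) # (row, col)
    rms <- sqrt(mean((sqrt((y - cy)^2 + (x - cx)^2) - radius)^2))
  }
  structure(list(center = unname(ctr), radius = unname(radius),
                 fit_rms = rms, circularity = circ,
                 n_boundary_points = nb, area = area),
            class = "stress_circle")
}

#' @export
print.stress_circle <- function(x, ...) {
  cat(sprintf(
    "<stress_circle center (%.1f, %.1f) radius %.2f px rms %.3f circ %.2f>\n",
    x$center[1], x$center[2], x$radius, x$fit_rms, x$circularity))
  invisible(x)
}

#' End-to-end leak detection on a thermal image
#'
#' Classifies the image; when it is predicted stressed, computes the
#' Grad-CAM heatmap for the stressed class, segments it and fits the stress
#' circle.
#'
#' @param model a trained `glnb` model.
#' @param img a [thermal_image()].
#' @param force_class compute the map for this class regardless of the
#'   prediction (`NULL` = predicted class).
#' @param min_circularity see [fit_circle()].
#' @param symmetrize average the class activation map over the four axis
#'   flips of the input (test-time symmetrization); cancels orientation-
#'   dependent map noise and sharpens the fitted center.
#' @return list with `predicted` (1 stressed / 2 control), `probs`,
#'   `heatmap` and `circle` (both `NULL` for control predictions).
#' @export
detect_leak <- function(model, img, force_class = NULL, min_circularity = 0.4,
                        symmetrize = TRUE) {
  input <- encode_input(img, model$config)
  pr <- predict_glnb(model, list(input))
  cls <- pr$class[1]
  if (cls != 1L && is.null(force_class))
    return(list(predicted = cls, probs = pr$probs[, 1],
                heatmap = NULL, circle = NULL))
  target <- force_class %||% 1L
  H <- dim(input)[1]; W <- dim(input)[2]
  flips <- if (symmetrize) list(
    c(FALSE, FALSE, FALSE), c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE),
    c(TRUE, TRUE, FALSE),
    if (H == W) c(FALSE, FALSE, TRUE), if (H == W) c(TRUE, FALSE, TRUE),
    if (H == W) c(FALSE, TRUE, TRUE), if (H == W) c(TRUE, TRUE, TRUE))
  else list(c(FALSE, FALSE, FALSE))
  flips <- Filter(Negate(is.null), flips)
  raw <- NULL
  for (fl in flips) {
    xi <- input
    if (fl[3]) xi <- aperm(xi, c(2, 1, 3))
    if (fl[1]) xi <- xi[dim(xi)[1]:1, , , drop = FALSE]
    if (fl[2]) xi <- xi[, dim(xi)[2]:1, , drop = FALSE]
    cm <- compute_cam(model, xi, class = target)
    r <- cm$raw
    if (fl[2]) r <- r[, ncol(r):1, drop = FALSE]
    if (fl[1]) r <- r[nrow(r):1, , drop = FALSE]
    if (fl[3]) r <- t(r)
    raw <- if (is.null(raw)) r else raw + r
  }
  heat <- upsample_cam(raw / length(flips), dim(img$values))
  mask <- segment_heatmap(heat)
  circle <- if (any(mask))
    tryCatch(fit_circle(mask, min_circularity = min_circularity),
             error = function(e) NULL)
  list(predicted = cls, probs = pr$probs[, 1], heatmap = heat, circle = circle)
}

#' Stress-radius time series
#'
#' Orders fitted circles by date and reports the mean stress radius, the
#' summary used to track leak spread over time.
#'
#' @param dates vector of dates (strictly increasing).
#' @param circles list of `stress_circle`s, same length.
#' @return list with `series` (data frame: date, radius_px, center_r,
#'   center_c) and `mean_radius`.
#' @export
radius_series <- function(dates, circles) {
  if (length(dates) != length(circles)) stop("dates/circles length mismatch")
  if (length(dates) == 0) stop("empty series")
  d <- as.Date(dates)
  if (any(duplicated(d))) stop("duplicate dates")
  if (is.unsorted(d, strictly = TRUE)) stop("dates must be strictly increasing")
  ser <- data.frame(
    date = d,
    radius_px = vapply(circles, function(c) c$radius, numeric(1)),
    center_r = vapply(circles, function(c) c$center[1], numeric(1)),
    center_c = vapply(circles, function(c) c$center[2], numeric(1)))
  list(series = ser, mean_radius = mean(ser$radius_px))
}
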