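# Label-preserving augmentation of model-input images: flips, random-angle
# rotation (reflection-padded), cropping with resize-back, brightness jitter
# (the only color-like degree of freedom of single-band thermal data after
# channel replication) and additive noise.

#' Augmentation plan
#'
#' @param ops ordered subset of `"hflip"`, `"vflip"`, `"rotate"`, `"crop"`,
#'   `"brightness"`, `"noise"`. When expanding a dataset, each op in the
#'   plan is applied with probability 1/2 (at least one is always applied),
#'   with parameters drawn from the ranges below.
#' @param target_count total images after expansion.
#' @param seed integer seed.
#' @param crop_range crop fraction bounds, within `(0.5, 1]`.
#' @param angle_range rotation bounds in degrees, within `[0, 360)`.
#' @param brightness_range additive brightness bounds.
#' @param noise_sd additive Gaussian noise sd (>= 0).
#' @return an object of class `augment_plan`.
#' @export
augment_plan <- function(ops = c("hflip", "vflip", "rotate", "crop",
                                 "brightness", "noise"),
                         target_count = 7571, seed = 1,
                         crop_range = c(0.7, 1), angle_range = c(0, 360),
                         brightness_range = c(-0.1, 0.1), noise_sd = 0.02) {
  ops <- match.arg(ops, several.ok = TRUE)
  if (any(crop_range <= 0.5) || any(crop_range > 1))
    stop("crop fraction must lie in (0.5, 1]")
  if (any(angle_range < 0) || any(angle_range >= 360.0001))
    stop("rotation angle must lie in [0, 360)")
  if (noise_sd < 0) stop("noise sd must be >= 0")
  structure(list(ops = ops, target_count = target_count, seed = seed,
                 crop_range = crop_range, angle_range = angle_range,
                 brightness_range = brightness_range, noise_sd = noise_sd),
            class = "augment_plan")
}

# rotate one channel by `angle` degrees about the image center, sampling the
# reflection-padded source bilinearly; output keeps the input shape.
rotate_channel <- function(m, angle) {
  H <- nrow(m); W <- ncol(m)
  pad <- ceiling((sqrt(H^2 + W^2) - min(H, W)) / 2) + 2
  mp <- m[reflect_index(H, pad), reflect_index(W, pad)]
  th <- angle * pi / 180
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  gr <- rep(seq_len(H), W) - cr
  gc <- rep(seq_len(W), each = H) - cc
  sr <- cos(th) * gr - sin(th) * gc + cr + pad
  sc <- sin(th) * gr + cos(th) * gc + cc + pad
  matrix(bilinear_sample(mp, sr, sc), H, W)
}

apply_channelwise <- function(x, f) {
  out <- x
  for (ch in seq_len(dim(x)[3])) out[, , ch] <- f(x[, , ch])
  out
}

#' Apply one augmentation operation
#'
#' Deterministic given `seed`; the output keeps the model-input shape
#' (crops are resized back, rotations fill exposed corners by reflection
#' padding) and stays in `[0, 1]`.
#'
#' @param x `H x W x C` model-input array in `[0, 1]`.
#' @param op operation name (see [augment_plan()]).
#' @param seed seed for the op's random parameters.
#' @param angle,fraction,delta,sd explicit parameters overriding the random
#'   draw: rotation angle (deg), crop fraction, brightness shift, noise sd.
#' @param plan an [augment_plan()] supplying parameter ranges.
#' @return augmented array of the same shape.
#' @export
apply_augment <- function(x, op, seed = 1, angle = NULL, fraction = NULL,
                          delta = NULL, sd = NULL, plan = augment_plan()) {
  H <- dim(x)[1]; W <- dim(x)[2]
  with_seed(seed, switch(op,
    hflip = x[, W:1, , drop = FALSE],
    vflip = x[H:1, , , drop = FALSE],
    rotate = {
      a <- angle %||% stats::runif(1, plan$angle_range[1], plan$angle_range[2])
      apply_channelwise(x, function(m) clamp(rotate_channel(m, a), 0, 1))
    },
    crop = {
      f <- fraction %||% stats::runif(1, plan$crop_range[1], plan$crop_range[2])
      if (f <= 0.5) stop("crop fraction must exceed 0.5")
      ch <- max(2, round(H * f)); cw <- max(2, round(W * f))
      r0 <- sample.int(H - ch + 1, 1); c0 <- sample.int(W - cw + 1, 1)
      apply_channelwise(x, function(m)
        resize_bilinear(m[r0:(r0 + ch - 1), c0:(c0 + cw - 1)], H, W))
    },
    brightness = {
      d <- delta %||% stats::runif(1, plan$brightness_range[1],
                                   plan$brightness_range[2])
      clamp(x + d, 0, 1)
    },
    noise = {
      s <- sd %||% plan$noise_sd
      clamp(x + array(stats::rnorm(length(x), sd = s), dim(x)), 0, 1)
    },
    stop("unknown augmentation op: ", op)))
}

#' Expand a dataset to a target size with augmentation
#'
#' Keeps every original image and adds augmented copies until
#' `plan$target_count` images exist, preserving per-class proportions within
#' one image (stratified largest-remainder allocation). Bit-reproducible for
#' a fixed plan seed.
#'
#' @param inputs list of `H x W x C` arrays.
#' @param labels class labels, same length.
#' @param plan an [augment_plan()] with `target_count >= length(inputs)`.
#' @return list with `inputs`, `labels` and `source` (index of each image's
#'   original).
#' @export
expand_dataset <- function(inputs, labels, plan = augment_plan()) {
  n <- length(inputs)
  if (!n) stop("empty dataset")
  if (plan$target_count < n) stop("target_count below dataset size")
  labels <- as.character(labels)
  extra <- plan$target_count - n
  # largest-remainder allocation of extra images across classes
  tab <- table(labels)
  quota <- extra * as.numeric(tab) / n
  base <- floor(quota)
  rem <- extra - sum(base)
  if (rem > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  out_inputs <- inputs; out_labels <- labels
  out_source <- seq_len(n)
  k <- n
  for (ci in seq_along(tab)) {
    cls <- names(tab)[ci]
    pool <- which(labels == cls)
    for (j in seq_len(base[ci])) {
      sd_j <- derive_seed(plan$seed, paste("aug", cls, j))
      src <- with_seed(sd_j, sample(pool, 1))
      img <- inputs[[src]]
      ops_on <- with_seed(derive_seed(sd_j, "ops"), {
        on <- stats::runif(length(plan$ops)) < 0.5
        if (!any(on)) on[sample.int(length(plan$ops), 1)] <- TRUE
        on
      })
      for (oi in which(ops_on))
        img <- apply_augment(img, plan$ops[oi],
                             seed = derive_seed(sd_j, plan$ops[oi]),
                             plan = plan)
      k <- k + 1
      out_inputs[[k]] <- img
      out_labels[k] <- cls
      out_source[k] <- src
    }
  }
  list(inputs = out_inputs, labels = out_labels, source = out_source)
}
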