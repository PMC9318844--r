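# Grad-CAM: class-specific localization maps from the last convolutional
# layer. The neuron weight of channel k for class c is the spatial average of
# the gradient of the class score with respect to that channel's activations;
# the raw map is the ReLU of the weighted channel sum, and the heatmap is its
# bilinear upsampling normalized to [0, 1].

#' Grad-CAM neuron weights
#'
#' The importance weight of channel `k` for the target class is the global
#' average (over the `Z` spatial locations) of the gradient of the class
#' score with respect to that channel: `alpha_k = (1/Z) sum_ij dy/dA_k[i,j]`.
#'
#' @param grads `H x W x K` array of score gradients with respect to the
#'   last convolutional activations.
#' @return numeric vector of `K` weights.
#' @export
neuron_weights <- function(grads) {
  d <- dim(grads)
  if (is.null(d) || length(d) != 3 || prod(d) == 0)
    stop("grads must be a non-empty H x W x K array")
  apply(grads, 3, mean)
}

#' Compute a class activation map
#'
#' Runs the image through the model, takes the gradient of the target class
#' score with respect to the last convolutional feature map, pools the
#' gradients into channel weights, and forms
#' `ReLU(sum_k alpha_k A_k)`.
#'
#' @param model a `glnb` model.
#' @param input `H x W x 3` model input array (see [to_model_input()]) or a
#'   [thermal_image()].
#' @param class target class index (1 = stressed, 2 = control); `NULL` uses
#'   the predicted class.
#' @param score_kind `"pre_softmax"` (the input of the softmax layer, the
#'   default) or `"post_softmax"`.
#' @return an object of class `class_activation_map`: list with `raw`
#'   (non-negative spatial grid), `alpha`, `grads`, `activations`, `Z`,
#'   `class`, `score`, `probs`.
#' @export
compute_cam <- function(model, input, class = NULL,
                        score_kind = c("pre_softmax", "post_softmax")) {
  score_kind <- match.arg(score_kind)
  if (inherits(input, "thermal_image"))
    input <- encode_input(input, model$config)
  x <- stack_inputs(list(input))
  fwd <- glnb_forward(model, x)
  nc <- model$config$n_classes
  probs <- softmax(fwd$scores)
  if (is.null(class)) class <- which.max(probs[, 1])
  if (class < 1 || class > nc) stop("class index out of range")
  dscores <- matrix(0, nc, 1)
  if (score_kind == "pre_softmax") {
    dscores[class, 1] <- 1
  } else {
    # d p_c / d s_j = p_c (delta_cj - p_j)
    p <- probs[, 1]
    dscores[, 1] <- p[class] * ((seq_len(nc) == class) - p)
  }
  bwd <- glnb_backward(model, fwd, dscores, stop_before = fwd$last_conv_idx)
  # the activation entering the bilinear layer is the last conv feature map;
  # recover it from the bilinear cache (stored feature matrix)
  bl <- fwd$caches[[fwd$last_conv_idx + 1L]]
  d <- bl$din
  acts <- array(array(bl$Fs[, , 1], c(bl$S, bl$C)), c(d[1], d[2], d[3]))
  grads <- array(bwd$dinput[, , , 1], c(d[1], d[2], d[3]))
  alpha <- neuron_weights(grads)
  wsum <- array(0, c(d[1], d[2]))
  for (k in seq_len(d[3])) wsum <- wsum + alpha[k] * acts[, , k]
  raw <- pmax(wsum, 0)
  structure(list(raw = raw, alpha = alpha, grads = grads, activations = acts,
                 Z = d[1] * d[2], class = class,
                 score = fwd$scores[class, 1], probs = probs[, 1]),
            class = "class_activation_map")
}

#' @export
print.class_activation_map <- function(x, ...) {
  cat(sprintf("<class_activation_map %dx%d, class %d, score %.3f, max %.4g>\n",
              nrow(x$raw), ncol(x$raw), x$class, x$score, max(x$raw)))
  invisible(x)
}

#' Upsample a class activation map to image resolution
#'
#' Corner-aligned bilinear interpolation followed by max-normalization to
#' `[0, 1]`; an identically-zero raw map stays identically zero.
#'
#' @param cam a `class_activation_map` or a non-negative matrix.
#' @param target_shape `(rows, cols)`, at least the raw map's shape.
#' @return matrix in `[0, 1]` of size `target_shape`.
#' @export
upsample_cam <- function(cam, target_shape) {
  raw <- if (inherits(cam, "class_activation_map")) cam$raw else as.matrix(cam)
  if (target_shape[1] < nrow(raw) || target_shape[2] < ncol(raw))
    stop("target smaller than the raw map")
  up <- resize_bilinear(raw, target_shape[1], target_shape[2])
  up <- pmax(up, 0)
  mx <- max(up)
  if (mx > 0) up <- up / mx
  up
}

#' Write a heatmap as a CSV matrix and an 8-bit grayscale PNG
#'
#' @param heatmap matrix in `[0, 1]`.
#' @param path_csv CSV output path (one value per cell).
#' @param path_png optional PNG path (requires the `png` package).
#' @return invisibly, the CSV path.
#' @export
write_heatmap <- function(heatmap, path_csv, path_png = NULL) {
  utils::write.table(heatmap, path_csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(path_png)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the 'png' package is required for PNG output")
    png::writePNG(clamp(heatmap, 0, 1), path_png)
  }
  invisible(path_csv)
}
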