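# GLNB: a GoogLeNet-style Inception stack with a bilinear-pooling head.
#
# The full configuration mirrors the canonical nine-module Inception-v1
# channel schedule (scaled by a width factor so CPU training is tractable);
# reduced-depth configurations are used for tests and desk-scale experiments.
# The classifier head is: bilinear pooling of the last convolutional feature
# map (signed square root + L2 normalization) followed by a single fully
# connected layer.

# canonical Inception-v1 channel schedule: b1, b2_reduce, b2, b3_reduce, b3, b4
INCEPTION_SCHEDULE <- list(
  c(64, 96, 128, 16, 32, 32),      # 3a
  c(128, 128, 192, 32, 96, 64),    # 3b
  c(192, 96, 208, 16, 48, 64),     # 4a
  c(160, 112, 224, 24, 64, 64),    # 4b
  c(128, 128, 256, 24, 64, 64),    # 4c
  c(112, 144, 288, 32, 64, 64),    # 4d
  c(256, 160, 320, 32, 128, 128),  # 4e
  c(256, 160, 320, 32, 128, 128),  # 5a
  c(384, 192, 384, 48, 128, 128))  # 5b

#' Inception module channel specification
#'
#' @param b1 1x1 branch output channels.
#' @param b2_reduce,b2 1x1 reduction then 3x3 branch channels.
#' @param b3_reduce,b3 1x1 reduction then 5x5 branch channels.
#' @param b4 pool-projection 1x1 channels.
#' @return a list with class `inception_spec`; total output channels are
#'   `b1 + b2 + b3 + b4`.
#' @export
inception_spec <- function(b1, b2_reduce, b2, b3_reduce, b3, b4) {
  v <- c(b1, b2_reduce, b2, b3_reduce, b3, b4)
  if (any(v < 1)) stop("all branch channel counts must be positive")
  structure(list(b1 = b1, b2_reduce = b2_reduce, b2 = b2,
                 b3_reduce = b3_reduce, b3 = b3, b4 = b4),
            class = "inception_spec")
}

scaled_schedule <- function(width_factor, n_modules) {
  lapply(INCEPTION_SCHEDULE[seq_len(n_modules)], function(v) {
    w <- pmax(1, round(v * width_factor))
    inception_spec(w[1], w[2], w[3], w[4], w[5], w[6])
  })
}

#' GLNB model configuration
#'
#' @param input_size `(H, W)` of the 3-channel model input.
#' @param n_modules number of Inception modules (default 9, the full stack;
#'   reduced depths >= 1 are supported for desk-scale work).
#' @param width_factor multiplier on the canonical channel schedule.
#' @param modules optional explicit list of [inception_spec()]s overriding
#'   the scaled schedule.
#' @param stem_channels `(conv1, conv2_reduce, conv2)` stem widths before
#'   scaling by `width_factor`.
#' @param stem_kernel kernel size of the first stem convolution (stride 2).
#'   7 is the canonical choice; a smaller kernel shrinks the network's
#'   receptive field, which keeps class activation maps tight around the
#'   evidence (useful for localization models).
#' @param stem_pool2 keep the second stem max-pool (input downsampled 8x
#'   before the Inception stack); drop it (4x) for higher-resolution class
#'   activation maps.
#' @param pool_after indices of Inception modules followed by a stride-2
#'   max-pool (the canonical stack pools after modules 2 and 7).
#' @param signed_sqrt,l2 bilinear-head normalization flags.
#' @param n_classes number of output classes (2: stressed vs control).
#' @param encoding temperature-to-channel encoding the model is trained and
#'   evaluated with (see [to_model_input()]). `"anomaly"` (default) encodes
#'   elevation above the plot's median temperature on an absolute span, so
#'   the class evidence for a stressed plot sits on the hot area itself and
#'   Grad-CAM localizes the leak; `"fixed_range"` keeps the raw absolute
#'   scale; `"minmax_gray"` is scale-free per image (usable for
#'   classification, but a hotspot then manifests mostly as suppressed
#'   background texture, which defeats localization).
#' @param enc_range temperature window (degC), see [to_model_input()].
#' @return an object of class `glnb_config`.
#' @export
glnb_config <- function(input_size = c(96, 96), n_modules = 9,
                        width_factor = 0.25, modules = NULL,
                        stem_channels = c(64, 64, 192), stem_kernel = 7,
                        stem_pool2 = TRUE,
                        pool_after = c(2, 7), signed_sqrt = TRUE, l2 = TRUE,
                        n_classes = 2,
                        encoding = c("anomaly", "fixed_range", "minmax_gray"),
                        enc_range = c(0, 10)) {
  encoding <- match.arg(encoding)
  if (n_modules < 1) stop("at least one Inception module is required")
  modules <- modules %||% scaled_schedule(width_factor, n_modules)
  if (length(modules) != n_modules)
    stop("modules list length must equal n_modules")
  pool_after <- pool_after[pool_after < n_modules]
  stem <- pmax(1, round(stem_channels * width_factor))
  structure(list(input_size = input_size, n_modules = n_modules,
                 width_factor = width_factor, modules = modules,
                 stem_channels = stem, stem_kernel = stem_kernel,
                 stem_pool2 = stem_pool2,
                 pool_after = pool_after, signed_sqrt = signed_sqrt, l2 = l2,
                 n_classes = n_classes, encoding = encoding,
                 enc_range = enc_range),
            class = "glnb_config")
}

#' Configuration hash
#'
#' Stable 32-bit hash of the architecture (used to check checkpoint
#' compatibility). The backbone hash ignores the classifier head size so
#' transfer across head configurations remains possible.
#'
#' @param config a [glnb_config()].
#' @param backbone hash only the backbone-defining fields.
#' @return hex string.
#' @export
config_hash <- function(config, backbone = FALSE) {
  f <- unclass(config)
  if (backbone) f$n_classes <- NULL
  key <- paste(vapply(rapply(f, as.character, how = "unlist"),
                      identity, character(1)), collapse = "|")
  sprintf("%08x", fnv1a32(utf8ToInt(key)))
}

#' Build a GLNB model with randomly initialized parameters
#'
#' @param config a [glnb_config()].
#' @param seed integer seed for the (He-normal) initialization.
#' @return an object of class `glnb`: layer list plus config.
#' @export
build_glnb <- function(config, seed = 1) {
  with_seed(seed, {
    st <- config$stem_channels
    layers <- list(
      list(name = "stem_conv1",
           l = layer_conv(3, st[1], config$stem_kernel, stride = 2,
                          pad = (config$stem_kernel - 1) %/% 2)),
      list(name = "stem_relu1", l = layer_relu()),
      list(name = "stem_pool1", l = layer_maxpool(3, 2, 1)),
      list(name = "stem_conv2r", l = layer_conv(st[1], st[2], 1)),
      list(name = "stem_relu2r", l = layer_relu()),
      list(name = "stem_conv2", l = layer_conv(st[2], st[3], 3)),
      list(name = "stem_relu2", l = layer_relu()))
    if (config$stem_pool2)
      layers <- c(layers, list(list(name = "stem_pool2", l = layer_maxpool(3, 2, 1))))
    cin <- st[3]
    for (i in seq_len(config$n_modules)) {
      li <- layer_inception(cin, config$modules[[i]])
      layers <- c(layers, list(list(name = sprintf("inception_%d", i), l = li)))
      cin <- li$cout
      if (i %in% config$pool_after)
        layers <- c(layers, list(list(name = sprintf("pool_%d", i),
                                      l = layer_maxpool(3, 2, 1))))
    }
    layers <- c(layers, list(list(
      name = "bilinear", l = layer_bilinear(config$signed_sqrt, config$l2))))
    layers <- c(layers, list(list(
      name = "fc", l = layer_linear(cin^2, config$n_classes, init_sd = 0.01))))
    structure(list(layers = layers, config = config, last_conv = cin),
              class = "glnb")
  })
}

#' @export
print.glnb <- function(x, ...) {
  cat(sprintf("<glnb: %d Inception modules, %d classes, %s params, hash %s>\n",
              x$config$n_modules, x$config$n_classes,
              format(glnb_n_params(x), big.mark = ","), config_hash(x$config)))
  invisible(x)
}

#' Total trainable parameter count
#'
#' @param model a `glnb` model.
#' @return integer parameter count.
#' @export
glnb_n_params <- function(model) {
  n <- 0
  for (ly in model$layers) n <- n + count_params(ly$l$params)
  n
}

# Forward pass through all layers; keeps per-layer caches when `train` or
# when gradients wrt activations will be requested.
glnb_forward <- function(model, x, keep_cache = TRUE) {
  caches <- vector("list", length(model$layers))
  a <- x
  last_conv_idx <- NA_integer_
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]$l
    r <- switch(ly$type,
      conv = conv_forward(ly, a),
      relu = relu_forward(a),
      maxpool = maxpool_forward(ly, a),
      inception = inception_forward(ly, a),
      bilinear = { last_conv_idx <- i - 1L; bilinear_forward(ly, a) },
      linear = linear_forward(ly, a))
    a <- r$out
    if (keep_cache) caches[[i]] <- r$cache
  }
  list(scores = a, caches = caches, last_conv_idx = last_conv_idx)
}

# Full backward pass from score gradients; returns per-layer grads and
# optionally stops early, returning d(score)/d(activation) at layer `stop_at`.
glnb_backward <- function(model, fwd, dscores, stop_before = 0L) {
  grads <- vector("list", length(model$layers))
  da <- dscores
  for (i in rev(seq_along(model$layers))) {
    if (i <= stop_before) break
    ly <- model$layers[[i]]$l
    cache <- fwd$caches[[i]]
    r <- switch(ly$type,
      conv = conv_backward(ly, da, cache),
      relu = list(dx = relu_backward(da, cache), grads = NULL),
      maxpool = list(dx = maxpool_backward(ly, da, cache), grads = NULL),
      inception = inception_backward(ly, da, cache),
      bilinear = list(dx = bilinear_backward(ly, da, cache), grads = NULL),
      linear = linear_backward(ly, da, cache))
    da <- r$dx
    grads[i] <- list(r$grads)
  }
  list(grads = grads, dinput = da)
}

# Stack a list of HxWx3 arrays into an (H, W, 3, N) batch.
stack_inputs <- function(inputs) {
  d <- dim(inputs[[1]])
  x <- array(0, c(d[1], d[2], d[3], length(inputs)))
  for (i in seq_along(inputs)) x[, , , i] <- inputs[[i]]
  x
}

#' Classify images with a GLNB model
#'
#' @param model a `glnb` model.
#' @param inputs list of `H x W x 3` arrays (see [to_model_input()]), a single
#'   such array, or a `thermal_dataset` (encoded with `minmax_gray`).
#' @param batch_size inference batch size.
#' @return list with `scores` (n_classes x N, pre-softmax), `probs`
#'   (columns sum to 1) and `class` (integer, 1 = stressed/experimental,
#'   2 = control).
#' @export
predict_glnb <- function(model, inputs, batch_size = 16) {
  inputs <- as_input_list(inputs, model$config)
  H <- model$config$input_size[1]; W <- model$config$input_size[2]
  nc <- model$config$n_classes
  scores <- matrix(0, nc, length(inputs))
  for (start in seq(1, length(inputs), by = batch_size)) {
    idx <- start:min(start + batch_size - 1, length(inputs))
    x <- stack_inputs(inputs[idx])
    if (dim(x)[1] != H || dim(x)[2] != W)
      stop(sprintf("input is %dx%d but model expects %dx%d",
                   dim(x)[1], dim(x)[2], H, W))
    fwd <- glnb_forward(model, x, keep_cache = FALSE)
    scores[, idx] <- fwd$scores
  }
  probs <- softmax(scores)
  list(scores = scores, probs = probs, class = apply(probs, 2, which.max))
}

as_input_list <- function(inputs, config = NULL) {
  if (inherits(inputs, "thermal_image")) inputs <- list(encode_input(inputs, config))
  if (inherits(inputs, "thermal_dataset"))
    return(lapply(inputs$images, encode_input, config = config))
  if (is.array(inputs) && length(dim(inputs)) == 3) return(list(inputs))
  inputs
}

# encode a thermal image with the model's configured encoding
encode_input <- function(img, config = NULL) {
  if (!inherits(img, "thermal_image")) return(img)
  if (is.null(config)) return(to_model_input(img))
  to_model_input(img, mode = config$encoding, range = config$enc_range)
}

#' Save / load a GLNB checkpoint
#'
#' A checkpoint is a single RDS file holding the configuration, its hash and
#' all parameters.
#'
#' @param model a `glnb` model.
#' @param path file path.
#' @return `path` invisibly for save; the restored `glnb` for load.
#' @export
save_glnb <- function(model, path) {
  params <- lapply(model$layers, function(ly) ly$l$params)
  saveRDS(list(config = unclass(model$config), hash = config_hash(model$config),
               params = params), path)
  invisible(path)
}

#' @rdname save_glnb
#' @export
load_glnb <- function(path) {
  ck <- readRDS(path)
  config <- ck$config
  config$modules <- lapply(config$modules, function(m)
    do.call(inception_spec, m[c("b1", "b2_reduce", "b2", "b3_reduce", "b3", "b4")]))
  config <- structure(config, class = "glnb_config")
  if (!identical(config_hash(config), ck$hash))
    stop("checkpoint hash mismatch")
  model <- build_glnb(config, seed = 1)
  for (i in seq_along(model$layers)) model$layers[[i]]$l$params <- ck$params[[i]]
  model
}

#' Closed-form parameter count for a configuration
#'
#' Computed from the channel arithmetic alone (conv `k^2*cin*cout + cout`,
#' linear `din*dout + dout`), independent of the built model; used as an
#' architecture self-check.
#'
#' @param config a [glnb_config()].
#' @return integer parameter count.
#' @export
glnb_expected_params <- function(config) {
  conv_p <- function(k, cin, cout) k * k * cin * cout + cout
  st <- config$stem_channels
  n <- conv_p(config$stem_kernel %||% 7, 3, st[1]) +
    conv_p(1, st[1], st[2]) + conv_p(3, st[2], st[3])
  cin <- st[3]
  for (m in config$modules) {
    n <- n + conv_p(1, cin, m$b1) + conv_p(1, cin, m$b2_reduce) +
      conv_p(3, m$b2_reduce, m$b2) + conv_p(1, cin, m$b3_reduce) +
      conv_p(5, m$b3_reduce, m$b3) + conv_p(1, cin, m$b4)
    cin <- m$b1 + m$b2 + m$b3 + m$b4
  }
  n + cin^2 * config$n_classes + config$n_classes
}
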