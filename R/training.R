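# Optimization of GLNB models: minibatch Adam on cross-entropy, seeded and
# fully reproducible, plus the pretrain-then-transfer workflow.

#' Training configuration
#'
#' Defaults follow the study's stated hyperparameters: Adam with learning
#' rate 1e-4 and cross-entropy loss (epochs are scaled to the task at hand;
#' the field-scale runs used 200).
#'
#' @param learning_rate Adam step size (> 0).
#' @param optimizer only `"adam"` is implemented.
#' @param epochs number of epochs (>= 0).
#' @param batch_size minibatch size.
#' @param seed seed controlling shuffling (and any head re-initialization).
#' @param freeze_backbone train only the fully connected head.
#' @param fine_tune_epochs with `freeze_backbone = FALSE` on a transferred
#'   model, number of initial head-only warm-up epochs before all layers
#'   update at `0.1 * learning_rate`.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, optimizer = "adam",
                         epochs = 200, batch_size = 16, seed = 1,
                         freeze_backbone = FALSE, fine_tune_epochs = 20) {
  stopifnot(learning_rate > 0, epochs >= 0, batch_size >= 1)
  optimizer <- match.arg(optimizer, "adam")
  structure(list(learning_rate = learning_rate, optimizer = optimizer,
                 epochs = epochs, batch_size = batch_size, seed = seed,
                 freeze_backbone = freeze_backbone,
                 fine_tune_epochs = fine_tune_epochs),
            class = "train_config")
}

# labels as integers 1..n_classes: 1 = experimental (stressed), 2 = control
label_int <- function(labels, n_classes) {
  y <- as.integer(factor(as.character(labels), levels = CONDITION_LEVELS))
  if (anyNA(y) || any(y > n_classes)) stop("label out of range")
  y
}

dataset_inputs <- function(ds, config = NULL)
  lapply(ds$images, encode_input, config = config)

# mean loss/accuracy of a model over inputs (list) and integer labels
eval_model <- function(model, inputs, y, batch_size = 16) {
  pr <- predict_glnb(model, inputs, batch_size = batch_size)
  idx <- cbind(y, seq_along(y))
  list(loss = -mean(log(pmax(pr$probs[idx], 1e-12))),
       acc = mean(pr$class == y))
}

#' Train a GLNB model
#'
#' Minibatch Adam on softmax cross-entropy. The history records one row per
#' epoch (train and validation loss/accuracy); the parameters of the best
#' validation-accuracy epoch are retained alongside the final ones. Fully
#' reproducible for a fixed `config$seed`.
#'
#' @param model a `glnb` model (see [build_glnb()], [transfer_glnb()]).
#' @param train_set,val_set `thermal_dataset`s (validation optional).
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list with `model` (final parameters), `best_model` (best
#'   validation accuracy; the final model when no validation set is given)
#'   and `history` (data frame: epoch, train_loss, train_acc, val_loss,
#'   val_acc).
#' @export
train_glnb <- function(model, train_set, val_set = NULL,
                       config = train_config(), verbose = FALSE) {
  if (!length(train_set$images)) stop("empty training set")
  nc <- model$config$n_classes
  y <- label_int(train_set$labels, nc)
  inputs <- dataset_inputs(train_set, model$config)
  vinputs <- if (!is.null(val_set)) dataset_inputs(val_set, model$config)
  vy <- if (!is.null(val_set)) label_int(val_set$labels, nc)

  frozen <- isTRUE(config$freeze_backbone) ||
    identical(attr(model, "transfer_mode"), "frozen")
  transferred <- isTRUE(attr(model, "transferred"))
  fc_idx <- length(model$layers)          # the fully connected head
  states <- lapply(model$layers, function(ly)
    if (length(ly$l$params)) adam_state(ly$l$params) else NULL)

  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), val_loss = numeric(0),
                     val_acc = numeric(0))
  best <- list(acc = -Inf, params = NULL)
  n <- length(inputs)

  for (epoch in seq_len(config$epochs)) {
    # schedule: frozen => head only; transferred fine-tune => head-only
    # warm-up, then all layers at a reduced rate
    head_only <- frozen || (transferred && epoch <= config$fine_tune_epochs)
    lr <- if (transferred && !frozen && epoch > config$fine_tune_epochs)
      0.1 * config$learning_rate else config$learning_rate
    ord <- with_seed(derive_seed(config$seed, paste("epoch", epoch)),
                     sample.int(n))
    tl <- 0; tc <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      x <- stack_inputs(inputs[idx])
      fwd <- glnb_forward(model, x)
      ls <- softmax_xent(fwd$scores, y[idx])
      bwd <- glnb_backward(model, fwd, ls$dscores,
                           stop_before = if (head_only) fwd$last_conv_idx else 0L)
      for (i in seq_along(model$layers)) {
        g <- bwd$grads[[i]]
        if (is.null(g) || is.null(states[[i]])) next
        if (head_only && i != fc_idx) next
        st <- adam_step(model$layers[[i]]$l$params, g, states[[i]], lr)
        model$layers[[i]]$l$params <- st$params
        states[[i]] <- st$state
      }
      tl <- tl + ls$loss * length(idx)
      tc <- tc + sum(apply(ls$probs, 2, which.max) == y[idx])
    }
    ev <- if (!is.null(val_set))
      eval_model(model, vinputs, vy, config$batch_size)
    else list(loss = NA_real_, acc = NA_real_)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tl / n,
                                   train_acc = tc / n, val_loss = ev$loss,
                                   val_acc = ev$acc))
    if (!is.null(val_set) && ev$acc > best$acc)
      best <- list(acc = ev$acc,
                   params = lapply(model$layers, function(ly) ly$l$params))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.3f  val_acc %.3f",
                      epoch, tl / n, tc / n, ev$acc))
  }
  best_model <- model
  if (!is.null(best$params))
    for (i in seq_along(best_model$layers))
      best_model$layers[[i]]$l$params <- best$params[[i]]
  list(model = model, best_model = best_model, history = hist)
}

#' Initialize a model from pretrained parameters (transfer learning)
#'
#' Copies every backbone parameter from `source` exactly and re-initializes
#' the fully connected head, so that a small target dataset suffices to
#' retrain the classifier. With `mode = "frozen"` subsequent training updates
#' the head only; with `mode = "finetune"` training warms up the head for
#' `fine_tune_epochs` and then updates all layers at a reduced rate (see
#' [train_glnb()]).
#'
#' @param model a freshly built `glnb` (target architecture).
#' @param source a trained `glnb` (or checkpoint path) with an identical
#'   backbone configuration.
#' @param mode `"frozen"` or `"finetune"`.
#' @param seed seed for the head re-initialization.
#' @return the initialized `glnb`; `attr(-, "transfer_mode")` records the mode.
#' @export
transfer_glnb <- function(model, source, mode = c("finetune", "frozen"),
                          seed = 1) {
  mode <- match.arg(mode)
  if (is.character(source)) source <- load_glnb(source)
  if (!identical(config_hash(model$config, backbone = TRUE),
                 config_hash(source$config, backbone = TRUE)))
    stop("incompatible architecture: backbone config hashes differ")
  fc_idx <- length(model$layers)
  for (i in seq_len(fc_idx - 1))
    model$layers[[i]]$l$params <- source$layers[[i]]$l$params
  ly <- model$layers[[fc_idx]]$l
  model$layers[[fc_idx]]$l <- with_seed(derive_seed(seed, "transfer-head"),
                                        layer_linear(ly$din, ly$dout,
                                                     init_sd = 0.01))
  attr(model, "transferred") <- TRUE
  attr(model, "transfer_mode") <- mode
  model
}

#' Stratified train/validation split
#'
#' Splits a dataset with per-stratum (species x condition) proportions, seeded.
#'
#' @param ds a `thermal_dataset`.
#' @param val_fraction fraction held out for validation.
#' @param seed integer seed.
#' @return `list(train = , val = )` of `thermal_dataset`s.
#' @export
split_dataset <- function(ds, val_fraction = 0.25, seed = 1) {
  strata <- paste(ds$species, ds$labels)
  val_idx <- with_seed(derive_seed(seed, "split"), {
    unlist(lapply(split(seq_along(strata), strata), function(ii) {
      nv <- max(1, round(length(ii) * val_fraction))
      sample(ii, nv)
    }), use.names = FALSE)
  })
  list(train = subset_dataset(ds, setdiff(seq_along(ds$images), val_idx)),
       val = subset_dataset(ds, sort(val_idx)))
}

#' Subset a dataset by scene index
#'
#' @param ds a `thermal_dataset`.
#' @param idx integer indices.
#' @return a `thermal_dataset`.
#' @export
subset_dataset <- function(ds, idx) {
  structure(list(images = ds$images[idx], labels = ds$labels[idx],
                 species = ds$species[idx],
                 truths = if (!is.null(ds$truths)) ds$truths[idx]),
            class = "thermal_dataset")
}

#' First epoch reaching a validation-accuracy criterion
#'
#' @param history a history data frame from [train_glnb()].
#' @param criterion accuracy threshold in `[0, 1]`.
#' @return the first epoch with `val_acc >= criterion`, or `Inf`.
#' @export
epochs_to_criterion <- function(history, criterion = 0.95) {
  hit <- which(history$val_acc >= criterion)
  if (!length(hit)) Inf else history$epoch[hit[1]]
}

#' Write a training history to CSV
#'
#' @param history history data frame.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
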