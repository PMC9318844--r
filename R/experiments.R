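# Desk-scale reference experiments: named model presets and the seeded
# end-to-end studies (localization parameter recovery, transfer-learning
# convergence) that the test suite and the acceptance script both run.
# Problem sizes are chosen so each study completes in minutes on one CPU
# while keeping the statistical structure of the field study.

#' Named GLNB configurations
#'
#' * `"full"` - the nine-module stack at the canonical channel schedule
#'   (width factor 0.25), 96 x 96 input.
#' * `"reduced"` - three Inception modules at width 1/8; the desk-scale
#'   classification model used throughout the tests.
#' * `"localizer"` - two Inception modules, small stem kernel, no
#'   downsampling after the stem pool (feature maps at 1/4 resolution) and a
#'   plain bilinear head (no signed square root, no L2). The compact
#'   receptive field and unnormalized head keep the class activation map
#'   proportional to the local anomaly evidence, which is what circle
#'   fitting needs; see the package vignette.
#'
#' @param preset preset name.
#' @param input_size `(H, W)` of the model input.
#' @param ... overrides passed on to [glnb_config()].
#' @return a [glnb_config()].
#' @export
glnb_preset <- function(preset = c("reduced", "localizer", "full"),
                        input_size = c(96, 96), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    full = list(n_modules = 9, width_factor = 0.25),
    reduced = list(n_modules = 3, width_factor = 1 / 8),
    localizer = list(n_modules = 2, width_factor = 1 / 8, stem_kernel = 3,
                     stem_pool2 = FALSE, pool_after = integer(0),
                     signed_sqrt = FALSE, l2 = FALSE))
  args$input_size <- input_size
  do.call(glnb_config, utils::modifyList(args, list(...)))
}

#' Train the desk-scale leak localizer
#'
#' Generates a seeded grass-scene training set (stress radii spanning
#' `radius_range`), trains the `"localizer"` preset and returns the best
#' validation model.
#'
#' @param seed integer seed (controls data, initialization and shuffling).
#' @param n_per_cell training scenes per condition.
#' @param epochs training epochs.
#' @param radius_range truth stress radius bounds, px.
#' @param shape scene shape.
#' @param verbose print progress.
#' @return list with `model`, `history`, `dataset`.
#' @export
train_localizer <- function(seed = 1, n_per_cell = 40, epochs = 30,
                            radius_range = c(10, 40), shape = c(96, 96),
                            verbose = FALSE) {
  ds <- generate_dataset(n_per_cell, species = "grass", shape = shape,
                         seed = derive_seed(seed, "loc-data"),
                         radius_range = radius_range)
  sp <- split_dataset(ds, 0.15, seed = derive_seed(seed, "loc-split"))
  model <- build_glnb(glnb_preset("localizer", input_size = shape),
                      seed = derive_seed(seed, "loc-init"))
  fit <- train_glnb(model, sp$train, sp$val,
                    train_config(learning_rate = 3e-3, epochs = epochs,
                                 batch_size = 16,
                                 seed = derive_seed(seed, "loc-train")),
                    verbose = verbose)
  list(model = fit$best_model, history = fit$history, dataset = ds)
}

#' Localization parameter-recovery study
#'
#' Renders `n_scenes` fresh stressed scenes with truth radii drawn uniformly
#' from `radius_range`, runs the full detection chain (classify, Grad-CAM,
#' Otsu segmentation, circle fit) with a trained localizer, and scores each
#' correctly classified scene: center error within `center_tol` times the
#' truth radius and radius error within `radius_tol` (relative).
#'
#' @param model a trained localizer (see [train_localizer()]); built
#'   internally when `NULL`.
#' @param seed integer seed for the evaluation scenes.
#' @param n_scenes number of scenes.
#' @param radius_range truth radius bounds, px.
#' @param center_tol,radius_tol scoring tolerances.
#' @param shape scene shape.
#' @return list with `results` (per-scene data frame), `n_classified`,
#'   `recovery_rate` (fraction of correctly classified scenes passing both
#'   tolerances), `center_rate`, `radius_rate`, `median_center_err_px`.
#' @export
experiment_localization <- function(model = NULL, seed = 1, n_scenes = 50,
                                    radius_range = c(10, 40),
                                    center_tol = 0.15, radius_tol = 0.20,
                                    shape = c(96, 96)) {
  if (is.null(model)) model <- train_localizer(seed)$model
  rows <- list()
  for (i in seq_len(n_scenes)) {
    s <- derive_seed(seed, paste("eval-scene", i))
    truth <- with_seed(s, {
      radius <- stats::runif(1, radius_range[1], radius_range[2])
      sigma <- radius / sqrt(2 * log(0.6 / STRESS_CONCENTRATION))
      margin <- min(radius + 5, (min(shape) - 1) / 2)
      ctr <- c(stats::runif(1, 1 + margin, shape[1] - margin),
               stats::runif(1, 1 + margin, shape[2] - margin))
      scene_truth(ctr, sigma, peak_concentration = 0.6, coupling_slope = 10,
                  background_mean = 27.53, background_sd = 0.67,
                  sensor_sd = 0.1, species = "grass")
    })
    sc <- render_scene(shape, truth, seed = derive_seed(s, "render"))
    det <- detect_leak(model, sc$image)
    radius <- stress_radius(truth)
    row <- data.frame(scene = i, truth_radius = radius,
                      truth_r = truth$leak_center[1],
                      truth_c = truth$leak_center[2],
                      classified = det$predicted == 1L,
                      est_radius = NA_real_, center_err = NA_real_,
                      center_ok = NA, radius_ok = NA)
    if (det$predicted == 1L && !is.null(det$circle)) {
      ce <- sqrt(sum((det$circle$center - truth$leak_center)^2))
      row$est_radius <- det$circle$radius
      row$center_err <- ce
      row$center_ok <- ce <= center_tol * radius
      row$radius_ok <- abs(det$circle$radius - radius) / radius <= radius_tol
    }
    rows[[i]] <- row
  }
  res <- do.call(rbind, rows)
  # a correctly classified scene with no fittable circle counts as a miss
  scored <- res[res$classified, ]
  ok <- function(v) sum(v, na.rm = TRUE) / nrow(scored)
  list(results = res,
       n_classified = nrow(scored),
       recovery_rate = ok(scored$center_ok & scored$radius_ok),
       center_rate = ok(scored$center_ok),
       radius_rate = ok(scored$radius_ok),
       median_center_err_px = stats::median(scored$center_err, na.rm = TRUE))
}

#' Transfer-learning convergence study
#'
#' For each of `n_seeds` seeds, trains the `"reduced"` classifier on a small
#' grass-scene target task twice -- from scratch and transfer-initialized
#' from a model pretrained on a larger multi-species corpus (fresh texture
#' seeds) -- and records the first epoch at which validation accuracy
#' reaches `criterion`.
#'
#' @param seed base seed.
#' @param n_seeds number of paired runs.
#' @param criterion validation-accuracy criterion in `[0, 1]`.
#' @param pretrain_n,pretrain_epochs corpus size per cell and epochs for the
#'   shared pretraining run.
#' @param target_n scenes per condition in each target task.
#' @param max_epochs epoch budget for target runs.
#' @param shape scene shape.
#' @param verbose print progress.
#' @return list with `table` (data frame: seed, epochs_scratch,
#'   epochs_transfer), `n_transfer_faster`, and `source_model`.
#' @export
experiment_transfer <- function(seed = 1, n_seeds = 3, criterion = 0.95,
                                pretrain_n = 8, pretrain_epochs = 25,
                                target_n = 16, max_epochs = 15,
                                shape = c(96, 96), verbose = FALSE) {
  cfg <- glnb_preset("reduced", input_size = shape)
  corpus <- generate_dataset(pretrain_n, shape = shape,
                             seed = derive_seed(seed, "pretrain-data"))
  csp <- split_dataset(corpus, 0.2, seed = derive_seed(seed, "pretrain-split"))
  source <- build_glnb(cfg, seed = derive_seed(seed, "pretrain-init"))
  pre <- train_glnb(source, csp$train, csp$val,
                    train_config(learning_rate = 3e-3,
                                 epochs = pretrain_epochs, batch_size = 16,
                                 seed = derive_seed(seed, "pretrain")),
                    verbose = verbose)
  rows <- list()
  for (k in seq_len(n_seeds)) {
    sk <- derive_seed(seed, paste("target", k))
    target <- generate_dataset(target_n, species = "grass", shape = shape,
                               seed = derive_seed(sk, "data"))
    tsp <- split_dataset(target, 0.5, seed = derive_seed(sk, "split"))
    tc <- train_config(learning_rate = 3e-3, epochs = max_epochs,
                       batch_size = 16, seed = derive_seed(sk, "train"),
                       fine_tune_epochs = 5)
    scratch <- build_glnb(cfg, seed = derive_seed(sk, "scratch-init"))
    fs <- train_glnb(scratch, tsp$train, tsp$val, tc, verbose = verbose)
    warm <- transfer_glnb(build_glnb(cfg, seed = derive_seed(sk, "warm-init")),
                          pre$best_model, mode = "finetune",
                          seed = derive_seed(sk, "head"))
    ft <- train_glnb(warm, tsp$train, tsp$val, tc, verbose = verbose)
    rows[[k]] <- data.frame(
      seed = k,
      epochs_scratch = epochs_to_criterion(fs$history, criterion),
      epochs_transfer = epochs_to_criterion(ft$history, criterion))
  }
  tab <- do.call(rbind, rows)
  list(table = tab,
       n_transfer_faster = sum(tab$epochs_transfer < tab$epochs_scratch),
       source_model = pre$best_model)
}
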