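# Run configuration and the high-level pipeline stages behind the command
# line entry point (simulate / train / detect / evaluate / profile). Every
# stage derives its seeds from the single global seed plus a stage tag and
# writes only into the configured output directory, alongside a manifest
# recording the config hash, seed and produced files.

RUN_CONFIG_KEYS <- c("data_dir", "out_dir", "seed", "simulator", "augment",
                     "model", "train", "localize")

#' Load and validate a run configuration
#'
#' The configuration is a single YAML (or JSON) key/value tree with the
#' top-level keys `data_dir`, `out_dir`, `seed` and optional `simulator`,
#' `augment`, `model`, `train`, `localize` sections whose entries override
#' the corresponding constructor defaults ([generate_dataset()],
#' [augment_plan()], [glnb_config()], [train_config()], [fit_circle()]).
#' Unknown keys are rejected with their key path.
#'
#' @param path YAML/JSON file, or a named list already in memory.
#' @return validated configuration list of class `run_config`.
#' @export
load_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  bad <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(bad)) stop("invalid config key(s): ", paste(bad, collapse = ", "))
  sections <- list(simulator = names(formals(generate_dataset)),
                   augment = names(formals(augment_plan)),
                   model = names(formals(glnb_config)),
                   train = names(formals(train_config)),
                   localize = c("min_circularity", "min_boundary"))
  for (sec in names(sections)) {
    extra <- setdiff(names(cfg[[sec]]), sections[[sec]])
    if (length(extra))
      stop("invalid config key(s): ", paste(paste0(sec, ".", extra), collapse = ", "))
  }
  cfg$seed <- as.integer(cfg$seed %||% 1)
  cfg$out_dir <- cfg$out_dir %||% "."
  structure(cfg, class = "run_config")
}

write_manifest <- function(cfg, stage, files) {
  jsonlite::write_json(
    list(stage = stage, seed = cfg$seed,
         config_hash = sprintf("%08x", fnv1a32(utf8ToInt(
           paste(utils::capture.output(utils::str(unclass(cfg))), collapse = "\n")))),
         files = files),
    file.path(cfg$out_dir, paste0("manifest_", stage, ".json")),
    auto_unbox = TRUE, digits = NA)
}

#' Pipeline stage: simulate a dataset
#'
#' @param cfg a `run_config` (see [load_run_config()]).
#' @return the dataset directory, invisibly.
#' @export
run_simulate <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  args <- cfg$simulator %||% list()
  args$seed <- derive_seed(cfg$seed, "simulate")
  args$dir <- file.path(cfg$out_dir, "scenes")
  if (is.null(args$n_per_cell)) args$n_per_cell <- 8
  if (!is.null(args$shape)) args$shape <- as.numeric(args$shape)
  ds <- do.call(generate_dataset, args)
  write_manifest(cfg, "simulate",
                 list.files(args$dir))
  message(sprintf("simulate: wrote %d scenes to %s", length(ds$images), args$dir))
  invisible(args$dir)
}

#' Pipeline stage: train a model
#'
#' Trains on the scenes under `data_dir` (stratified split) and writes the
#' best checkpoint plus the per-epoch history CSV.
#'
#' @param cfg a `run_config`.
#' @param pretrained optional source checkpoint for transfer learning.
#' @return path of the written checkpoint, invisibly.
#' @export
run_train <- function(cfg, pretrained = NULL) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- read_dataset(cfg$data_dir)
  shp <- dim(ds$images[[1]]$values)
  margs <- cfg$model %||% list()
  if (is.null(margs$input_size)) margs$input_size <- shp
  mcfg <- do.call(glnb_config, margs)
  model <- build_glnb(mcfg, seed = derive_seed(cfg$seed, "init"))
  if (!is.null(pretrained))
    model <- transfer_glnb(model, pretrained,
                           seed = derive_seed(cfg$seed, "transfer"))
  targs <- cfg$train %||% list()
  targs$seed <- derive_seed(cfg$seed, "train")
  tcfg <- do.call(train_config, targs)
  sp <- split_dataset(ds, seed = derive_seed(cfg$seed, "split"))
  fit <- train_glnb(model, sp$train, sp$val, tcfg)
  ck <- file.path(cfg$out_dir, "glnb_checkpoint.rds")
  save_glnb(fit$best_model, ck)
  write_history(fit$history, file.path(cfg$out_dir, "history.csv"))
  write_manifest(cfg, "train", c("glnb_checkpoint.rds", "history.csv"))
  invisible(ck)
}

#' Pipeline stage: detect leaks on every scene
#'
#' Runs classification + Grad-CAM localization over the scenes in
#' `data_dir`; one JSON result per image (circle emitted only for stressed
#' predictions) and a summary CSV.
#'
#' @param cfg a `run_config`.
#' @param checkpoint model checkpoint path (default: the one in `out_dir`).
#' @return the summary data frame, invisibly.
#' @export
run_detect <- function(cfg, checkpoint = file.path(cfg$out_dir,
                                                   "glnb_checkpoint.rds")) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- load_glnb(checkpoint)
  ds <- read_dataset(cfg$data_dir)
  det_dir <- file.path(cfg$out_dir, "detections")
  dir.create(det_dir, showWarnings = FALSE)
  rows <- list()
  for (i in seq_along(ds$images)) {
    det <- detect_leak(model, ds$images[[i]],
                       min_circularity = cfg$localize$min_circularity %||% 0.4)
    res <- list(index = i, species = ds$species[i],
                predicted = CONDITION_LEVELS[det$predicted])
    if (!is.null(det$circle)) {
      px <- ds$images[[i]]$meta$pixel_size
      res$circle <- list(center = det$circle$center,
                         radius_px = det$circle$radius,
                         fit_rms = det$circle$fit_rms,
                         circularity = det$circle$circularity)
      if (!is.null(px)) res$circle$radius_m <- det$circle$radius * px
    }
    jsonlite::write_json(res, file.path(det_dir, sprintf("det_%03d.json", i)),
                         auto_unbox = TRUE, digits = NA)
    rows[[i]] <- data.frame(
      index = i, species = ds$species[i], label = as.character(ds$labels[i]),
      predicted = CONDITION_LEVELS[det$predicted],
      radius_px = if (!is.null(det$circle)) det$circle$radius else NA_real_)
  }
  summary <- do.call(rbind, rows)
  utils::write.csv(summary, file.path(cfg$out_dir, "detections.csv"),
                   row.names = FALSE)
  write_manifest(cfg, "detect", c("detections.csv", list.files(det_dir)))
  invisible(summary)
}

#' Pipeline stage: evaluate a model per species
#'
#' @param cfg a `run_config`.
#' @param checkpoint model checkpoint path.
#' @return the evaluation list, invisibly.
#' @export
run_evaluate <- function(cfg, checkpoint = file.path(cfg$out_dir,
                                                     "glnb_checkpoint.rds")) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- load_glnb(checkpoint)
  ds <- read_dataset(cfg$data_dir)
  ev <- evaluate_by_species(model, ds)
  jsonlite::write_json(ev, file.path(cfg$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(format_metrics_report(ev$per_species, ev$average),
             file.path(cfg$out_dir, "metrics.txt"))
  write_manifest(cfg, "evaluate", c("metrics.json", "metrics.txt"))
  invisible(ev)
}

#' Pipeline stage: temperature profile report
#'
#' @param cfg a `run_config`.
#' @return the statistics table, invisibly.
#' @export
run_profile <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- read_dataset(cfg$data_dir)
  tab <- dataset_profile_table(ds)
  utils::write.csv(tab, file.path(cfg$out_dir, "profile_stats.csv"),
                   row.names = FALSE)
  ctr <- stress_contrasts(tab)
  jsonlite::write_json(ctr, file.path(cfg$out_dir, "contrasts.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_manifest(cfg, "profile", c("profile_stats.csv", "contrasts.json"))
  invisible(tab)
}
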