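#' Pipeline run configuration
#'
#' Bundles the per-stage configurations of the simulate -> split -> train ->
#' predict -> assess -> evaluate pipeline with one global seed. Each stage
#' derives its own seed from the global seed and the stage name, so stages
#' are independently reproducible.
#'
#' @param sim Named list of [sim_config()] overrides.
#' @param net Named list of [net_config()] overrides.
#' @param train Named list of [train_config()] overrides.
#' @param test_n_patients Whole patients held out for the test set.
#' @param metrics Named list: `aggregation_mode`, `narrowed_mm2`,
#'   `severe_rule`, `strut_tol_px`, `min_strut_pixels`.
#' @param out_dir Output directory for all stages.
#' @param seed Global integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = list(), net = list(), train = list(),
                       test_n_patients = 2L, metrics = list(),
                       out_dir = "ivusseg_run", seed = 1L) {
  mdef <- list(aggregation_mode = "pooled", narrowed_mm2 = 4.0,
               severe_rule = "quadrants", strut_tol_px = 5,
               min_strut_pixels = 3L)
  mdef[names(metrics)] <- metrics
  if (mdef$narrowed_mm2 <= 0 || mdef$strut_tol_px <= 0)
    stop("validation error at metrics: thresholds must be positive", call. = FALSE)
  cfg <- structure(list(
    sim = do.call(sim_config, sim),
    net = do.call(net_config, net),
    train = do.call(train_config, train),
    test_n_patients = as.integer(test_n_patients),
    metrics = mdef,
    out_dir = out_dir,
    seed = as.integer(seed)
  ), class = "run_config")
  if (cfg$net$input_size != cfg$sim$image_size)
    stop("validation error at net.input_size: must equal sim.image_size",
         call. = FALSE)
  cfg
}

#' Load a pipeline configuration from YAML or JSON
#'
#' The file holds any subset of the [run_config()] fields (`sim`, `net`,
#' `train`, `test_n_patients`, `metrics`, `out_dir`, `seed`); missing
#' entries keep their defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path))
    stop("missing config file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("config must be YAML or JSON, got .", ext, call. = FALSE))
  do.call(run_config, raw)
}

# deterministic per-stage seed fan-out (kept below 2^31)
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483629 + 1)
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, force = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

write_stage_manifest <- function(cfg, stage, extra = list()) {
  obj <- c(list(stage = stage,
                config_hash = config_hash(cfg),
                seed = cfg$seed, stage_seed = stage_seed(cfg$seed, stage),
                package_version = as.character(utils::packageVersion("ivusseg")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
           extra)
  jsonlite::write_json(obj, file.path(cfg$out_dir, paste0("run_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(obj)
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path))
    stop("missing upstream artifact ", path, " (run ", produced_by, " first)",
         call. = FALSE)
  path
}

#' Simulate stage: phantom dataset on disk
#'
#' @param cfg A `run_config`.
#' @return Invisibly, the dataset manifest data frame.
#' @export
cmd_simulate <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- cfg$sim
  sim$rng_seed <- stage_seed(cfg$seed, "simulate")
  ds <- generate_dataset(sim, file.path(cfg$out_dir, "dataset"))
  write_stage_manifest(cfg, "simulate",
                       list(n_frames = nrow(ds$manifest),
                            n_patients = length(unique(ds$manifest$patient_id)),
                            calc_fraction = mean(ds$manifest$has_calcification),
                            stent_fraction = mean(ds$manifest$has_stent)))
  invisible(ds$manifest)
}

load_manifest <- function(cfg) {
  mpath <- require_artifact(file.path(cfg$out_dir, "dataset", "manifest.csv"),
                            "cmd_simulate")
  read.csv(mpath, stringsAsFactors = FALSE)
}

load_pair <- function(cfg, row) {
  base <- file.path(cfg$out_dir, "dataset")
  list(frame = read_frame(file.path(base, row$frame_path)),
       mask = read_mask(file.path(base, row$mask_path), cfg$sim$pixel_spacing))
}

#' Train stage: patient-level split + U-Net fit
#'
#' Splits patients (test held out whole, validation frames drawn from
#' training patients), trains the network, and writes the checkpoint,
#' training history CSV and split JSON.
#'
#' @param cfg A `run_config`.
#' @param verbose Print per-epoch losses.
#' @return Invisibly, the trained model.
#' @export
cmd_train <- function(cfg, verbose = FALSE) {
  manifest <- load_manifest(cfg)
  set.seed(stage_seed(cfg$seed, "split"))
  split <- make_split(manifest, cfg$test_n_patients,
                      cfg$train$validation_fraction)
  jsonlite::write_json(split[c("train_patients", "test_patients",
                               "train_idx", "validation_idx", "test_idx")],
                       file.path(cfg$out_dir, "split.json"), auto_unbox = FALSE)
  load_rows <- function(idx) {
    pairs <- lapply(idx, function(i) load_pair(cfg, manifest[i, ]))
    list(frames = lapply(pairs, `[[`, "frame"),
         masks = lapply(pairs, `[[`, "mask"))
  }
  tr <- load_rows(split$train_idx)
  va <- load_rows(split$validation_idx)
  set.seed(stage_seed(cfg$seed, "train"))
  model <- build_unet(cfg$net)
  model <- train_unet(model, tr$frames, tr$masks, cfg$train,
                      va$frames, va$masks, verbose = verbose)
  saveRDS(model, file.path(cfg$out_dir, "checkpoint.rds"))
  write.csv(model$history, file.path(cfg$out_dir, "history.csv"),
            row.names = FALSE)
  write_stage_manifest(cfg, "train",
                       list(n_train = length(split$train_idx),
                            n_validation = length(split$validation_idx),
                            n_test = length(split$test_idx),
                            best_epoch = model$best_epoch))
  invisible(model)
}

#' Predict stage: segment the held-out test frames
#'
#' @param cfg A `run_config`.
#' @return Invisibly, the list of predicted masks.
#' @export
cmd_predict <- function(cfg) {
  manifest <- load_manifest(cfg)
  model <- readRDS(require_artifact(file.path(cfg$out_dir, "checkpoint.rds"),
                                    "cmd_train"))
  split <- jsonlite::read_json(require_artifact(
    file.path(cfg$out_dir, "split.json"), "cmd_train"), simplifyVector = TRUE)
  pdir <- file.path(cfg$out_dir, "predictions")
  dir.create(pdir, showWarnings = FALSE)
  preds <- vector("list", length(split$test_idx))
  for (k in seq_along(split$test_idx)) {
    row <- manifest[split$test_idx[k], ]
    fr <- read_frame(file.path(cfg$out_dir, "dataset", row$frame_path))
    pr <- predict(model, fr, pixel_spacing = cfg$sim$pixel_spacing)
    preds[[k]] <- pr$mask
    write_mask(pr$mask, file.path(pdir, basename(row$mask_path)))
  }
  write_stage_manifest(cfg, "predict", list(n_predicted = length(preds)))
  invisible(preds)
}

pipeline_test_masks <- function(cfg) {
  manifest <- load_manifest(cfg)
  split <- jsonlite::read_json(require_artifact(
    file.path(cfg$out_dir, "split.json"), "cmd_train"), simplifyVector = TRUE)
  rows <- manifest[split$test_idx, ]
  truth <- lapply(seq_len(nrow(rows)), function(i)
    read_mask(file.path(cfg$out_dir, "dataset", rows$mask_path[i]),
              cfg$sim$pixel_spacing))
  pred <- lapply(seq_len(nrow(rows)), function(i)
    read_mask(require_artifact(
      file.path(cfg$out_dir, "predictions", basename(rows$mask_path[i])),
      "cmd_predict"), cfg$sim$pixel_spacing))
  list(rows = rows, truth = truth, pred = pred)
}

#' Assess stage: per-frame clinical report of the test predictions
#'
#' @param cfg A `run_config`.
#' @return Invisibly, the clinical report data frame (also written as CSV).
#' @export
cmd_assess <- function(cfg) {
  tm <- pipeline_test_masks(cfg)
  rep <- clinical_report(tm$truth, tm$pred,
                         frame_ids = paste0(tm$rows$patient_id, "_",
                                            tm$rows$frame_index),
                         tol_px = cfg$metrics$strut_tol_px,
                         narrowed_mm2 = cfg$metrics$narrowed_mm2,
                         rule = cfg$metrics$severe_rule,
                         min_strut_pixels = cfg$metrics$min_strut_pixels,
                         center_fallback = TRUE)
  write.csv(rep, file.path(cfg$out_dir, "clinical_report.csv"), row.names = FALSE)
  write_stage_manifest(cfg, "assess", list(n_frames = nrow(rep)))
  invisible(rep)
}

#' Evaluate stage: full metric report of the test predictions
#'
#' Computes per-class and mean IoU/Dice in the configured aggregation mode,
#' image-level classification metrics for the narrowed-lumen and
#' severe-calcification rules, the Spearman correlation of predicted vs
#' true lumen areas, and the mean strut recall over frames whose truth
#' contains a stent.
#'
#' @param cfg A `run_config`.
#' @param pred_masks Optional list of masks standing in for the stored
#'   predictions (used, e.g., to evaluate ground truth against itself).
#' @return Invisibly, the evaluation list (also written as JSON + CSV).
#' @export
cmd_evaluate <- function(cfg, pred_masks = NULL) {
  tm <- pipeline_test_masks_or(cfg, pred_masks)
  seg <- aggregate_metrics(tm$pred, tm$truth, cfg$metrics$aggregation_mode)
  narrowed_rule <- function(m)
    classify_narrowed(lumen_area(m), cfg$metrics$narrowed_mm2)
  severe_rule <- function(m)
    calcification_arc(m, rule = cfg$metrics$severe_rule,
                      center_fallback = TRUE)$severe_calc
  cls_narrow <- image_level_classification(tm$truth, tm$pred, narrowed_rule)
  cls_severe <- image_level_classification(tm$truth, tm$pred, severe_rule)
  ta <- vapply(tm$truth, lumen_area, numeric(1))
  pa <- vapply(tm$pred, lumen_area, numeric(1))
  # degenerate predictions (e.g. a barely trained net segmenting no lumen)
  # make the rank correlation undefined; report NA rather than fail the stage
  corr <- tryCatch(lumen_area_correlation(ta, pa), error = function(e)
    list(rho = NA_real_, r_squared = NA_real_, p_value = NA_real_,
         n = length(ta), note = conditionMessage(e)))
  stent_i <- which(vapply(tm$truth, function(m) any(m$labels == 4L), logical(1)))
  strut_rec <- if (length(stent_i)) {
    mean(vapply(stent_i, function(i) {
      strut_recall(extract_struts(tm$pred[[i]], cfg$metrics$min_strut_pixels),
                   extract_struts(tm$truth[[i]], cfg$metrics$min_strut_pixels),
                   cfg$metrics$strut_tol_px)
    }, numeric(1)))
  } else NA_real_
  out <- list(segmentation = list(
                aggregation_mode = seg$aggregation_mode,
                per_class = seg$per_class,
                mean_iou = seg$mean_iou, mean_dice = seg$mean_dice),
              narrowed_classification = cls_narrow[c("accuracy", "recall", "precision")],
              severe_calc_classification = cls_severe[c("accuracy", "recall", "precision")],
              lumen_area_correlation = corr,
              strut_recall = strut_rec,
              n_test_frames = length(tm$truth),
              n_stent_frames = length(stent_i))
  jsonlite::write_json(out, file.path(cfg$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write_metrics_report(seg, csv_path = file.path(cfg$out_dir, "metrics_per_class.csv"))
  write_stage_manifest(cfg, "evaluate", list(mean_iou = seg$mean_iou))
  invisible(out)
}

pipeline_test_masks_or <- function(cfg, pred_masks) {
  if (is.null(pred_masks)) return(pipeline_test_masks(cfg))
  manifest <- load_manifest(cfg)
  split <- jsonlite::read_json(require_artifact(
    file.path(cfg$out_dir, "split.json"), "cmd_train"), simplifyVector = TRUE)
  rows <- manifest[split$test_idx, ]
  truth <- lapply(seq_len(nrow(rows)), function(i)
    read_mask(file.path(cfg$out_dir, "dataset", rows$mask_path[i]),
              cfg$sim$pixel_spacing))
  if (length(pred_masks) != length(truth))
    stop("argument error: pred_masks count differs from test frames", call. = FALSE)
  list(rows = rows, truth = truth, pred = pred_masks)
}

#' Run the whole pipeline
#'
#' simulate -> train (with split) -> predict -> assess -> evaluate, all
#' under the global seed of `cfg`.
#'
#' @param cfg A `run_config`.
#' @param verbose Print training progress.
#' @return Invisibly, the evaluation list of [cmd_evaluate()].
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  cmd_simulate(cfg)
  cmd_train(cfg, verbose = verbose)
  cmd_predict(cfg)
  cmd_assess(cfg)
  invisible(cmd_evaluate(cfg))
}
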