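# End-to-end orchestration: generate -> preprocess -> augment -> train ->
# evaluate -> predict, each stage writing its artifacts and a completion
# marker into a run directory.

#' Pipeline run configuration
#'
#' Nested configuration for [run_pipeline()]; round-trips through YAML
#' unchanged.  The `tiny` preset is the desk-scale profile used throughout
#' the package's tests: 1/8-width model on 64 x 64 phantoms with 200/50/50
#' train/validation/test images generated directly (no augmentation at this
#' scale), a learning rate of 3e-3 suited to the narrow model's short
#' schedule, and a background-prior initialization of the output bias.
#'
#' @param out Run directory.
#' @param seed Master seed; stage seeds are derived from it.
#' @param tiny Use the desk-scale profile (default `TRUE`; the full-width
#'   profile matches the published setup but is not CPU-practical).
#' @param overrides Named list merged over the preset (nested lists merge
#'   recursively).
#' @export
run_config <- function(out = "csn_run", seed = 42L, tiny = TRUE,
                       overrides = list()) {
  base <- if (tiny) list(
    data = list(size = 64L, n_train = 200L, n_val = 50L, n_test = 50L,
                augment = FALSE, train_fraction = 0.8),
    clahe = list(clip_limit = 2, tile_grid = c(8L, 8L)),
    model = list(input_size = 64L, width_multiplier = 1 / 8),
    train = list(learning_rate = 3e-3, batch_size = 4L, max_epochs = 12L,
                 patience = 20L, output_bias_init = -2),
    threshold = 0.5
  ) else list(
    data = list(size = 256L, n_train = 90L, n_val = NULL, n_test = 17L,
                augment = TRUE, train_fraction = 0.8),
    clahe = list(clip_limit = 2, tile_grid = c(8L, 8L)),
    model = list(input_size = 256L, width_multiplier = 1),
    train = list(learning_rate = 1e-4, batch_size = 4L, max_epochs = 200L,
                 patience = 20L, output_bias_init = 0),
    threshold = 0.5
  )
  merge_lists <- function(a, b) {
    for (k in names(b))
      a[[k]] <- if (is.list(a[[k]]) && is.list(b[[k]]))
        merge_lists(a[[k]], b[[k]]) else b[[k]]
    a
  }
  cfg <- merge_lists(base, overrides)
  cfg$out <- out
  cfg$seed <- as.integer(seed)
  cfg$tiny <- tiny
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    csn_dependency_error(sprintf("config '%s' not found", path))
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

stage_marker <- function(out, stage) file.path(out, stage, ".done")

require_stage <- function(out, stage) {
  if (!file.exists(stage_marker(out, stage)))
    csn_dependency_error(sprintf(
      "stage '%s' has not completed in '%s'; run it first", stage, out))
}

mark_done <- function(out, stage) {
  writeLines(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
             stage_marker(out, stage))
}

tagged_dataset <- function(cfg, which, n, seed_offset) {
  spec <- phantom_spec(size = cfg$data$size)
  generate_dataset(n, cfg$seed + seed_offset, spec,
                   dir = file.path(cfg$out, "raw", which), split = which,
                   dataset_tag = "phantom")
}

load_split <- function(out, stage, split) {
  man <- read_manifest(file.path(out, stage, split, "manifest.csv"))
  load_samples(man)
}

#' Run the segmentation pipeline
#'
#' Executes the requested stages in dependency order inside `cfg$out`:
#' `generate` (phantom image/mask pairs + manifests), `preprocess` (CLAHE on
#' every split, applied identically to train/validation/test), `augment`
#' (eight-fold rotation/flip of the training pool and the seed-deterministic
#' train/validation split; skipped by the tiny profile, which generates the
#' splits directly), `train`, `evaluate` (metrics JSON + normalized
#' confusion CSV on the untouched test split) and `predict` (binary masks +
#' overlays for the test images).  Stages are idempotent: re-running with an
#' unchanged config rewrites byte-identical artifacts.
#'
#' @param cfg A [run_config()].
#' @param stages Character subset of
#'   `c("generate", "preprocess", "augment", "train", "evaluate", "predict")`.
#' @return Invisibly, the run directory.
#' @export
run_pipeline <- function(cfg = run_config(),
                         stages = c("generate", "preprocess", "augment",
                                    "train", "evaluate", "predict")) {
  all_stages <- c("generate", "preprocess", "augment", "train", "evaluate",
                  "predict")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  out <- cfg$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  if ("generate" %in% stages) {
    if (isTRUE(cfg$data$augment)) {
      tagged_dataset(cfg, "trainval", cfg$data$n_train, 0L)
    } else {
      tagged_dataset(cfg, "train", cfg$data$n_train, 0L)
      tagged_dataset(cfg, "val", cfg$data$n_val, cfg$data$n_train)
    }
    tagged_dataset(cfg, "test", cfg$data$n_test,
                   cfg$data$n_train + (cfg$data$n_val %||% 0L))
    dir.create(file.path(out, "generate"), showWarnings = FALSE)
    mark_done(out, "generate")
  }

  if ("preprocess" %in% stages) {
    require_stage(out, "generate")
    params <- clahe_params(cfg$clahe$clip_limit, unlist(cfg$clahe$tile_grid))
    for (split in list.dirs(file.path(out, "raw"), recursive = FALSE)) {
      man <- read_manifest(file.path(split, "manifest.csv"))
      dst <- file.path(out, "preprocess", basename(split))
      dir.create(dst, recursive = TRUE, showWarnings = FALSE)
      for (i in seq_len(nrow(man))) {
        img <- apply_clahe(read_gray_image(man$image_path[i]), params)
        write_gray_png(img, file.path(dst, basename(man$image_path[i])))
        file.copy(man$mask_path[i],
                  file.path(dst, basename(man$mask_path[i])),
                  overwrite = TRUE)
      }
      local_man <- utils::read.csv(file.path(split, "manifest.csv"),
                                   stringsAsFactors = FALSE)
      utils::write.csv(local_man, file.path(dst, "manifest.csv"),
                       row.names = FALSE)
    }
    mark_done(out, "preprocess")
  }

  if ("augment" %in% stages) {
    require_stage(out, "preprocess")
    dir.create(file.path(out, "augment"), showWarnings = FALSE)
    if (isTRUE(cfg$data$augment)) {
      man <- read_manifest(file.path(out, "preprocess", "trainval",
                                     "manifest.csv"))
      pool <- load_samples(man)
      aug <- unlist(lapply(pool, augment_eightfold), recursive = FALSE)
      sp <- split_train_val(aug, split_spec(cfg$data$train_fraction, cfg$seed))
      for (split in c("train", "val")) {
        items <- if (split == "train") sp$train else sp$validation
        dst <- file.path(out, "augment", split)
        dir.create(dst, recursive = TRUE, showWarnings = FALSE)
        rows <- lapply(seq_along(items), function(i) {
          s <- items[[i]]
          ip <- sprintf("image_%05d.png", i)
          mp <- sprintf("mask_%05d.png", i)
          write_gray_png(s$image, file.path(dst, ip))
          write_gray_png(s$mask, file.path(dst, mp))
          data.frame(image_path = ip, mask_path = mp, split = split,
                     dataset_tag = s$dataset_tag %||% "phantom",
                     source_id = s$source_id %||% NA_character_,
                     variant_rotation = s$variant_rotation,
                     variant_flipped = s$variant_flipped,
                     stringsAsFactors = FALSE)
        })
        utils::write.csv(do.call(rbind, rows),
                         file.path(dst, "manifest.csv"), row.names = FALSE)
      }
    }
    mark_done(out, "augment")
  }

  if ("train" %in% stages) {
    require_stage(out, "augment")
    src_stage <- if (isTRUE(cfg$data$augment)) "augment" else "preprocess"
    train_samples <- load_split(out, src_stage, "train")
    val_samples <- load_split(out, src_stage, "val")
    model <- build_architecture(model_config(
      input_size = cfg$model$input_size,
      width_multiplier = cfg$model$width_multiplier, seed = cfg$seed))
    model$nodes$out$units[[1]]$b <- cfg$train$output_bias_init %||% 0
    tc <- train_config(learning_rate = cfg$train$learning_rate,
                       batch_size = cfg$train$batch_size,
                       max_epochs = cfg$train$max_epochs,
                       patience = cfg$train$patience, seed = cfg$seed,
                       threshold = cfg$threshold)
    dir.create(file.path(out, "train"), showWarnings = FALSE)
    res <- train_segnet(model, train_samples, val_samples, tc,
                        checkpoint_path = file.path(out, "train",
                                                    "checkpoint.rds"))
    utils::write.csv(res$history, file.path(out, "train", "history.csv"),
                     row.names = FALSE)
    write_run_config(cfg, file.path(out, "train", "config.yaml"))
    mark_done(out, "train")
  }

  if ("evaluate" %in% stages) {
    require_stage(out, "train")
    model <- load_checkpoint(file.path(out, "train", "checkpoint.rds"))
    test_samples <- load_split(out, "preprocess", "test")
    ev <- evaluate_segnet(model, test_samples, threshold = cfg$threshold)
    dir.create(file.path(out, "evaluate"), showWarnings = FALSE)
    write_metrics_json(ev$aggregate,
                       file.path(out, "evaluate", "metrics.json"))
    utils::write.csv(as.data.frame(ev$normalized_confusion),
                     file.path(out, "evaluate", "confusion.csv"))
    utils::write.csv(ev$per_sample,
                     file.path(out, "evaluate", "per_sample.csv"),
                     row.names = FALSE)
    mark_done(out, "evaluate")
  }

  if ("predict" %in% stages) {
    require_stage(out, "train")
    man <- read_manifest(file.path(out, "preprocess", "test",
                                   "manifest.csv"))
    predict_masks(file.path(out, "train", "checkpoint.rds"),
                  man$image_path, file.path(out, "predict"),
                  threshold = cfg$threshold)
    mark_done(out, "predict")
  }

  invisible(out)
}

#' Predict binary masks (and overlays) for images
#'
#' Loads a checkpoint, runs inference on each image, thresholds to a strict
#' {0, 1} mask and writes `pred_<name>.png` plus an RGB overlay
#' `overlay_<name>.png` with the predicted boundary in red.
#'
#' @param checkpoint Path to a [save_checkpoint()] file.
#' @param image_paths Character vector of grayscale image files sized to
#'   the model input.
#' @param out_dir Output directory.
#' @param threshold Binarization threshold.
#' @return Invisibly, data frame of input and output paths.
#' @export
predict_masks <- function(checkpoint, image_paths, out_dir, threshold = 0.5) {
  model <- load_checkpoint(checkpoint)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sz <- model$config$input_size
  rows <- lapply(image_paths, function(pth) {
    img <- read_gray_image(pth)
    if (!identical(dim(img), c(sz, sz)))
      csn_error(sprintf("image '%s' is %dx%d; model expects %dx%d",
                        pth, nrow(img), ncol(img), sz, sz),
                "csn_shape_error")
    pred <- segnet_forward(model, img)$pred[, , 1, 1]
    mask <- binarize_prediction(pred, threshold)
    mp <- file.path(out_dir, paste0("pred_", basename(pth)))
    write_gray_png(mask, mp)
    op <- file.path(out_dir, paste0("overlay_", basename(pth)))
    write_overlay_png(img, mask, op)
    data.frame(image = pth, mask = mp, overlay = op,
               stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, rows))
}

# red boundary of `mask` drawn over the grayscale image; the boundary is
# the mask minus its 4-neighbour erosion
write_overlay_png <- function(img, mask, path) {
  n <- nrow(mask); m <- ncol(mask)
  up <- rbind(mask[-1, , drop = FALSE], mask[n, , drop = FALSE])
  dn <- rbind(mask[1, , drop = FALSE], mask[-n, , drop = FALSE])
  lf <- cbind(mask[, -1, drop = FALSE], mask[, m, drop = FALSE])
  rt <- cbind(mask[, 1, drop = FALSE], mask[, -m, drop = FALSE])
  edge <- mask == 1 & (mask * up * dn * lf * rt) == 0
  rgb <- array(rep(pmin(pmax(img, 0), 1), 3), c(dim(img), 3))
  rgb[, , 1][edge] <- 1
  rgb[, , 2][edge] <- 0
  rgb[, , 3][edge] <- 0
  png::writePNG(aperm(rgb, c(2, 1, 3)), target = path)
  invisible(path)
}
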