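# End-to-end pipeline: phantom synthesis -> preprocessing -> patching ->
# feature fusion -> (optional swarm tuning) -> progressive cyclical
# training -> evaluation, with a reproducible run record.

#' Default run configuration
#'
#' Nested list mirroring the pipeline stages. Every stage reads only its
#' own subtree plus the master `seed`; the study defaults are 256x256
#' phantoms, 64x64 non-overlapping patches, fused deep + handcrafted
#' features, a 70-30 image-level train/test split with a 80/20
#' train/validation carve-out, and 50 epochs of batch-32 training with
#' cyclical learning rates in [1e-5, 1e-3] and dropout 0.3.
#'
#' @param seed Master seed.
#' @return Named list of stage configurations.
#' @export
default_run_config <- function(seed = 0) {
  list(
    seed = as.integer(seed),
    synth = list(n_images = 200L, malignant_fraction = 0.5,
                 height = 256L, width = 256L, intensity_gain = 1.6),
    preprocess = list(target_size = c(256L, 256L), clahe_clip_limit = 2,
                      clahe_tile_grid = c(8L, 8L)),
    patch = list(patch_height = 64L, patch_width = 64L,
                 step_vertical = 64L, step_horizontal = 64L,
                 threshold = 0.5),
    features = list(deep = TRUE, handcrafted = TRUE, backbone_seed = 0L,
                    backbone_filters = c(4L, 8L),
                    lbp_convention = "center_minus_neighbor"),
    split = list(train_fraction = 0.7, val_fraction = 0.2),
    train = list(total_epochs = 50L, batch_size = 32L, dropout_rate = 0.3,
                 lr_min = 1e-5, lr_max = 1e-3, hidden = c(32L, 16L),
                 n_stages = NULL),
    tune = list(enabled = FALSE, swarm_size = 8L, generations = 5L,
                proxy_epochs = 5L),
    evaluate = list(threshold = 0.5, calibration_bins = 10L))
}

#' Read and validate a YAML run configuration
#'
#' Values from the file override the defaults; unknown keys raise an error
#' (a guard against silently misspelled hyperparameters).
#'
#' @param path YAML file.
#' @param seed Fallback master seed when the file sets none.
#' @return A validated config list.
#' @export
read_run_config <- function(path, seed = 0) {
  user <- yaml::read_yaml(path)
  merge_checked(default_run_config(seed), user, prefix = "")
}

merge_checked <- function(base, user, prefix) {
  if (!is.list(user)) return(user)
  for (key in names(user)) {
    full <- paste0(prefix, key)
    if (!key %in% names(base)) {
      stop("unknown config key: ", full, call. = FALSE)
    }
    base[[key]] <- if (is.list(base[[key]]) && is.list(user[[key]])) {
      merge_checked(base[[key]], user[[key]], paste0(full, "."))
    } else {
      user[[key]]
    }
  }
  base
}

stage_cache_path <- function(out_dir, stage) {
  file.path(out_dir, paste0(stage, ".json"))
}

cache_valid <- function(out_dir, stage, hash, artifact) {
  meta_path <- stage_cache_path(out_dir, paste0(stage, "_meta"))
  if (!file.exists(meta_path) || !file.exists(artifact)) return(FALSE)
  meta <- jsonlite::read_json(meta_path)
  identical(meta$hash, hash)
}

write_stage_meta <- function(out_dir, stage, hash) {
  jsonlite::write_json(list(stage = stage, hash = hash),
                       stage_cache_path(out_dir, paste0(stage, "_meta")),
                       auto_unbox = TRUE)
}

#' Run the full pipeline
#'
#' Executes synth -> preprocess -> patch -> features -> (tune) -> train ->
#' evaluate under a single master seed; two runs with equal configs yield
#' byte-identical metric reports. With `out_dir` set, stage artifacts are
#' cached keyed by the hash of the stage-relevant config subtree, and
#' `resume = TRUE` reuses any cached stage whose key matches.
#'
#' @param config Config list from [default_run_config()] /
#'   [read_run_config()].
#' @param out_dir Optional output directory for artifacts, the metric
#'   report JSON and the run record.
#' @param resume Reuse matching cached stage artifacts?
#' @param verbose Print one line per stage?
#' @return List: `report` (patch-level `metric_report`), `image_report`
#'   (secondary image-level report aggregating patch scores), `history`,
#'   `tuning` (or NULL), `split_counts`, `n_patches`, `config`,
#'   `timings`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL,
                         resume = FALSE, verbose = FALSE) {
  t_all <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    t_all[[stage]] <<- proc.time()[["elapsed"]] - t0
    if (verbose) message(sprintf("[%s] %.1fs", stage, t_all[[stage]]))
    res
  }
  seeds <- derive_seeds(config$seed, 4)
  use_cache <- !is.null(out_dir)
  if (use_cache) dir.create(out_dir, recursive = TRUE,
                            showWarnings = FALSE)

  # --- synth ----------------------------------------------------------
  synth_hash <- config_hash(list(seed = config$seed, synth = config$synth))
  synth_dir <- if (use_cache) file.path(out_dir, "phantoms") else NULL
  dataset <- tick("synth", {
    manifest_path <- if (use_cache) file.path(synth_dir, "manifest.csv")
    if (resume && use_cache &&
        cache_valid(out_dir, "synth", synth_hash, manifest_path)) {
      manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
      phantoms <- lapply(seq_len(nrow(manifest)), function(i) {
        structure(list(image = read_gray_png(manifest$path[i]) * 255,
                       mask = (read_gray_png(manifest$mask_path[i]) > 0.5) * 1L,
                       label = manifest$label[i], seed = manifest$seed[i]),
                  class = "phantom")
      })
      structure(list(manifest = manifest, phantoms = phantoms),
                class = "phantom_set")
    } else {
      ds <- generate_dataset(
        config$synth$n_images, config$synth$malignant_fraction,
        height = config$synth$height, width = config$synth$width,
        seed = seeds[1], intensity_gain = config$synth$intensity_gain,
        dir = synth_dir)
      if (use_cache) write_stage_meta(out_dir, "synth", synth_hash)
      ds
    }
  })

  # --- preprocess -----------------------------------------------------
  processed <- tick("preprocess", {
    lapply(dataset$phantoms, function(ph) {
      img <- normalize_image(ph$image)
      img <- clahe_enhance(img, config$preprocess$clahe_clip_limit,
                           config$preprocess$clahe_tile_grid)
      if (!all(dim(img) == config$preprocess$target_size)) {
        img <- resize_image(img, config$preprocess$target_size)
      }
      img
    })
  })

  # --- patch ----------------------------------------------------------
  spec <- patch_grid_spec(config$patch$patch_height,
                          config$patch$patch_width,
                          config$patch$step_vertical,
                          config$patch$step_horizontal)
  patches <- tick("patch", {
    patch_dataset(dataset, spec, threshold = config$patch$threshold,
                  images = processed)
  })

  # --- features -------------------------------------------------------
  feat_hash <- config_hash(list(seed = config$seed, synth = config$synth,
                                preprocess = config$preprocess,
                                patch = config$patch,
                                features = config$features))
  feat_path <- if (use_cache) file.path(out_dir, "features.rds")
  feats <- tick("features", {
    if (resume && use_cache &&
        cache_valid(out_dir, "features", feat_hash, feat_path)) {
      cached <- readRDS(feat_path)
      list(features = cached$features, labels = cached$labels,
           records = patches$records)
    } else {
      backbone <- if (isTRUE(config$features$deep)) {
        tiny_backbone(seed = config$features$backbone_seed,
                      filters = config$features$backbone_filters,
                      input_size = c(spec$patch_height, spec$patch_width))
      }
      fe <- patch_features(patches, backbone = backbone,
                           handcrafted = isTRUE(config$features$handcrafted),
                           lbp_convention = config$features$lbp_convention)
      if (use_cache) {
        saveRDS(list(features = fe$features, labels = fe$labels),
                feat_path)
        # CSV export for downstream tools (lossy float formatting; the
        # RDS above is the cache of record)
        utils::write.csv(
          cbind(data.frame(source_id = fe$records$source_id,
                           label = fe$labels), fe$features),
          file.path(out_dir, "features.csv"), row.names = FALSE)
        jsonlite::write_json(list(columns = colnames(fe$features)),
                             file.path(out_dir, "features_columns.json"))
        write_stage_meta(out_dir, "features", feat_hash)
      }
      fe
    }
  })

  # --- split (image-level, stratified) --------------------------------
  split_info <- tick("split", {
    img_manifest <- data.frame(id = seq_along(dataset$phantoms),
                               label = dataset$manifest$label)
    sp <- split_dataset(img_manifest, config$split$train_fraction,
                        stratify = TRUE, seed = seeds[2])
    trval <- sp$train
    sp2 <- split_dataset(trval, 1 - config$split$val_fraction,
                         stratify = TRUE, seed = seeds[2] + 1L)
    list(train_ids = sp2$train$id, val_ids = sp2$test$id,
         test_ids = sp$test$id)
  })
  src <- feats$records$source_id
  idx_tr <- src %in% split_info$train_ids
  idx_va <- src %in% split_info$val_ids
  idx_te <- src %in% split_info$test_ids

  std <- fit_standardizer(feats$features[idx_tr, , drop = FALSE])
  x_tr <- apply_standardizer(feats$features[idx_tr, , drop = FALSE], std)
  x_va <- apply_standardizer(feats$features[idx_va, , drop = FALSE], std)
  x_te <- apply_standardizer(feats$features[idx_te, , drop = FALSE], std)
  y_tr <- feats$labels[idx_tr]
  y_va <- feats$labels[idx_va]
  y_te <- feats$labels[idx_te]

  # --- tune (optional) ------------------------------------------------
  tuning <- NULL
  hidden <- config$train$hidden
  plan <- train_plan(
    total_epochs = config$train$total_epochs,
    batch_size = config$train$batch_size,
    dropout_rate = config$train$dropout_rate,
    lr_spec = cyclical_lr_spec(config$train$lr_min, config$train$lr_max),
    n_stages = config$train$n_stages)
  if (isTRUE(config$tune$enabled)) {
    tuning <- tick("tune", {
      tune_train_plan(
        x_tr, y_tr, x_va, y_va,
        config = swarm_config(swarm_size = config$tune$swarm_size,
                              generations = config$tune$generations,
                              seed = seeds[3]),
        proxy_epochs = config$tune$proxy_epochs,
        total_epochs = config$train$total_epochs)
    })
    plan <- tuning$plan
    hidden <- tuning$hidden
  }

  # --- train ----------------------------------------------------------
  train_hash <- config_hash(list(seed = config$seed, synth = config$synth,
                                 preprocess = config$preprocess,
                                 patch = config$patch,
                                 features = config$features,
                                 split = config$split,
                                 train = config$train, tune = config$tune))
  model_path <- if (use_cache) file.path(out_dir, "model.rds")
  fit <- tick("train", {
    if (resume && use_cache &&
        cache_valid(out_dir, "train", train_hash, model_path)) {
      readRDS(model_path)
    } else {
      f <- train_classifier(x_tr, y_tr, plan = plan,
                            model = mlp_model(ncol(x_tr), hidden = hidden,
                                              seed = seeds[4]),
                            seed = seeds[4], x_val = x_va, y_val = y_va)
      if (use_cache) {
        saveRDS(f, model_path)
        write_stage_meta(out_dir, "train", train_hash)
      }
      f
    }
  })

  # --- evaluate -------------------------------------------------------
  reports <- tick("evaluate", {
    scores <- predict_proba(fit$model, x_te)
    list(patch = metric_report(y_te, scores,
                               threshold = config$evaluate$threshold,
                               n_bins = config$evaluate$calibration_bins),
         image = image_level_report(
           src[idx_te],
           data.frame(id = seq_along(dataset$phantoms),
                      label = dataset$manifest$label),
           scores, threshold = config$evaluate$threshold))
  })
  report <- reports$patch
  image_report <- reports$image
  if (use_cache) {
    write_metric_report(report, file.path(out_dir, "metric_report.json"))
    record <- list(config_hash = config_hash(config),
                   package_version =
                     as.character(utils::packageVersion("mammopatch")),
                   stage_seconds = t_all,
                   artifacts = list(
                     phantoms = synth_dir, features = feat_path,
                     report = file.path(out_dir, "metric_report.json")))
    tmp <- tempfile(tmpdir = out_dir)
    jsonlite::write_json(record, tmp, auto_unbox = TRUE, digits = NA)
    file.rename(tmp, file.path(out_dir, "run_record.json"))
  }
  list(report = report, image_report = image_report,
       history = fit$history, tuning = tuning,
       split_counts = vapply(split_info, length, numeric(1)),
       n_patches = nrow(feats$records), config = config,
       timings = t_all)
}
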