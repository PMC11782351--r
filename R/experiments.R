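# Figure-analog experiments: end-to-end pipelines over synthetic scenes.
#
# Each runner regenerates its inputs from a seed, executes the method
# under study, and returns a summary of plain numbers; run_experiment()
# wraps them with resolved-config and summary JSON output. Problem sizes
# default to desk scale (documented in the methods vignette).

# Scenes for training/evaluating cell-channel models: small pavement
# fields with lobe amplitudes cycling through `amplitudes`.
pavement_scene_set <- function(n, seed, size_px = 64L, n_cells = 4L,
                               amplitudes = c(0, 2, 4),
                               pixel_size_um = 0.56) {
  lapply(seq_len(n), function(i) {
    generate_scene(scene_spec(
      width_px = size_px, height_px = size_px,
      pixel_size_um = pixel_size_um, n_cells = n_cells,
      shape_model = "pavement",
      lobe_amplitude = amplitudes[(i - 1L) %% length(amplitudes) + 1L],
      seed = child_seed(seed, paste0("scene", i))))
  })
}

scene_pairs_for <- function(scenes, channel) {
  lapply(scenes, function(s) list(s$brightfield, s$channels[[channel]]))
}

# Batched forward pass over equally sized crops (shared normalization).
predict_stain_batch <- function(model, crops, batch = 64L) {
  out <- vector("list", length(crops))
  f <- 2^model$config$depth
  for (b0 in seq(1L, length(crops), by = batch)) {
    sel <- b0:min(b0 + batch - 1L, length(crops))
    h <- nrow(crops[[sel[1L]]]); w <- ncol(crops[[sel[1L]]])
    stopifnot(h %% f == 0, w %% f == 0)
    x4 <- array(0, c(h, w, length(sel), 1L))
    for (k in seq_along(sel)) {
      x4[, , k, 1L] <- normalize_percentile(crops[[sel[k]]],
                                            bounds = model$norm$input)
    }
    y <- unet_forward(model$params, x4)$y
    for (k in seq_along(sel)) out[[sel[k]]] <- matrix(y[, , k, 1L], h, w)
  }
  out
}

#' Virtual-staining colocalization experiment (TOS cross-matrix analog)
#'
#' Trains one RCA-UNet per requested channel on synthetic pavement
#' scenes, then scores the predictions on held-out scenes against every
#' truth channel with the log-rescaled TOS at the top percentile. The
#' diagonal of the resulting matrix measures staining fidelity, the
#' off-diagonal structure specificity; an untrained-weights baseline is
#' reported alongside.
#'
#' @param seed Experiment seed.
#' @param channels Channels to train models for.
#' @param n_train,n_test Scene counts.
#' @param size_px,n_cells Scene geometry.
#' @param epochs,base_channels,depth Model size/schedule.
#' @return List with `tos` (trained-channel x truth-channel matrix of
#'   mean TOS), `tos_sd`, `untrained_tos` (membrane baseline), `models`,
#'   and the held-out `test_scenes`.
#' @export
run_stain_specificity <- function(seed = 1L,
                              channels = c("membrane", "nucleus"),
                              n_train = 200L, n_test = 20L,
                              size_px = 64L, n_cells = 4L,
                              epochs = 10L, base_channels = 8L,
                              depth = 2L) {
  train_scenes <- pavement_scene_set(n_train, child_seed(seed, "train"),
                                     size_px = size_px, n_cells = n_cells)
  test_scenes <- pavement_scene_set(n_test, child_seed(seed, "test"),
                                    size_px = size_px, n_cells = n_cells)
  models <- list()
  for (ch in channels) {
    cfg <- model_config(depth = depth, base_channels = base_channels,
                        attention_reduction_r = 4L,
                        patch_size_px = size_px, epochs = epochs,
                        seed = child_seed(seed, paste0("model_", ch)))
    models[[ch]] <- train_model(build_model(cfg, channel_name = ch),
                                scene_pairs_for(train_scenes, ch))
  }
  truth_channels <- names(test_scenes[[1L]]$channels)
  tos_mat <- matrix(NA_real_, length(channels), length(truth_channels),
                    dimnames = list(channels, truth_channels))
  sd_mat <- tos_mat
  for (ch in channels) {
    preds <- lapply(test_scenes, function(s)
      predict_stain(models[[ch]], s$brightfield))
    for (tc in truth_channels) {
      b <- tos_batch(lapply(seq_along(preds), function(i)
        list(preds[[i]], test_scenes[[i]]$channels[[tc]])))
      tos_mat[ch, tc] <- b$mean
      sd_mat[ch, tc] <- b$sd
    }
  }
  cfg0 <- model_config(depth = depth, base_channels = base_channels,
                       attention_reduction_r = 4L, patch_size_px = size_px,
                       seed = child_seed(seed, "untrained"))
  m0 <- build_model(cfg0, channel_name = "membrane")
  # the zero-initialized head makes untrained predictions constant; the
  # deterministic tie-rule selection warning is expected here
  base <- suppressWarnings(tos_batch(lapply(test_scenes, function(s)
    list(predict_stain(m0, s$brightfield, allow_untrained = TRUE),
         s$channels$membrane))))
  list(tos = tos_mat, tos_sd = sd_mat,
       untrained_tos = base$mean, models = models,
       test_scenes = test_scenes)
}

# Mutual-best-overlap matching of two label images; returns matched id
# pairs with intersection-over-union above `min_iou`.
match_labels <- function(lab_a, lab_b, min_iou = 0.3) {
  va <- as.integer(lab_a); vb <- as.integer(lab_b)
  keep <- va > 0L & vb > 0L
  if (!any(keep)) return(data.frame(a = integer(0), b = integer(0)))
  ov <- table(va[keep], vb[keep])
  na <- tabulate(va[va > 0L]); nb <- tabulate(vb[vb > 0L])
  ids_a <- as.integer(rownames(ov)); ids_b <- as.integer(colnames(ov))
  best_b <- apply(ov, 1L, which.max)
  best_a <- apply(ov, 2L, which.max)
  out <- data.frame(a = integer(0), b = integer(0))
  for (r in seq_along(ids_a)) {
    cb <- best_b[r]
    if (best_a[cb] != r) next
    inter <- ov[r, cb]
    uni <- na[ids_a[r]] + nb[ids_b[cb]] - inter
    if (inter / uni >= min_iou) {
      out <- rbind(out, data.frame(a = ids_a[r], b = ids_b[cb]))
    }
  }
  out
}

#' Morphometric agreement experiment (virtual stain vs ground truth)
#'
#' On synthetic pavement scenes, cells are measured twice: from the
#' ground-truth label mask, and from a tolerance-watershed segmentation
#' of the virtually stained membrane. Matched cells (mutual best
#' overlap) are compared metric-by-metric with OLS R-squared.
#'
#' @param model A trained membrane model.
#' @param seed Experiment seed.
#' @param n_scenes Number of evaluation scenes.
#' @param size_px,n_cells,amplitudes Scene geometry (amplitudes cycle).
#' @param tolerance Watershed basin-merging tolerance on the `[0, 1]`
#'   prediction scale; the default 0.2 corresponds to 13100 on a 16-bit
#'   scale, within the range the tolerance is conventionally tuned over
#'   for membrane images.
#' @param min_area_px Minimum measured cell size.
#' @return List with `r_squared` (named: area_um2, circularity,
#'   solidity), `n_cells_matched`, and the pooled matched records.
#' @export
run_morph_analog <- function(model, seed = 1L, n_scenes = 20L,
                             size_px = 192L, n_cells = 12L,
                             amplitudes = c(0, 4, 8),
                             tolerance = 0.2, min_area_px = 60L) {
  scenes <- pavement_scene_set(n_scenes, child_seed(seed, "morph"),
                               size_px = size_px, n_cells = n_cells,
                               amplitudes = amplitudes)
  psz <- scenes[[1L]]$spec$pixel_size_um
  rec_a <- NULL; rec_b <- NULL; off <- 0L
  for (s in scenes) {
    pred <- predict_stain(model, s$brightfield)
    seg <- marker_watershed(pred, tolerance = tolerance,
                            gradient_radius_px = 0L)
    seg <- filter_labels(seg, min_area_px = min_area_px)
    truth_lab <- filter_labels(s$labels, min_area_px = min_area_px)
    mm <- match_labels(truth_lab, seg)
    if (!nrow(mm)) next
    ma <- measure_cells(truth_lab, psz)
    mb <- measure_cells(seg, psz)
    ma <- ma[match(mm$a, ma$id), ]
    mb <- mb[match(mm$b, mb$id), ]
    ok <- stats::complete.cases(ma) & stats::complete.cases(mb)
    ma <- ma[ok, ]; mb <- mb[ok, ]
    ma$id <- mb$id <- off + seq_len(nrow(ma))
    off <- off + nrow(ma)
    rec_a <- rbind(rec_a, ma); rec_b <- rbind(rec_b, mb)
  }
  if (is.null(rec_a) || nrow(rec_a) < 3L) {
    stop("too few matched cells for agreement analysis")
  }
  mets <- c("area_um2", "circularity", "solidity")
  r2 <- vapply(mets, function(m) agreement(rec_a, rec_b, m)$r_squared,
               numeric(1))
  list(r_squared = r2, n_cells_matched = nrow(rec_a),
       truth_records = rec_a, stain_records = rec_b)
}

#' Chloroplast-speed tracking experiment
#'
#' Generates a seeded chloroplast time-lapse, detects centroids per frame
#' (from the virtually stained channel if a model is given, otherwise
#' from the truth autofluorescence channel), links them into tracks, and
#' compares recovered per-interval speeds with the ground truth.
#'
#' @param seed Experiment seed.
#' @param model Optional trained chloroplast model.
#' @param n_objects,n_frames Scene size.
#' @param size_px Canvas side.
#' @param mean_um_s,sd_um_s,persistence Speed model.
#' @param pixel_size_um,dt_s Calibration (defaults 0.28 um/px, 0.5 s).
#' @param max_disp_px Linking gate.
#' @return List with `r_squared`, `n_tracks`, `tracks`, `truth`.
#' @export
run_motion_analog <- function(seed = 1L, model = NULL,
                              n_objects = 30L, n_frames = 10L,
                              size_px = 320L, mean_um_s = 2,
                              sd_um_s = 0.5, persistence = 0.8,
                              pixel_size_um = 0.28, dt_s = 0.5,
                              max_disp_px = 15) {
  spec <- scene_spec(width_px = size_px, height_px = size_px,
                     pixel_size_um = pixel_size_um, n_cells = n_objects,
                     shape_model = "chloroplast_field",
                     seed = child_seed(seed, "timelapse"))
  tl <- generate_timelapse(spec, n_frames,
                           speed_model = list(mean_um_s = mean_um_s,
                                              sd = sd_um_s,
                                              direction_persistence = persistence),
                           dt_s = dt_s)
  frames <- lapply(tl$frames, function(fr) {
    if (is.null(model)) fr$channels$chloroplast
    else predict_stain(model, fr$brightfield, tile_px = Inf)
  })
  cents <- lapply(frames, extract_centroids, min_area_px = 10L)
  tracks <- link_tracks(cents, max_disp_px = max_disp_px, dt_s = dt_s,
                        pixel_size_um = pixel_size_um)
  ag <- speed_agreement(tl, tracks)
  list(r_squared = ag$r_squared, n_tracks = length(tracks),
       n_speed_pairs = ag$n, tracks = tracks, truth = tl)
}

#' Live/dead classification experiment (texture features, two channels)
#'
#' Generates balanced living/dead crops, virtually stains them with a
#' membrane model trained on an independent crop set, extracts Haralick
#' texture features from the bright-field and the virtually stained
#' channel, and evaluates a random-forest classifier on both over
#' multiple seeds with a fixed train/test split. A label-permutation
#' null is evaluated the same way.
#'
#' @param seed Experiment seed.
#' @param n_per_class Crops per class (train + test).
#' @param n_train_per_class Training crops per class; the rest are held
#'   out.
#' @param n_stain_pairs Crop pairs used to train the staining model.
#' @param stain_epochs Staining-model epochs.
#' @param seeds Forest seeds.
#' @param n_trees Trees per forest.
#' @return List with `eval_bf`, `eval_vs` (eval_report), `p_value`
#'   (one-sided rank-sum, virtual > bright-field), `null_mean`
#'   (label-permutation accuracy), and the stain model.
#' @export
run_viability_analog <- function(seed = 1L, n_per_class = 1200L,
                                 n_train_per_class = 900L,
                                 n_stain_pairs = 200L, stain_epochs = 24L,
                                 seeds = 1:10, n_trees = 500L) {
  stopifnot(n_train_per_class < n_per_class)
  # independent crop set for the staining model
  stain_set <- generate_viability_set(ceiling(n_stain_pairs / 2),
                                      seed = child_seed(seed, "stain_crops"))
  pairs <- lapply(stain_set[seq_len(n_stain_pairs)], function(cr)
    list(cr$brightfield, cr$membrane))
  cfg <- model_config(depth = 2L, base_channels = 8L,
                      attention_reduction_r = 4L, patch_size_px = 64L,
                      epochs = stain_epochs, batch_size = 4L,
                      seed = child_seed(seed, "stain_model"))
  model <- train_model(build_model(cfg, channel_name = "membrane"), pairs)

  crops <- generate_viability_set(n_per_class,
                                  seed = child_seed(seed, "classify_crops"))
  labels <- vapply(crops, `[[`, "", "label")
  bf <- lapply(crops, `[[`, "brightfield")
  vs <- predict_stain_batch(model, bf)

  gcfg <- glcm_config()
  feat_bf <- texture_features(bf, gcfg)
  feat_vs <- texture_features(vs, gcfg)

  idx_train <- unlist(lapply(c("living", "dead"), function(cl)
    which(labels == cl)[seq_len(n_train_per_class)]))
  idx_test <- setdiff(seq_along(labels), idx_train)

  eval_bf <- evaluate_classifier(feat_bf[idx_train, ], labels[idx_train],
                                 feat_bf[idx_test, ], labels[idx_test],
                                 seeds = seeds, n_trees = n_trees)
  eval_vs <- evaluate_classifier(feat_vs[idx_train, ], labels[idx_train],
                                 feat_vs[idx_test, ], labels[idx_test],
                                 seeds = seeds, n_trees = n_trees)
  pv <- stats::wilcox.test(eval_vs$accuracies, eval_bf$accuracies,
                           alternative = "greater", exact = FALSE)$p.value
  perm_labels <- with_seed(child_seed(seed, "perm"),
                           sample(labels[idx_train]))
  eval_null <- evaluate_classifier(feat_vs[idx_train, ], perm_labels,
                                   feat_vs[idx_test, ], labels[idx_test],
                                   seeds = seeds, n_trees = n_trees)
  list(eval_bf = eval_bf, eval_vs = eval_vs, p_value = pv,
       null_mean = eval_null$mean, model = model)
}

#' Run a named experiment and write its report files
#'
#' Writes `config.json` (the resolved configuration plus package
#' version) and `summary.json` into `out_dir`; reruns with the same
#' configuration reproduce the deterministic outputs bit-identically.
#'
#' @param experiment One of `"stain_specificity"`, `"morph_agreement"`,
#'   `"speed_tracking"`, `"viability_classification"`.
#' @param seed Experiment seed.
#' @param out_dir Output directory.
#' @param ... Additional arguments for the underlying runner
#'   (`morph_agreement` accepts `model`; if absent a membrane model is
#'   trained first).
#' @return The experiment summary (numbers only), invisibly.
#' @export
run_experiment <- function(experiment, seed, out_dir, ...) {
  runners <- c("stain_specificity", "morph_agreement", "speed_tracking",
               "viability_classification")
  if (!experiment %in% runners) {
    stop("unknown experiment id: ", experiment,
         " (expected one of ", paste(runners, collapse = ", "), ")")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  args <- list(...)
  summary <- switch(
    experiment,
    stain_specificity = {
      r <- do.call(run_stain_specificity, c(list(seed = seed), args))
      list(tos = r$tos, tos_sd = r$tos_sd, untrained_tos = r$untrained_tos)
    },
    morph_agreement = {
      if (is.null(args$model)) {
        t1 <- run_stain_specificity(seed = seed, channels = "membrane")
        args$model <- t1$models$membrane
      }
      r <- do.call(run_morph_analog, c(list(seed = seed), args))
      list(r_squared = as.list(r$r_squared),
           n_cells_matched = r$n_cells_matched)
    },
    speed_tracking = {
      r <- do.call(run_motion_analog, c(list(seed = seed), args))
      list(r_squared = r$r_squared, n_tracks = r$n_tracks,
           n_speed_pairs = r$n_speed_pairs,
           passes_threshold = r$r_squared >= 0.95)
    },
    viability_classification = {
      r <- do.call(run_viability_analog, c(list(seed = seed), args))
      list(accuracy_brightfield = r$eval_bf$mean,
           accuracy_virtual = r$eval_vs$mean,
           p_value = r$p_value, null_mean = r$null_mean,
           confusion_virtual = unclass(r$eval_vs$confusion))
    })
  jsonlite::write_json(
    list(experiment = experiment, seed = seed,
         package_version = as.character(utils::packageVersion("vstain")),
         args = args[!vapply(args, is.list, TRUE)]),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(summary)
}
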