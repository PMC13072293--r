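#' Configuration for the synthetic-sample benchmark
#'
#' Bundles everything the end-to-end sample-ladder experiment needs: the
#' scene specification, the sampling sizes (study defaults: 10,000 pixels
#' per class for the balanced classifiers; 60,000 normals and 10,000
#' contrastive pairs for the anomaly detector), the model roster, the clVAE
#' training configuration, and explicit seeds for every stage.
#'
#' @param scene_spec A [sample_scene_spec()].
#' @param n_per_class Balanced-set size per class for the baselines.
#' @param n_normal,n_pairs Anomaly-training sizes for the clVAE.
#' @param models Roster subset of
#'   `c("svm", "nb", "nn", "clvae_b1", "clvae_b2", "clvae_b3")`.
#' @param target_specificity Fixed-specificity operating level.
#' @param vae Base [vae_config()] whose `beta_max` is overridden per clVAE
#'   roster entry.
#' @param preprocess Logical: run artifact removal on rendered frames.
#' @param n_test_neg Optional cap on the number of negative test pixels
#'   scored (sampled without replacement with the `sampling` seed);
#'   `NULL` scores every negative pixel of the test scene.
#' @param seeds Named integer seeds (`train_scene`, `test_scene`,
#'   `sampling`, `models`).
#' @param out_dir Optional directory for report files.
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(scene_spec = sample_scene_spec(),
                             n_per_class = 10000L,
                             n_normal = 60000L, n_pairs = 10000L,
                             models = c("svm", "nb", "nn",
                                        "clvae_b1", "clvae_b2", "clvae_b3"),
                             target_specificity = 0.99,
                             vae = vae_config(),
                             preprocess = TRUE,
                             n_test_neg = NULL,
                             seeds = c(train_scene = 11L, test_scene = 12L,
                                       sampling = 13L, models = 14L),
                             out_dir = NULL) {
  models <- match.arg(models, several.ok = TRUE)
  structure(list(scene_spec = scene_spec, n_per_class = n_per_class,
                 n_normal = n_normal, n_pairs = n_pairs, models = models,
                 target_specificity = target_specificity, vae = vae,
                 preprocess = preprocess, n_test_neg = n_test_neg,
                 seeds = seeds, out_dir = out_dir),
            class = "benchmark_config")
}

scene_pixel_pools <- function(scene, train_concs = c(5, 2, 1)) {
  conc <- scene$truth$concentration_map
  pos_list <- lapply(sort(unique(conc[conc > 0]), decreasing = TRUE),
    function(cc) extract_roi_pixels(scene$frame, conc == cc, "positive",
                                    concentration = cc))
  positives <- do.call(rbind, pos_list)
  negatives <- extract_roi_pixels(scene$frame, conc == 0, "negative",
                                  concentration = 0)
  list(positive = positives, negative = negatives,
       train_positive = positives[positives$concentration %in% train_concs, ])
}

benchmark_model_scores <- function(name, pools, test, config) {
  seed <- config$seeds[["models"]]
  if (name %in% c("svm", "nb", "nn")) {
    train <- build_balanced_training_set(pools$train_positive,
                                         pools$negative,
                                         config$n_per_class,
                                         seed = config$seeds[["sampling"]])
    model <- train_baseline(baseline_spec(name, seed = seed), train)
    list(pos = score_pixels(model, test$positive),
         neg = score_pixels(model, test$negative), model = model)
  } else {
    beta <- as.numeric(sub("clvae_b", "", name))
    sets <- build_anomaly_training_set(pools$negative, pools$train_positive,
                                       config$n_normal, config$n_pairs,
                                       seed = config$seeds[["sampling"]])
    cfg <- config$vae
    cfg$beta_max <- beta
    cfg$seed <- seed
    model <- train_clvae(sets$normal, sets$pairs, cfg)
    list(pos = score_features(model, pixel_set_features(test$positive)),
         neg = score_features(model, pixel_set_features(test$negative)),
         model = model)
  }
}

#' Run the synthetic-sample benchmark
#'
#' End-to-end experiment on the concentration ladder: renders a training
#' and a test scene, optionally removes compression artifacts, assembles
#' the class pools (positives from the 5/2/1 ug/mL wells, negatives from
#' the reference well and background), trains the configured model roster,
#' and evaluates each model's ROC/AUC, optimal operating point, and
#' per-concentration detection rate at the fixed-specificity threshold
#' calibrated on the test-scene negatives. Fully reproducible from the
#' config seeds.
#'
#' @param config A [benchmark_config()].
#' @return A `benchmark_report` list: `table` (one row per model: AUC,
#'   operating-point accuracy/sensitivity/specificity, detection rate per
#'   ladder concentration), `threshold` per model, and `config`. If
#'   `config$out_dir` is set, the table is also written as CSV and JSON.
#' @export
run_synthetic_benchmark <- function(config = benchmark_config()) {
  stopifnot(inherits(config, "benchmark_config"))
  train_scene <- render_sample_scene(config$scene_spec,
                                     seed = config$seeds[["train_scene"]])
  test_scene <- render_sample_scene(config$scene_spec,
                                    seed = config$seeds[["test_scene"]])
  if (config$preprocess) {
    train_scene$frame <- preprocess_frame(train_scene$frame)
    test_scene$frame <- preprocess_frame(test_scene$frame)
  }
  pools <- scene_pixel_pools(train_scene)
  test <- scene_pixel_pools(test_scene)
  if (!is.null(config$n_test_neg) &&
      nrow(test$negative) > config$n_test_neg) {
    set.seed(config$seeds[["sampling"]] + 1L)
    test$negative <- sample_rows(test$negative, config$n_test_neg,
                                 "test-negative")
  }

  rows <- list(); thresholds <- numeric(0)
  for (name in config$models) {
    sc <- benchmark_model_scores(name, pools, test, config)
    curve <- roc_curve(c(sc$pos, sc$neg),
                       c(rep(TRUE, length(sc$pos)), rep(FALSE, length(sc$neg))))
    oop <- optimal_operating_point(curve)
    tau <- calibrate_threshold(sc$neg, config$target_specificity)
    rates <- detection_rate_table(sc$pos, test$positive$concentration, tau)
    row <- data.frame(model = name, auc = curve$auc,
                      accuracy = oop$accuracy, sensitivity = oop$sensitivity,
                      specificity = oop$specificity)
    for (i in seq_len(nrow(rates)))
      row[[sprintf("c_%g", rates$concentration[i])]] <- rates$detection_rate[i]
    rows[[name]] <- row
    thresholds[name] <- tau
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  report <- structure(list(table = table, thresholds = thresholds,
                           config = config),
                      class = "benchmark_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(table, file.path(config$out_dir, "benchmark.csv"),
                     row.names = FALSE)
    jsonlite::write_json(table, file.path(config$out_dir, "benchmark.json"),
                         dataframe = "rows", digits = NA)
  }
  report
}

#' Configuration for the transfer evaluation
#'
#' The intraoperative transfer protocol, driven by
#' synthetic surgical scenes: a beta = 1 clVAE is trained on pixels from
#' negative (non-fluorescence-guided) frames (reference sizes: 500,000 normals,
#' 50,000 pairs), its threshold calibrated on held-out negative frames at
#' the target specificity, and the model is then evaluated on negative test
#' frames (specificity report) and on fluorescence-guided test frames
#' (annotation overlap and concentration mapping).
#'
#' @param scene_spec A [surgical_scene_spec()] for the evaluation frames;
#'   negative frames reuse it with zero blobs.
#' @param n_train_neg,n_calib_neg,n_test_neg,n_test_fgs Frame counts per
#'   role.
#' @param n_normal,n_pairs clVAE training-set sizes.
#' @param vae Base [vae_config()] (`beta_max = 1` enforced).
#' @param annotation_threshold Concentration (ug/mL) above which a pixel
#'   counts as visibly fluorescent for the synthetic annotation masks.
#' @param quant_model Optional `quant_model` for concentration maps; by
#'   default one is fitted on a rendered sample-ladder scene.
#' @param target_specificity Calibration level.
#' @param seeds Named seeds.
#' @param out_dir Optional output directory for masks, maps and overlays.
#' @return A `transfer_config` list.
#' @export
transfer_config <- function(scene_spec = surgical_scene_spec(),
                            n_train_neg = 3L, n_calib_neg = 2L,
                            n_test_neg = 5L, n_test_fgs = 3L,
                            n_normal = 500000L, n_pairs = 50000L,
                            vae = vae_config(),
                            annotation_threshold = 0.5,
                            quant_model = NULL,
                            target_specificity = 0.99,
                            seeds = c(frames = 21L, sampling = 22L,
                                      model = 23L),
                            out_dir = NULL) {
  structure(list(scene_spec = scene_spec, n_train_neg = n_train_neg,
                 n_calib_neg = n_calib_neg, n_test_neg = n_test_neg,
                 n_test_fgs = n_test_fgs, n_normal = n_normal,
                 n_pairs = n_pairs, vae = vae,
                 annotation_threshold = annotation_threshold,
                 quant_model = quant_model,
                 target_specificity = target_specificity,
                 seeds = seeds, out_dir = out_dir),
            class = "transfer_config")
}

negative_spec <- function(spec) {
  spec$n_blobs <- 0L
  spec
}

#' Run the transfer evaluation
#'
#' @param config A [transfer_config()].
#' @return A `transfer_report` list: `model` (the trained clVAE),
#'   `threshold`, `specificity` (a [negative_frame_specificity()] report
#'   over the negative test frames), `overlaps` (one
#'   [annotation_overlap()] per fluorescence-guided test frame, empty when
#'   there are none), `blob_coverage` (fraction of ground-truth core
#'   pixels, concentration >= 1 ug/mL, detected per FGS frame), and the
#'   concentration `maps`. With `out_dir` set, masks, maps and overlays
#'   are written per evaluated frame.
#' @export
run_transfer_evaluation <- function(config = transfer_config()) {
  stopifnot(inherits(config, "transfer_config"))
  fseed <- config$seeds[["frames"]]
  neg_spec <- negative_spec(config$scene_spec)
  render_many <- function(spec, n, seed0)
    lapply(seq_len(n), function(i) render_surgical_scene(spec, seed = seed0 + i))

  train_neg <- render_many(neg_spec, config$n_train_neg, fseed)
  train_fgs <- render_many(config$scene_spec, max(1L, config$n_train_neg), fseed + 100L)
  calib_neg <- render_many(neg_spec, config$n_calib_neg, fseed + 200L)
  test_neg <- render_many(neg_spec, config$n_test_neg, fseed + 300L)
  test_fgs <- render_many(config$scene_spec, config$n_test_fgs, fseed + 400L)

  normal_pool <- do.call(rbind, lapply(train_neg, function(s)
    extract_roi_pixels(s$frame, matrix(TRUE, nrow(s$truth$concentration_map),
                                       ncol(s$truth$concentration_map)),
                       "negative")))
  anomaly_pool <- do.call(rbind, lapply(train_fgs, function(s)
    extract_roi_pixels(s$frame, s$truth$concentration_map >= 1, "positive")))

  sets <- build_anomaly_training_set(normal_pool, anomaly_pool,
                                     config$n_normal, config$n_pairs,
                                     seed = config$seeds[["sampling"]])
  cfg <- config$vae
  cfg$beta_max <- 1
  cfg$seed <- config$seeds[["model"]]
  model <- train_clvae(sets$normal, sets$pairs, cfg)

  calib_scores <- unlist(lapply(calib_neg, function(s)
    as.vector(score_frame(model, s$frame))))
  tau <- calibrate_threshold(calib_scores, config$target_specificity)

  neg_masks <- lapply(test_neg, function(s)
    detection_mask(score_frame(model, s$frame), s$frame, tau))
  specificity <- negative_frame_specificity(neg_masks,
                                            lapply(test_neg, `[[`, "frame"))

  qm <- config$quant_model
  if (is.null(qm)) {
    cal_scene <- render_sample_scene(sample_scene_spec(
      well_radius = 20L, noise_sd = config$scene_spec$noise_sd,
      K = config$scene_spec$K, A = config$scene_spec$A),
      seed = fseed + 500L)
    cal <- scene_pixel_pools(cal_scene)
    feats <- pixel_set_features(cal$positive)
    qm <- fit_poly_2d(feats[, "R"], feats[, "pG"], cal$positive$concentration)
  }

  overlaps <- list(); maps <- list(); coverage <- numeric(0)
  for (i in seq_along(test_fgs)) {
    s <- test_fgs[[i]]
    mask <- detection_mask(score_frame(model, s$frame), s$frame, tau)
    annot <- s$truth$concentration_map >= config$annotation_threshold
    overlaps[[i]] <- annotation_overlap(mask, annot)
    core <- s$truth$concentration_map >= 1
    coverage[i] <- if (any(core)) sum(mask & core) / sum(core) else NA_real_
    rendered <- render_concentration_map(s$frame, qm, mask)
    maps[[i]] <- rendered$map
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      write_mask(mask, file.path(config$out_dir, sprintf("fgs_%02d_mask.png", i)))
      write_float_map(rendered$map,
                      file.path(config$out_dir, sprintf("fgs_%02d_map.tsv", i)))
      write_frame(rendered$overlay,
                  file.path(config$out_dir, sprintf("fgs_%02d_overlay.png", i)))
    }
  }
  if (!is.null(config$out_dir)) {
    utils::write.csv(as.data.frame(specificity),
                     file.path(config$out_dir, "specificity.csv"),
                     row.names = FALSE)
  }
  structure(list(model = model, threshold = tau, specificity = specificity,
                 overlaps = overlaps, blob_coverage = coverage,
                 maps = maps, quant_model = qm, config = config),
            class = "transfer_report")
}
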