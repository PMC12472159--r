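# Pipeline surface: run configuration, batch commands (synth / attribute /
# overlap / agree / metrics) and file layout. The Rscript front-end at
# inst/cli/fundusxai.R is a thin wrapper over these functions.
#
# On-disk layout of a run directory:
#   images/<image_id>.png           RGB scenes / fundus images
#   masks/<lesion_type>/<id>.png    binary masks, one directory per type
#   manifest.csv                    image_id, grade
#   predictions.csv                 image_id, true_grade, predicted_grade,
#                                   p0..p4
#   heatmaps/<method>/<id>.tif      normalized heatmaps, float TIFF
#   records.csv                     overlap records
#   overlap_table.csv               per-grade hit counts (wide)
#   agreement_table.csv             kappa table (wide)

#' Run configuration
#'
#' @param data_dir Run directory holding `images/`, `masks/`,
#'   `manifest.csv` and receiving all outputs.
#' @param methods Attribution methods to run.
#' @param percentiles Named numeric: threshold percentile per method.
#' @param ig IG settings, an [ig_config()].
#' @param seed Integer seed for anything stochastic.
#' @param annotations Optional path to a manual-annotation CSV
#'   (`image_id`, `method`, `lesion`, `highlighted`).
#' @return A `run_config`.
#' @export
run_config <- function(data_dir, methods = c("gradcam", "ig"),
                       percentiles = c(gradcam = 90, ig = 97),
                       ig = ig_config(), seed = 1L, annotations = NULL) {
  stopifnot(all(methods %in% c("gradcam", "ig")))
  for (m in methods) threshold_spec(percentiles[[m]])  # validate
  structure(
    list(data_dir = data_dir, methods = methods, percentiles = percentiles,
         ig = ig, seed = as.integer(seed), annotations = annotations),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Recognized keys: `data_dir`, `methods`, `percentiles` (map method ->
#' percentile), `ig: {steps, riemann_rule, channel_reduction}`, `seed`,
#' `annotations`.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  igy <- y$ig %||% list()
  run_config(
    data_dir = y$data_dir %||% dirname(path),
    methods = unlist(y$methods %||% c("gradcam", "ig")),
    percentiles = unlist(y$percentiles %||% c(gradcam = 90, ig = 97)),
    ig = ig_config(steps = igy$steps %||% 64L,
                   riemann_rule = igy$riemann_rule %||% "trapezoid",
                   channel_reduction = igy$channel_reduction %||% "abs_sum"),
    seed = y$seed %||% 1L,
    annotations = y$annotations
  )
}

#' Generate a batch of synthetic scenes into a run directory
#'
#' Writes images, per-lesion mask directories and `manifest.csv`. Grades are
#' assigned round-robin over `grades`; scene seeds derive deterministically
#' from `seed`.
#'
#' @param data_dir Output directory.
#' @param n_images Number of scenes.
#' @param grades DR grades to cycle through.
#' @param seed Base seed.
#' @param image_size Scene side length in pixels.
#' @return The manifest data.frame, invisibly.
#' @export
run_synth <- function(data_dir, n_images = 10L, grades = 0:4, seed = 1L,
                      image_size = 224L) {
  dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    g <- grades[((i - 1L) %% length(grades)) + 1L]
    spec <- sample_scene_spec(g, seed = seed * 1000L + i,
                              image_size = image_size)
    sample <- generate_scene(spec, image_id = sprintf("img_%04d", i))
    write_scene(sample, data_dir)
    rows[[i]] <- data.frame(image_id = sample$image_id, grade = sample$grade,
                            stringsAsFactors = FALSE)
    fx_log("debug", "synth %s grade %d", sample$image_id, sample$grade)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(data_dir, "manifest.csv"), row.names = FALSE)
  fx_log("info", "wrote %d scenes to %s", n_images, data_dir)
  invisible(manifest)
}

read_manifest <- function(data_dir) {
  path <- file.path(data_dir, "manifest.csv")
  if (!file.exists(path)) {
    stop_fundus(sprintf("manifest not found: %s", path),
                "fundusXAI_config_error")
  }
  read.csv(path, stringsAsFactors = FALSE)
}

#' Compute and store heatmaps and predictions for a run directory
#'
#' For every image in the manifest: predict with the adapter, attribute the
#' predicted class with each configured method, resize to the image grid,
#' normalize, and store as float TIFF under `heatmaps/<method>/`. Also
#' writes `predictions.csv`. Unreadable images are reported per file and
#' skipped; the function errors at the end if any failed.
#'
#' @param config A [run_config()].
#' @param adapter A [classifier_adapter()]; default: the fixture classifier.
#' @return The predictions data.frame, invisibly.
#' @export
run_attribute <- function(config, adapter = NULL) {
  stopifnot(inherits(config, "run_config"))
  manifest <- read_manifest(config$data_dir)
  img_dir <- file.path(config$data_dir, "images")
  if (!dir.exists(img_dir) || nrow(manifest) == 0) {
    stop_fundus("no images found", "fundusXAI_input_error")
  }
  adapter <- adapter %||% fixture_classifier()
  for (m in config$methods) {
    dir.create(file.path(config$data_dir, "heatmaps", m), recursive = TRUE,
               showWarnings = FALSE)
  }
  failed <- character()
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$image_id[i]
    img <- tryCatch(png::readPNG(file.path(img_dir, paste0(id, ".png"))),
                    error = function(e) NULL)
    if (is.null(img)) {
      fx_log("warn", "unreadable image %s", id)
      failed <- c(failed, id)
      next
    }
    probs <- adapter$predict(img)
    cls <- target_class_policy(adapter, img)
    shape <- dim(img)[1:2]
    for (m in config$methods) {
      raw <- if (m == "gradcam") {
        grad_cam(adapter, img, cls, image_id = id)
      } else {
        integrated_gradients(adapter, img, cls, cfg = config$ig, image_id = id)
      }
      field <- resize_to_image(
        reduce_channels(raw, if (m == "ig") config$ig$channel_reduction
                        else "abs_sum"), shape)
      h <- normalize_heatmap(field, provenance = m, image_id = id)
      write_heatmap_tiff(h, file.path(config$data_dir, "heatmaps", m,
                                      paste0(id, ".tif")))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      image_id = id, true_grade = manifest$grade[i], predicted_grade = cls,
      t(setNames(probs, prob_cols())), stringsAsFactors = FALSE)
    fx_log("debug", "attributed %s (predicted %d)", id, cls)
  }
  preds <- do.call(rbind, rows)
  write.csv(preds, file.path(config$data_dir, "predictions.csv"),
            row.names = FALSE)
  if (length(failed)) {
    stop_fundus(sprintf("failed on %d image(s): %s", length(failed),
                        paste(failed, collapse = ", ")),
                "fundusXAI_input_error")
  }
  invisible(preds)
}

#' Intersect stored heatmaps with masks and build overlap tables
#'
#' Reads `heatmaps/`, `masks/` and `predictions.csv`, evaluates every image
#' with [evaluate_image()] at the configured percentiles, and writes
#' `records.csv` plus a wide `overlap_table.csv`.
#'
#' @param config A [run_config()].
#' @param lesions Mask types to use (default: mask directories present).
#' @return The records data.frame, invisibly.
#' @export
run_overlap <- function(config, lesions = NULL) {
  stopifnot(inherits(config, "run_config"))
  preds_path <- file.path(config$data_dir, "predictions.csv")
  if (!file.exists(preds_path)) {
    stop_fundus("predictions.csv not found; run the attribute step first",
                "fundusXAI_config_error")
  }
  preds <- read.csv(preds_path, stringsAsFactors = FALSE)
  mask_root <- file.path(config$data_dir, "masks")
  lesions <- lesions %||% list.dirs(mask_root, recursive = FALSE,
                                    full.names = FALSE)
  missing <- setdiff(lesions, list.dirs(mask_root, recursive = FALSE,
                                        full.names = FALSE))
  if (length(missing)) {
    stop_fundus(sprintf("mask directories missing for: %s",
                        paste(missing, collapse = ", ")),
                "fundusXAI_config_error")
  }
  all_records <- list()
  for (i in seq_len(nrow(preds))) {
    id <- preds$image_id[i]
    heatmaps <- list()
    for (m in config$methods) {
      heatmaps[[m]] <- read_heatmap_tiff(
        file.path(config$data_dir, "heatmaps", m, paste0(id, ".tif")),
        provenance = m, image_id = id)
    }
    shape <- dim(heatmaps[[1]]$values)
    masks <- list()
    for (lt in lesions) {
      mk <- load_mask(file.path(mask_root, lt, paste0(id, ".png")), lt, id)
      if (lt %in% LANDMARK_TYPES) mk <- suppressWarnings(retain_single_component(mk))
      masks[[lt]] <- align_mask_to_grid(mk, shape)
    }
    all_records[[i]] <- evaluate_image(
      masks, heatmaps, grade = preds$true_grade[i],
      predicted_grade = preds$predicted_grade[i], image_id = id,
      percentiles = config$percentiles)
  }
  records <- do.call(rbind, all_records)
  write.csv(records, file.path(config$data_dir, "records.csv"),
            row.names = FALSE)
  tab <- build_overlap_table(records)
  write.csv(render_overlap_table(tab),
            file.path(config$data_dir, "overlap_table.csv"), row.names = FALSE)
  fx_log("info", "overlap: %d records, thresholds %s", nrow(records),
         paste(sprintf("%s=%g", names(config$percentiles),
                       config$percentiles), collapse = " "))
  invisible(records)
}

#' Kappa agreement table between manual annotations and overlap records
#'
#' @param config A [run_config()] whose `annotations` points at the manual
#'   CSV.
#' @return The long agreement table, invisibly; also writes
#'   `agreement_table.csv` (wide rendering).
#' @export
run_agree <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$annotations) || !file.exists(config$annotations)) {
    stop_fundus("annotations CSV not configured or missing",
                "fundusXAI_config_error")
  }
  records <- read.csv(file.path(config$data_dir, "records.csv"),
                      stringsAsFactors = FALSE)
  manual <- read.csv(config$annotations, stringsAsFactors = FALSE)
  tab <- build_agreement_table(manual, records)
  write.csv(render_agreement_table(tab),
            file.path(config$data_dir, "agreement_table.csv"),
            row.names = FALSE)
  invisible(tab)
}

#' Classification metrics and score statistics for a run directory
#'
#' @param config A [run_config()].
#' @return List with `metrics`, `score_stats`, `confusion`; also writes
#'   `metrics.csv`, `score_stats.csv`, `confusion.csv`.
#' @export
run_metrics <- function(config) {
  stopifnot(inherits(config, "run_config"))
  preds <- read.csv(file.path(config$data_dir, "predictions.csv"),
                    stringsAsFactors = FALSE)
  met <- classification_metrics(preds)
  stats <- score_statistics(preds)
  conf <- confusion_matrix(preds)
  write.csv(data.frame(metric = names(met),
                       value = vapply(met, identity, numeric(1))),
            file.path(config$data_dir, "metrics.csv"), row.names = FALSE)
  write.csv(stats, file.path(config$data_dir, "score_stats.csv"),
            row.names = FALSE)
  write.csv(as.data.frame.matrix(conf),
            file.path(config$data_dir, "confusion.csv"))
  invisible(list(metrics = met, score_stats = stats, confusion = conf))
}

#' Simple heatmap overlay for visual reports
#'
#' Blends a heatmap into the red channel of an RGB image and writes a PNG.
#'
#' @param image RGB array in `[0,1]`.
#' @param h A `heatmap`.
#' @param path Output PNG path.
#' @param alpha Blend weight of the heatmap.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(image, h, path, alpha = 0.5) {
  stopifnot(inherits(h, "heatmap"))
  out <- image
  out[, , 1] <- pmin(1, (1 - alpha) * image[, , 1] + alpha * h$values)
  png::writePNG(out, path)
  invisible(path)
}
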