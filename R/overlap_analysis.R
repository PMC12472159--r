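# Overlap analysis: activation-mask intersection, hit decision, IoU, and
# stratified count tables.

#' Intersect an activation map with a lesion mask
#'
#' Computes the pixel-wise AND `I = A & M`, the hit decision (`sum(I) > 0`:
#' any overlap counts, the amount does not), the intersection pixel count,
#' and the Jaccard IoU `|A & M| / |A | M|` (defined as 0 with a flag when
#' both sets are empty).
#'
#' @param a An `activation_map` (or 0/1 matrix).
#' @param m A `lesion_mask` (or 0/1 matrix).
#' @return List with `hit`, `intersection_pixels`, `iou`, `both_empty`,
#'   `intersection` (the 0/1 matrix `I`).
#' @export
intersect_activation <- function(a, m) {
  av <- if (inherits(a, "activation_map")) a$values else a
  mv <- if (inherits(m, "lesion_mask")) m$values else m
  assert_binary_matrix(av, "activation map")
  assert_binary_matrix(mv, "mask")
  if (!identical(dim(av), dim(mv))) {
    stop_fundus("intersect_activation: grid shapes differ",
                "fundusXAI_input_error")
  }
  I <- av * mv
  inter <- sum(I)
  uni <- sum((av + mv) > 0)
  both_empty <- uni == 0
  list(
    hit = inter > 0,
    intersection_pixels = as.integer(inter),
    iou = if (both_empty) 0 else inter / uni,
    both_empty = both_empty,
    intersection = I
  )
}

#' Evaluate one image: all (method, lesion) overlap records
#'
#' For each requested attribution method the normalized heatmap is binarized
#' at its method-specific percentile (90 Grad-CAM / 97 IG by default) and
#' intersected with every supplied lesion mask, yielding one record per
#' (method, lesion type).
#'
#' @param masks Named list of `lesion_mask` objects (names = lesion types).
#' @param heatmaps Named list of `heatmap` objects, e.g.
#'   `list(gradcam=, ig=)`.
#' @param grade True DR grade 0-4.
#' @param predicted_grade Predicted DR grade 0-4.
#' @param image_id Identifier used in the records.
#' @param percentiles Named numeric vector overriding per-method percentiles.
#' @return A data.frame of overlap records (possibly 0-row, with a warning,
#'   when no masks are supplied).
#' @export
evaluate_image <- function(masks, heatmaps, grade, predicted_grade,
                           image_id = NA_character_, percentiles = NULL) {
  if (length(masks) == 0) {
    warning(sprintf("no masks supplied for image '%s'", image_id),
            call. = FALSE)
    return(overlap_records_schema())
  }
  stopifnot(length(heatmaps) >= 1, !is.null(names(heatmaps)))
  rows <- list()
  for (method in names(heatmaps)) {
    h <- heatmaps[[method]]
    if (is.null(h)) {
      stop_fundus(sprintf("missing heatmap for method '%s'", method),
                  "fundusXAI_config_error")
    }
    spec <- if (!is.null(percentiles) && method %in% names(percentiles)) {
      threshold_spec(percentiles[[method]])
    } else {
      default_threshold_spec(method)
    }
    act <- percentile_threshold(h, spec)
    for (lt in names(masks)) {
      mk <- masks[[lt]]
      if (!identical(dim(mk$values), dim(h$values))) {
        stop_fundus(sprintf(
          "mask %s and heatmap grids differ for image '%s'", lt, image_id),
          "fundusXAI_input_error")
      }
      ov <- intersect_activation(act, mk)
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = image_id, method = method, lesion = lt,
        grade = as.integer(grade), correct = grade == predicted_grade,
        hit = ov$hit, intersection_pixels = ov$intersection_pixels,
        iou = ov$iou, mask_pixels = sum(mk$values),
        degenerate_heatmap = act$degenerate_flag,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

overlap_records_schema <- function() {
  data.frame(image_id = character(), method = character(), lesion = character(),
             grade = integer(), correct = logical(), hit = logical(),
             intersection_pixels = integer(), iou = numeric(),
             mask_pixels = integer(), degenerate_heatmap = logical(),
             stringsAsFactors = FALSE)
}

#' Aggregate overlap records into a per-grade count table
#'
#' Counts, for each (method, grade, correctness) stratum, the number of
#' images whose activation map hit each lesion type, plus the stratum image
#' total — the layout used for per-grade lesion-attention summaries.
#'
#' @param records Data.frame from [evaluate_image()] (row-bound over images).
#' @return A long data.frame: method, grade, correct, lesion, hits, total.
#' @export
build_overlap_table <- function(records) {
  req <- c("image_id", "method", "lesion", "grade", "correct", "hit")
  if (!all(req %in% names(records))) {
    stop_fundus("build_overlap_table: records missing required columns",
                "fundusXAI_input_error")
  }
  key <- interaction(records$image_id, records$method, records$lesion,
                     drop = TRUE)
  if (anyDuplicated(key)) {
    stop_fundus("build_overlap_table: duplicate (image, method, lesion) records",
                "fundusXAI_data_error")
  }
  out <- list()
  for (method in sort(unique(records$method))) {
    for (g in sort(unique(records$grade))) {
      for (corr in c(TRUE, FALSE)) {
        sub <- records[records$method == method & records$grade == g &
                         records$correct == corr, , drop = FALSE]
        total <- length(unique(sub$image_id))
        for (lt in sort(unique(records$lesion))) {
          lsub <- sub[sub$lesion == lt, , drop = FALSE]
          out[[length(out) + 1L]] <- data.frame(
            method = method, grade = g, correct = corr, lesion = lt,
            hits = sum(lsub$hit), total = total, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Render an overlap table in wide per-grade layout
#'
#' One row per (method, grade); columns give stratum totals and per-lesion
#' hit counts under "correct" then "incorrect" prediction headings; empty
#' strata are rendered as an en dash.
#'
#' @param tab Long table from [build_overlap_table()].
#' @param lesions Column order for lesion types (default: those present).
#' @return A character data.frame ready for CSV output.
#' @export
render_overlap_table <- function(tab, lesions = NULL) {
  lesions <- lesions %||% sort(unique(tab$lesion))
  rows <- list()
  for (method in unique(tab$method)) {
    for (g in sort(unique(tab$grade))) {
      row <- list(method = method, grade = g)
      for (corr in c(TRUE, FALSE)) {
        pre <- if (corr) "correct" else "incorrect"
        sub <- tab[tab$method == method & tab$grade == g & tab$correct == corr, ]
        total <- if (nrow(sub)) sub$total[1] else 0L
        row[[paste0(pre, "_total")]] <- as.character(total)
        for (lt in lesions) {
          hits <- sub$hits[sub$lesion == lt]
          row[[paste0(pre, "_", lt)]] <-
            if (total == 0L || !length(hits)) "-" else as.character(hits)
        }
      }
      rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
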