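# Lesion / landmark mask handling and patch tiling.

#' Lesion and landmark type vocabulary
#'
#' MA microaneurysm, EX hard exudate, SE soft exudate (cotton-wool spot),
#' HE hemorrhage, NV neovascularization, rHE/pHE/vHE retinal/preretinal/
#' vitreous hemorrhage, FP fibrous proliferation, OD optic disc, MC macula.
#'
#' @export
LESION_TYPES <- c("MA", "EX", "SE", "HE", "NV", "rHE", "pHE", "vHE", "FP",
                  "OD", "MC")

# Landmark types that may be post-processed to a single component.
LANDMARK_TYPES <- c("OD", "MC")

new_lesion_mask <- function(values, lesion_type, image_id = NA_character_) {
  assert_binary_matrix(values, sprintf("%s mask", lesion_type))
  if (!lesion_type %in% LESION_TYPES) {
    stop_fundus(sprintf("unknown lesion type '%s'", lesion_type),
                "fundusXAI_input_error")
  }
  structure(list(values = values, lesion_type = lesion_type,
                 image_id = image_id),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask %s %s: %d positive px of %d>\n", x$lesion_type,
              x$image_id %||% "", sum(x$values), length(x$values)))
  invisible(x)
}

#' Load a binary lesion mask from a single-channel PNG
#'
#' Any pixel strictly greater than zero becomes 1.
#'
#' @param path PNG file path.
#' @param lesion_type One of [LESION_TYPES].
#' @param image_id Optional identifier (default: file stem).
#' @return A `lesion_mask`.
#' @export
load_mask <- function(path, lesion_type, image_id = NULL) {
  if (!file.exists(path)) {
    stop_fundus(sprintf("mask file not found: %s", path),
                "fundusXAI_format_error")
  }
  v <- tryCatch(png::readPNG(path), error = function(e) {
    stop_fundus(sprintf("unreadable mask PNG: %s", path),
                "fundusXAI_format_error")
  })
  if (length(dim(v)) == 3L) {
    stop_fundus(sprintf("mask must be single-channel: %s", path),
                "fundusXAI_format_error")
  }
  new_lesion_mask((v > 0) * 1, lesion_type,
                  image_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname load_mask
#' @param mask A `lesion_mask`.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "lesion_mask"))
  png::writePNG(mask$values, path)
  invisible(path)
}

# 8-connected component labelling (two-pass BFS flood fill).
# Returns an integer matrix of labels (0 = background), numbered in raster
# order of each component's first-encountered pixel.
label_components <- function(m, connectivity = 8L) {
  assert_binary_matrix(m)
  nr <- nrow(m); nc <- ncol(m)
  labels <- matrix(0L, nr, nc)
  offsets <- if (connectivity == 8L) {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  }
  nextlab <- 0L
  # raster order: column-major in R; component ids follow first pixel seen
  fg <- which(m == 1)
  for (start in fg) {
    if (labels[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    labels[start] <- nextlab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((cur - 1L) %% nr) + 1L
      cc <- ((cur - 1L) %/% nr) + 1L
      for (o in seq_len(nrow(offsets))) {
        rr <- r + offsets[o, 1]; ccc <- cc + offsets[o, 2]
        if (rr >= 1 && rr <= nr && ccc >= 1 && ccc <= nc) {
          idx <- (ccc - 1L) * nr + rr
          if (m[idx] == 1 && labels[idx] == 0L) {
            labels[idx] <- nextlab
            queue <- c(queue, idx)
          }
        }
      }
    }
  }
  labels
}

#' Keep only the largest connected component of a landmark mask
#'
#' Segmentation output sometimes contains several blobs for the optic disc
#' or macula, which are anatomically unique; this keeps the largest
#' 8-connected component. Ties are broken deterministically in favor of the
#' component whose lexicographically smallest `(row, col)` pixel comes
#' first. Lesion masks (everything except OD/MC) must not be post-processed
#' and are rejected. An empty mask is returned unchanged with a warning.
#'
#' @param mask A `lesion_mask` with `lesion_type` `"OD"` or `"MC"`.
#' @return A `lesion_mask` with at most one connected component.
#' @export
retain_single_component <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (!mask$lesion_type %in% LANDMARK_TYPES) {
    stop_fundus(sprintf(
      "retain_single_component applies only to OD/MC landmarks, not '%s' (lesion masks are used as generated)",
      mask$lesion_type), "fundusXAI_usage_error")
  }
  if (sum(mask$values) == 0) {
    warning(sprintf("empty %s mask for image '%s'", mask$lesion_type,
                    mask$image_id), call. = FALSE)
    return(mask)
  }
  labels <- label_components(mask$values, 8L)
  n <- max(labels)
  if (n == 1L) return(mask)
  sizes <- tabulate(labels[labels > 0L], nbins = n)
  # top-left pixel of each component: minimal (row, col) lexicographically
  key <- vapply(seq_len(n), function(k) {
    idx <- which(labels == k, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    idx[1, 1] * (ncol(labels) + 1) + idx[1, 2]
  }, numeric(1))
  best <- order(-sizes, key)[1]
  new_lesion_mask((labels == best) * 1, mask$lesion_type, mask$image_id)
}

#' Tile an image-mask pair into non-overlapping patches
#'
#' Splits the pair into a row-major ordered list of disjoint square patches
#' that exactly cover the grid; a 1120x1120 pair at patch size 224 yields 25
#' patches. Image dimensions must be divisible by the patch size.
#'
#' @param image Image array `[row, col, channel]` or matrix.
#' @param mask A `lesion_mask` on the same grid (or `NULL`).
#' @param patch_size Patch side length in pixels.
#' @return List of `list(image=, mask=, row_block=, col_block=)`, row-major.
#' @export
tile_patches <- function(image, mask = NULL, patch_size) {
  d <- dim(image)
  nr <- d[1]; nc <- d[2]
  if (nr %% patch_size != 0 || nc %% patch_size != 0) {
    stop_fundus(sprintf(
      "tile_patches: image dims %dx%d must be divisible by patch size %d",
      nr, nc, patch_size), "fundusXAI_input_error")
  }
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "lesion_mask"))
    if (!identical(dim(mask$values), c(nr, nc))) {
      stop_fundus("tile_patches: mask grid does not match image",
                  "fundusXAI_input_error")
    }
  }
  rb <- nr %/% patch_size; cb <- nc %/% patch_size
  out <- vector("list", rb * cb)
  i <- 0L
  for (r in seq_len(rb)) {
    rows <- ((r - 1) * patch_size + 1):(r * patch_size)
    for (cc in seq_len(cb)) {
      cols <- ((cc - 1) * patch_size + 1):(cc * patch_size)
      i <- i + 1L
      out[[i]] <- list(
        image = if (length(d) == 3L) image[rows, cols, , drop = FALSE]
                else image[rows, cols, drop = FALSE],
        mask = if (is.null(mask)) NULL
               else new_lesion_mask(mask$values[rows, cols, drop = FALSE],
                                    mask$lesion_type, mask$image_id),
        row_block = r, col_block = cc
      )
    }
  }
  out
}

#' Reassemble patches produced by [tile_patches()]
#'
#' @param patches Row-major patch list from [tile_patches()].
#' @return The reconstructed image array.
#' @export
stitch_patches <- function(patches) {
  rb <- max(vapply(patches, `[[`, 1L, "row_block"))
  cb <- max(vapply(patches, `[[`, 1L, "col_block"))
  p1 <- patches[[1]]$image
  ps <- dim(p1)[1]
  d <- if (length(dim(p1)) == 3L) c(rb * ps, cb * ps, dim(p1)[3]) else c(rb * ps, cb * ps)
  out <- array(0, d)
  for (p in patches) {
    rows <- ((p$row_block - 1) * ps + 1):(p$row_block * ps)
    cols <- ((p$col_block - 1) * ps + 1):(p$col_block * ps)
    if (length(d) == 3L) out[rows, cols, ] <- p$image else out[rows, cols] <- p$image
  }
  out
}

# Align a mask to an image grid: error-free passthrough when shapes match;
# otherwise bilinear resize + re-binarize at 0.5 with a logged warning.
align_mask_to_grid <- function(mask, target_shape) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (identical(dim(mask$values), as.integer(target_shape))) return(mask)
  fx_log("warn", "resizing %s mask for '%s' from %dx%d to %dx%d",
         mask$lesion_type, mask$image_id, nrow(mask$values), ncol(mask$values),
         target_shape[1], target_shape[2])
  v <- resize_to_image(mask$values, target_shape)
  new_lesion_mask((v >= 0.5) * 1, mask$lesion_type, mask$image_id)
}
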