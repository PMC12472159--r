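# Heatmap operations: resize -> normalize -> percentile threshold.
#
# Pipeline order matters: attributions are first resized to the image grid
# (Grad-CAM lives on the coarse conv grid), then normalized so [0,1] holds on
# the final grid, then binarized at a method-specific percentile of all
# pixels.

#' Bilinear resize of a scalar field
#'
#' Half-pixel-center convention: output pixel centers `(i - 0.5) / n_out`
#' are mapped into input pixel-center coordinates and bilinearly
#' interpolated, with replicated edges. Identity when shapes already match.
#'
#' @param raw A `raw_attribution` or numeric matrix.
#' @param target_shape Integer vector `c(rows, cols)`.
#' @return Numeric matrix with `target_shape` dimensions.
#' @export
resize_to_image <- function(raw, target_shape) {
  m <- if (inherits(raw, "raw_attribution")) {
    reduce_channels(raw)
  } else raw
  if (!is.matrix(m)) stop_fundus("resize_to_image: expected a matrix field",
                                 "fundusXAI_input_error")
  if (length(target_shape) != 2L || any(target_shape < 1)) {
    stop_fundus("resize_to_image: target dimensions must be positive",
                "fundusXAI_input_error")
  }
  nr <- as.integer(target_shape[1]); nc <- as.integer(target_shape[2])
  if (nr == nrow(m) && nc == ncol(m)) return(m)

  src_coord <- function(n_out, n_in) {
    x <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5  # input pixel-center coords
    pmin(pmax(x, 1), n_in)
  }
  r <- src_coord(nr, nrow(m)); c_ <- src_coord(nc, ncol(m))
  r0 <- pmin(floor(r), nrow(m) - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(c_), ncol(m) - 1L); c0 <- pmax(c0, 1L)
  fr <- r - r0; fc <- c_ - c0
  if (nrow(m) == 1L) { r0 <- rep(1L, nr); fr <- rep(0, nr) }
  if (ncol(m) == 1L) { c0 <- rep(1L, nc); fc <- rep(0, nc) }
  top <- m[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
    m[r0, pmin(c0 + 1L, ncol(m)), drop = FALSE] * outer(1 - fr, fc)
  bot <- m[pmin(r0 + 1L, nrow(m)), c0, drop = FALSE] * outer(fr, 1 - fc) +
    m[pmin(r0 + 1L, nrow(m)), pmin(c0 + 1L, ncol(m)), drop = FALSE] * outer(fr, fc)
  top + bot
}

#' Normalize a scalar field to a heatmap on [0,1]
#'
#' Min-max normalization `(v - min) / (max - min)`. A constant field cannot
#' be normalized; it becomes the all-zero heatmap, flagged degenerate, with
#' a warning (downstream reports can exclude such images).
#'
#' @param field Numeric matrix (finite values).
#' @param provenance `"gradcam"` or `"ig"` (recorded only).
#' @param image_id Optional identifier.
#' @return A `heatmap` object: list with `values` (matrix in `[0,1]`),
#'   `provenance`, `image_id`, `degenerate`.
#' @export
normalize_heatmap <- function(field, provenance = c("gradcam", "ig"),
                              image_id = NA_character_) {
  provenance <- match.arg(provenance)
  if (!is.matrix(field)) stop_fundus("normalize_heatmap: expected a matrix",
                                     "fundusXAI_input_error")
  if (any(!is.finite(field))) {
    stop_fundus("normalize_heatmap: field contains NaN/Inf",
                "fundusXAI_numeric_error")
  }
  lo <- min(field); hi <- max(field)
  degenerate <- hi == lo
  values <- if (degenerate) {
    warning(sprintf("constant attribution field for image '%s': degenerate heatmap",
                    image_id), call. = FALSE)
    matrix(0, nrow(field), ncol(field))
  } else {
    (field - lo) / (hi - lo)
  }
  structure(
    list(values = values, provenance = provenance, image_id = image_id,
         degenerate = degenerate),
    class = "heatmap"
  )
}

#' @export
print.heatmap <- function(x, ...) {
  cat(sprintf("<heatmap %s %s %dx%d%s>\n", x$provenance,
              x$image_id %||% "", nrow(x$values), ncol(x$values),
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Percentile threshold specification
#'
#' Method defaults follow the pipeline definition: the 90th percentile for
#' Grad-CAM and the 97th for Integrated Gradients. The threshold is the
#' linear-interpolation percentile (R quantile type 7) over the heatmap's
#' pixel population.
#'
#' @param percentile Real in `(0, 100)`.
#' @return A `threshold_spec`.
#' @export
threshold_spec <- function(percentile) {
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile <= 0 || percentile >= 100) {
    stop_fundus("threshold_spec: percentile must lie in (0, 100)",
                "fundusXAI_config_error")
  }
  structure(list(percentile = percentile), class = "threshold_spec")
}

#' @rdname threshold_spec
#' @param method Attribution method name.
#' @export
default_threshold_spec <- function(method = c("gradcam", "ig")) {
  method <- match.arg(method)
  threshold_spec(if (method == "gradcam") 90 else 97)
}

#' Binarize a heatmap at a percentile threshold
#'
#' `A(x,y) = 1` iff `H(x,y) >= T`, where `T` is the requested percentile of
#' all pixels of `H` (linear interpolation between order statistics). The
#' `>=` makes ties at the threshold active, so the active fraction is always
#' at least `(100 - p)/100`, with equality on distinct-valued heatmaps
#' whenever the percentile rank is compatible with the pixel count. A
#' degenerate (constant, all-zero) heatmap activates every pixel
#' (`0 >= 0`) and is flagged so reports can exclude it.
#'
#' @param h A `heatmap` from [normalize_heatmap()], or a numeric matrix
#'   already in `[0,1]`.
#' @param spec A [threshold_spec()]; default depends on the heatmap's
#'   provenance.
#' @param fov_mask Optional 0/1 matrix restricting the pixel population over
#'   which the percentile is computed (the threshold is still applied to the
#'   whole grid). Default: all pixels.
#' @return An `activation_map`: list with `values` (0/1 matrix),
#'   `threshold_used`, `percentile`, `degenerate_flag`.
#' @export
percentile_threshold <- function(h, spec = NULL, fov_mask = NULL) {
  if (is.matrix(h)) h <- structure(
    list(values = h, provenance = "gradcam", image_id = NA_character_,
         degenerate = max(h) == min(h)), class = "heatmap")
  stopifnot(inherits(h, "heatmap"))
  if (is.null(spec)) spec <- default_threshold_spec(h$provenance)
  stopifnot(inherits(spec, "threshold_spec"))
  pop <- if (is.null(fov_mask)) {
    h$values
  } else {
    assert_binary_matrix(fov_mask, "fov_mask")
    h$values[fov_mask == 1]
  }
  T <- unname(quantile(pop, spec$percentile / 100, type = 7))
  values <- (h$values >= T) * 1
  structure(
    list(values = values, threshold_used = T, percentile = spec$percentile,
         degenerate_flag = h$degenerate, image_id = h$image_id,
         provenance = h$provenance),
    class = "activation_map"
  )
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map p%s, T=%.4f, %.1f%% active%s>\n",
              format(x$percentile), x$threshold_used,
              100 * mean(x$values),
              if (x$degenerate_flag) ", degenerate" else ""))
  invisible(x)
}

#' Heatmap / activation-map file IO
#'
#' Heatmaps are stored as 32-bit float single-channel TIFF; activation maps
#' as 8-bit PNG with values 0/255.
#'
#' @param h A `heatmap`.
#' @param path File path.
#' @return `path` invisibly (writers); a `heatmap` / 0/1 matrix (readers).
#' @export
write_heatmap_tiff <- function(h, path) {
  stopifnot(inherits(h, "heatmap"))
  tiff::writeTIFF(h$values, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_heatmap_tiff
#' @param provenance,image_id Metadata restored on read.
#' @export
read_heatmap_tiff <- function(path, provenance = "gradcam",
                              image_id = NA_character_) {
  v <- tiff::readTIFF(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  structure(
    list(values = v, provenance = provenance, image_id = image_id,
         degenerate = max(v) == min(v)),
    class = "heatmap"
  )
}

#' @rdname write_heatmap_tiff
#' @param a An `activation_map`.
#' @export
write_activation_png <- function(a, path) {
  stopifnot(inherits(a, "activation_map"))
  png::writePNG(a$values, path)  # 0/1 -> 0/255 grayscale
  invisible(path)
}
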