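#' Integrated Gradients configuration
#'
#' @param steps Positive integer: number of quadrature intervals along the
#'   straight-line path from baseline to input. Default 64.
#' @param baseline Baseline image `x'` (same shape as the input) or `NULL`
#'   for the all-zero image in the model's input space.
#' @param riemann_rule `"trapezoid"` (default, faster convergence of the
#'   completeness residual) or `"left"`.
#' @param channel_reduction How a per-pixel-per-channel attribution is
#'   collapsed to one heatmap channel downstream: `"abs_sum"` (default) or
#'   `"signed_sum"`.
#' @return An `ig_config` object.
#' @export
ig_config <- function(steps = 64L, baseline = NULL,
                      riemann_rule = c("trapezoid", "left"),
                      channel_reduction = c("abs_sum", "signed_sum")) {
  riemann_rule <- match.arg(riemann_rule)
  channel_reduction <- match.arg(channel_reduction)
  if (!is.numeric(steps) || length(steps) != 1L || steps < 1 ||
      steps != round(steps)) {
    stop_fundus("ig_config: steps must be a positive integer",
                "fundusXAI_config_error")
  }
  structure(
    list(steps = as.integer(steps), baseline = baseline,
         riemann_rule = riemann_rule, channel_reduction = channel_reduction),
    class = "ig_config"
  )
}

new_raw_attribution <- function(values, method, target_class, image_id = NA_character_) {
  structure(
    list(values = values, method = method,
         target_class = as.integer(target_class), image_id = image_id),
    class = "raw_attribution"
  )
}

#' @export
print.raw_attribution <- function(x, ...) {
  d <- dim(x$values) %||% length(x$values)
  cat(sprintf("<raw_attribution %s, class %d, dims %s>\n",
              x$method, x$target_class, paste(d, collapse = "x")))
  invisible(x)
}

#' Grad-CAM attribution
#'
#' Gradient-weighted class activation mapping: the class score is
#' differentiated with respect to each feature map `A^k` of the designated
#' last convolutional layer; each map's gradient is spatially averaged into
#' a scalar weight `alpha_k`, and the map `ReLU(sum_k alpha_k A^k)` is
#' returned on the conv-layer grid (it is *not* resized or normalized here;
#' see [resize_to_image()] and [normalize_heatmap()]).
#'
#' @param adapter A [classifier_adapter()] exposing conv activations.
#' @param image Image array.
#' @param target_class 0-based class index; default: the predicted class via
#'   [target_class_policy()].
#' @param image_id Optional identifier carried through to error messages and
#'   records.
#' @return A `raw_attribution` with non-negative values on the conv grid.
#' @export
grad_cam <- function(adapter, image, target_class = NULL,
                     image_id = NA_character_) {
  if (is.null(adapter$conv_activations_and_gradients)) {
    stop_fundus("grad_cam: adapter has no designated convolutional layer",
                "fundusXAI_config_error")
  }
  if (is.null(target_class)) target_class <- target_class_policy(adapter, image)
  if (target_class < 0 || target_class >= adapter$n_classes) {
    stop_fundus("grad_cam: target_class out of range", "fundusXAI_config_error")
  }
  ag <- adapter$conv_activations_and_gradients(image, target_class)
  A <- ag$activations
  G <- ag$gradients
  if (!identical(dim(A), dim(G))) {
    stop_fundus("grad_cam: activation and gradient shapes disagree",
                "fundusXAI_adapter_error")
  }
  if (any(!is.finite(G)) || any(!is.finite(A))) {
    stop_fundus(sprintf("grad_cam: non-finite conv gradients for image '%s'",
                        image_id), "fundusXAI_numeric_error")
  }
  if (length(dim(A)) == 2L) {  # single feature map
    A <- array(A, c(dim(A), 1L))
    G <- array(G, c(dim(G), 1L))
  }
  alpha <- apply(G, 3L, mean)               # spatially pooled weights
  L <- matrix(0, nrow = dim(A)[1], ncol = dim(A)[2])
  for (k in seq_along(alpha)) L <- L + alpha[k] * A[, , k]
  L <- pmax(L, 0)                           # ReLU
  new_raw_attribution(L, "gradcam", target_class, image_id)
}

# Quadrature nodes/weights on [0,1] for the IG path integral.
ig_quadrature <- function(steps, rule) {
  if (rule == "left") {
    list(alpha = (seq_len(steps) - 1) / steps, w = rep(1 / steps, steps))
  } else {
    list(alpha = seq(0, 1, length.out = steps + 1),
         w = c(0.5, rep(1, steps - 1), 0.5) / steps)
  }
}

#' Integrated Gradients attribution
#'
#' Path-integral attribution along the straight line from a baseline image
#' `x'` to the input `x`: the gradient of the class score is averaged over
#' the path (left-Riemann or composite-trapezoid quadrature) and multiplied
#' elementwise by `x - x'`. For an exact integral the attributions satisfy
#' the completeness identity `sum(attr) = F(x) - F(x')`; the quadrature
#' residual shrinks as `steps` grows.
#'
#' @inheritParams grad_cam
#' @param cfg An [ig_config()].
#' @return A `raw_attribution` with values of the same shape as the image.
#' @export
integrated_gradients <- function(adapter, image, target_class = NULL,
                                 cfg = ig_config(), image_id = NA_character_) {
  stopifnot(inherits(cfg, "ig_config"))
  if (is.null(target_class)) target_class <- target_class_policy(adapter, image)
  if (target_class < 0 || target_class >= adapter$n_classes) {
    stop_fundus("integrated_gradients: target_class out of range",
                "fundusXAI_config_error")
  }
  x <- image
  baseline <- cfg$baseline
  if (is.null(baseline)) {
    baseline <- x
    baseline[] <- 0
  }
  if (!identical(dim(baseline) %||% length(baseline),
                 dim(x) %||% length(x))) {
    stop_fundus("integrated_gradients: baseline shape mismatch",
                "fundusXAI_input_error")
  }
  q <- ig_quadrature(cfg$steps, cfg$riemann_rule)
  diff <- x - baseline
  avg_grad <- x
  avg_grad[] <- 0
  for (i in seq_along(q$alpha)) {
    xi <- baseline + q$alpha[i] * diff
    g <- adapter$input_gradient(xi, target_class)
    if (any(!is.finite(g))) {
      stop_fundus(sprintf(
        "integrated_gradients: non-finite gradient for image '%s'", image_id),
        "fundusXAI_numeric_error")
    }
    avg_grad <- avg_grad + q$w[i] * g
  }
  new_raw_attribution(diff * avg_grad, "ig", target_class, image_id)
}

#' Collapse a per-channel attribution to a single-channel field
#'
#' Grad-CAM is already single-channel; multi-channel attributions (IG on an
#' RGB image) are reduced by summing per-channel absolute values
#' (`abs_sum`, default: magnitude of evidence regardless of sign) or the
#' signed values (`signed_sum`).
#'
#' @param raw A `raw_attribution`.
#' @param method `"abs_sum"` or `"signed_sum"`.
#' @return A numeric matrix.
#' @export
reduce_channels <- function(raw, method = c("abs_sum", "signed_sum")) {
  method <- match.arg(method)
  v <- if (inherits(raw, "raw_attribution")) raw$values else raw
  if (is.matrix(v)) return(v)
  if (length(dim(v)) != 3L) {
    stop_fundus("reduce_channels: expected a matrix or 3-d array",
                "fundusXAI_input_error")
  }
  if (method == "abs_sum") apply(abs(v), c(1, 2), sum) else apply(v, c(1, 2), sum)
}

#' Write / read a raw attribution as 32-bit float TIFF
#'
#' Values are stored as IEEE floats in a single-channel TIFF; multi-channel
#' attributions are reduced with [reduce_channels()] first. TIFF float
#' storage is only well-defined on `[0,1]`, so fields with values outside
#' that range are min-max scaled on write and the original range is kept in
#' a `<path>.range` sidecar that the reader uses to restore the values.
#'
#' @param raw A `raw_attribution` or numeric matrix.
#' @param path Output path.
#' @param reduction Channel reduction used when `raw` is multi-channel.
#' @return `path`, invisibly (for the writer); a numeric matrix (reader).
#' @export
write_attribution_tiff <- function(raw, path, reduction = "abs_sum") {
  m <- reduce_channels(raw, reduction)
  lo <- min(m); hi <- max(m)
  if (lo < 0 || hi > 1) {
    scaled <- if (hi > lo) (m - lo) / (hi - lo) else m * 0
    writeLines(sprintf("%.17g %.17g", lo, hi), paste0(path, ".range"))
    m <- scaled
  } else if (file.exists(paste0(path, ".range"))) {
    file.remove(paste0(path, ".range"))
  }
  tiff::writeTIFF(m, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_attribution_tiff
#' @export
read_attribution_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  sidecar <- paste0(path, ".range")
  if (file.exists(sidecar)) {
    r <- as.numeric(strsplit(trimws(readLines(sidecar)[1]), " ")[[1]])
    m <- m * (r[2] - r[1]) + r[1]
  }
  m
}
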