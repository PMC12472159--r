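#' Classifier adapter contract
#'
#' Attribution methods in this package never touch an autodiff framework
#' directly; they talk to a *classifier adapter*, a plain list of closures
#' that any gradient-capable model (torch, tensorflow, a hand-written net)
#' can satisfy. The class score that is differentiated is the adapter's
#' choice; the shipped fixture (and the recommended convention) uses the
#' pre-softmax class score, which avoids gradient saturation when the
#' softmax is confident.
#'
#' @param predict `function(image) -> numeric` per-class probability vector
#'   (non-negative, sums to 1 within 1e-6).
#' @param input_gradient `function(image, class_index) -> array` gradient of
#'   the class score with respect to every input entry; same shape as the
#'   image.
#' @param conv_activations_and_gradients `function(image, class_index) ->
#'   list(activations=, gradients=)`, both `[row, col, channel]` arrays on
#'   the grid of the designated last convolutional layer (the layer feeding
#'   global average pooling), or `NULL` for models without one (Grad-CAM is
#'   then unavailable).
#' @param n_classes Number of classes the probability vector has.
#' @param name Human-readable model name used in messages.
#'
#' @return An object of class `classifier_adapter`.
#' @export
classifier_adapter <- function(predict, input_gradient,
                               conv_activations_and_gradients = NULL,
                               n_classes, name = "model") {
  stopifnot(is.function(predict), is.function(input_gradient))
  if (!is.null(conv_activations_and_gradients)) {
    stopifnot(is.function(conv_activations_and_gradients))
  }
  stopifnot(is.numeric(n_classes), length(n_classes) == 1L, n_classes >= 2)
  structure(
    list(
      predict = predict,
      input_gradient = input_gradient,
      conv_activations_and_gradients = conv_activations_and_gradients,
      n_classes = as.integer(n_classes),
      name = name
    ),
    class = "classifier_adapter"
  )
}

#' @export
print.classifier_adapter <- function(x, ...) {
  cat(sprintf(
    "<classifier_adapter '%s': %d classes, %s Grad-CAM support>\n",
    x$name, x$n_classes,
    if (is.null(x$conv_activations_and_gradients)) "without" else "with"
  ))
  invisible(x)
}

# Validate a probability vector coming out of an adapter.
check_probabilities <- function(p, n_classes) {
  if (!is.numeric(p) || length(p) != n_classes || any(!is.finite(p))) {
    stop_fundus("adapter returned a malformed probability vector",
                "fundusXAI_adapter_error")
  }
  if (any(p < -1e-9) || abs(sum(p) - 1) > 1e-6) {
    stop_fundus("adapter probabilities must be non-negative and sum to 1",
                "fundusXAI_adapter_error")
  }
  invisible(p)
}

#' Predicted-class policy
#'
#' Attribution always targets the class the model actually predicted (not
#' the true label): the argmax of the adapter's probability vector, with
#' exact ties broken in favor of the lowest class index. Class indices are
#' 0-based so they coincide with DR grades 0-4 for a five-class grader.
#'
#' @param adapter A [classifier_adapter()].
#' @param image Image array accepted by the adapter.
#' @return Integer 0-based class index.
#' @export
target_class_policy <- function(adapter, image) {
  p <- check_probabilities(adapter$predict(image), adapter$n_classes)
  which.max(p) - 1L  # which.max already keeps the first (lowest) index on ties
}
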