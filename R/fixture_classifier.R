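# Fixture classifier: a small fixed-weight convolutional scorer with exact
# analytic gradients, standing in for a trained DR grader at desk scale.
#
# Architecture (input: size x size x 3 RGB in [0,1], default 224):
#   1. 4x4 average pooling                       -> P  (56 x 56 x 3)
#   2. 5x5 'same' convolution, 7 fixed templates -> Apre
#   3. softplus (beta = 25), FOV-interior gate   -> A   (last conv layer)
#   4. global average pooling                    -> z   (7)
#   5. linear 5-class head on z                  -> logits -> softmax
#
# Template channels: [bg] raw brightness; [MA][EX][SE][HE][NV] color-keyed
# center-surround contrast detectors matched to the synthetic palette; [BR]
# generic brightness contrast (optic disc, camera spots). The head is
# centered on a lesion-free reference scene so class scores respond to
# lesion evidence, not to the constant landmark geometry. Class scores are
# pre-softmax logits; both Grad-CAM and Integrated Gradients differentiate
# them (not the softmax output).
#
# Designed behavior: a blank field of view scores grade 0; a pure-
# microaneurysm scene scores grade 1 (MA template drives class 1); exudate
# templates drive class 2, the hemorrhage template class 3, the
# neovascularization template class 4. All class rows put non-negative
# weight on every lesion template so Grad-CAM highlights planted lesions of
# any type under the predicted class.

FIXTURE_BETA <- 25       # softplus sharpness
FIXTURE_POOL <- 4L       # input downsampling factor
FIXTURE_KSIZE <- 5L      # conv kernel side
FIXTURE_CHANNELS <- c("bg", "MA", "EX", "SE", "HE", "NV", "BR")

# color projections for the center-surround detectors (see palette deltas
# in synthetic_data.R); chosen so each lesion class responds strongest on
# its own channel
fixture_color_keys <- function() {
  rbind(
    MA = c(-0.5, -0.5, -2.0),
    EX = c(0.5, 1.0, -1.0),
    SE = c(-1.0, 0.3, 1.5),
    HE = c(-0.8, -0.5, 2.0),
    NV = c(2.0, -2.0, 2.0),
    BR = c(0.5, 1.0, 1.0)
  )
}

# Head weights on the summed-activation scale (rows = classes 0..4, cols =
# FIXTURE_CHANNELS) and class offsets. Each row is a shared *detection*
# vector (equal lesion weights, so the class-activation map treats every
# lesion template comparably and localizes all planted types) plus a small
# *grading* tilt that alone decides the argmax (the shared part contributes
# identically to every logit).
fixture_head <- function() {
  detection <- c(0, 3, 3, 3, 3, 3, 0.6)
  tilt <- rbind(
    c(0.5, 0.3, 0.3, 0.3, 0.3, 0.3, 0.2),  # grade 0: overall fundus presence
    c(0,   4,   0.8, 0.8, 0.6, 0.8, 0.2),  # grade 1: microaneurysms
    c(0,   1.2, 3,   2.5, 1.0, 0.8, 0.2),  # grade 2: exudates
    c(0,   0.8, 1.0, 1.0, 4.5, 0.8, 0.2),  # grade 3: hemorrhage load
    c(0,   0.6, 0.6, 0.6, 0.8, 7,   0.2)   # grade 4: neovascularization
  )
  w <- matrix(rep(detection, each = 5), nrow = 5) + 0.15 * tilt
  colnames(w) <- FIXTURE_CHANNELS
  list(w = w, offset = 0.15 * c(3.0, 0, -0.5, -1.0, -1.0))
}

softplus <- function(x, beta = FIXTURE_BETA) {
  # numerically stable log(1 + exp(beta x)) / beta
  ifelse(x > 0, x + log1p(exp(-beta * x)) / beta, log1p(exp(beta * x)) / beta)
}

softplus_grad <- function(x, beta = FIXTURE_BETA) stats::plogis(beta * x)

# Build the conv kernel stack W[5,5,3,K]: center-surround color detectors
# plus the plain-brightness bg channel.
fixture_kernels <- function() {
  ks <- FIXTURE_KSIZE
  cs <- matrix(0, ks, ks)                # single-cell center vs outer ring:
  cs[c(1, ks), ] <- -1 / 16              # keeps sub-cell lesions undiluted
  cs[, c(1, ks)] <- -1 / 16
  cs[3, 3] <- 1
  keys <- fixture_color_keys()
  K <- length(FIXTURE_CHANNELS)
  W <- array(0, c(ks, ks, 3, K))
  for (ch in 1:3) W[3, 3, ch, 1] <- 1 / 3              # bg: brightness
  for (k in 2:K) {
    d <- keys[FIXTURE_CHANNELS[k], ]
    for (ch in 1:3) W[, , ch, k] <- d[ch] * cs
  }
  W
}

# cache of grid-dependent constants, keyed by image size
fixture_cache <- new.env(parent = emptyenv())

fixture_grid <- function(size) {
  key <- as.character(size)
  if (!is.null(fixture_cache[[key]])) return(fixture_cache[[key]])
  g <- size %/% FIXTURE_POOL
  ks <- FIXTURE_KSIZE
  pad <- (ks - 1L) %/% 2L
  gp <- g + 2L * pad
  # pooling operator: size x g block-indicator / pool
  M <- matrix(0, size, g)
  M[cbind(seq_len(size), rep(seq_len(g), each = FIXTURE_POOL))] <- 1 / FIXTURE_POOL
  # im2col gather indices into the zero-padded (gp x gp x 3) array
  n <- g * g
  pos_r <- rep(seq_len(g), times = g)
  pos_c <- rep(seq_len(g), each = g)
  idx <- matrix(0L, n, ks * ks * 3L)
  q <- 0L
  for (ch in 1:3) for (v in seq_len(ks)) for (u in seq_len(ks)) {
    q <- q + 1L
    idx[, q] <- (ch - 1L) * gp * gp + (pos_c + v - 2L) * gp + (pos_r + u - 1L)
  }
  # flattened kernels matching the idx column order (u fastest, then v, ch)
  W <- fixture_kernels()
  Wmat <- matrix(0, ks * ks * 3L, length(FIXTURE_CHANNELS))
  q <- 0L
  for (ch in 1:3) for (v in seq_len(ks)) for (u in seq_len(ks)) {
    q <- q + 1L
    Wmat[q, ] <- W[u, v, ch, ]
  }
  # FOV-interior gate on the conv grid: receptive fields fully inside the FOV
  ctr <- (size + 1) / 2
  fov_r <- 0.47 * size
  cell_ctr <- (seq_len(g) - 0.5) * FIXTURE_POOL + 0.5
  d2 <- outer((cell_ctr - ctr)^2, (cell_ctr - ctr)^2, "+")
  gate <- (d2 <= (fov_r - 3 * FIXTURE_POOL)^2) * 1
  out <- list(g = g, pad = pad, gp = gp, M = M, idx = idx, Wmat = Wmat,
              gate = as.vector(gate), gate_mat = gate, n = n)
  fixture_cache[[key]] <- out
  out
}

# forward pass; returns every intermediate needed for the backward passes
fixture_forward <- function(x, grid) {
  g <- grid$g; gp <- grid$gp
  P <- array(0, c(g, g, 3))
  for (ch in 1:3) P[, , ch] <- t(grid$M) %*% x[, , ch] %*% grid$M
  Ppad <- array(0, c(gp, gp, 3))
  Ppad[(grid$pad + 1):(gp - grid$pad), (grid$pad + 1):(gp - grid$pad), ] <- P
  col <- matrix(Ppad[grid$idx], nrow = grid$n)
  Apre <- col %*% grid$Wmat                      # n x K
  A <- softplus(Apre) * grid$gate                # gated last-conv activations
  z <- colMeans(A)
  head <- fixture_head()
  S_ref <- fixture_reference_sums(dim(x)[1])
  logits <- as.vector(head$w %*% (z * grid$n - S_ref)) + head$offset
  list(P = P, col = col, Apre = Apre, A = A, z = z, logits = logits,
       probs = {
         e <- exp(logits - max(logits)); e / sum(e)
       })
}

# summed activations of the lesion-free reference scene (head centering);
# computed once per image size from a deterministic blank scene
fixture_reference_sums <- function(size) {
  key <- paste0("ref", size)
  if (!is.null(fixture_cache[[key]])) return(fixture_cache[[key]])
  blank <- generate_scene(scene_spec(image_size = size, seed = 999L,
                                     noise_sd = 0), image_id = "reference")
  grid <- fixture_grid(size)
  # inline forward up to z to avoid recursion into the head
  g <- grid$g; gp <- grid$gp
  P <- array(0, c(g, g, 3))
  for (ch in 1:3) P[, , ch] <- t(grid$M) %*% blank$image[, , ch] %*% grid$M
  Ppad <- array(0, c(gp, gp, 3))
  Ppad[(grid$pad + 1):(gp - grid$pad), (grid$pad + 1):(gp - grid$pad), ] <- P
  col <- matrix(Ppad[grid$idx], nrow = grid$n)
  S <- colSums(softplus(col %*% grid$Wmat) * grid$gate)
  fixture_cache[[key]] <- S
  S
}

# gradient of logit[class] w.r.t. the input image (exact backprop)
fixture_input_gradient <- function(x, class0, grid) {
  fw <- fixture_forward(x, grid)
  head <- fixture_head()
  wrow <- head$w[class0 + 1L, ]                 # d logit / d A (per channel)
  dApre <- (grid$gate * softplus_grad(fw$Apre)) *
    matrix(wrow, nrow = grid$n, ncol = length(wrow), byrow = TRUE)
  dcol <- dApre %*% t(grid$Wmat)                # n x 75
  gp <- grid$gp
  dPpad <- numeric(gp * gp * 3L)
  for (q in seq_len(ncol(dcol))) {
    ii <- grid$idx[, q]
    dPpad[ii] <- dPpad[ii] + dcol[, q]
  }
  dPpad <- array(dPpad, c(gp, gp, 3))
  core <- (grid$pad + 1):(gp - grid$pad)
  dP <- dPpad[core, core, , drop = FALSE]
  size <- dim(x)[1]
  dx <- array(0, c(size, size, 3))
  rep_idx <- rep(seq_len(grid$g), each = FIXTURE_POOL)
  for (ch in 1:3) {
    dx[, , ch] <- dP[rep_idx, rep_idx, ch] / (FIXTURE_POOL^2)
  }
  dx
}

#' Fixture classifier adapter
#'
#' A deterministic, fixed-weight five-grade scorer over synthetic fundus
#' scenes, exposing the full [classifier_adapter()] contract with exact
#' analytic gradients: probabilities, input gradients of the pre-softmax
#' class score, and the activations/gradients of its last convolutional
#' layer (seven gated template channels on a `size/4` grid). Designed
#' responses: a lesion-free scene scores grade 0, a pure-microaneurysm scene
#' grade 1, exudates drive grade 2, heavy hemorrhage load grade 3,
#' neovascularization grade 4; template responses localize on the planted
#' shapes, so Grad-CAM and Integrated Gradients highlight them.
#'
#' @param image_size Side length the adapter expects (default 224).
#' @return A [classifier_adapter()].
#' @export
fixture_classifier <- function(image_size = 224L) {
  grid <- fixture_grid(image_size)
  force(fixture_reference_sums(image_size))
  check_image <- function(image) {
    if (!identical(dim(image), c(image_size, image_size, 3L)) &&
        !identical(dim(image), as.integer(c(image_size, image_size, 3)))) {
      stop_fundus(sprintf("fixture expects a %dx%dx3 image", image_size,
                          image_size), "fundusXAI_input_error")
    }
  }
  classifier_adapter(
    predict = function(image) {
      check_image(image)
      fixture_forward(image, grid)$probs
    },
    input_gradient = function(image, class_index) {
      check_image(image)
      fixture_input_gradient(image, class_index, grid)
    },
    conv_activations_and_gradients = function(image, class_index) {
      check_image(image)
      fw <- fixture_forward(image, grid)
      head <- fixture_head()
      K <- length(FIXTURE_CHANNELS)
      acts <- array(fw$A, c(grid$g, grid$g, K))
      grads <- array(rep(head$w[class_index + 1L, ], each = grid$n),
                     c(grid$g, grid$g, K))
      list(activations = acts, gradients = grads)
    },
    n_classes = 5L,
    name = sprintf("fixture-cnn-%d", image_size)
  )
}

# forward details for diagnostics and tests
fixture_forward_details <- function(image) {
  grid <- fixture_grid(dim(image)[1])
  fw <- fixture_forward(image, grid)
  list(z = fw$z, S = fw$z * grid$n, logits = fw$logits, probs = fw$probs,
       S_ref = fixture_reference_sums(dim(image)[1]))
}
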