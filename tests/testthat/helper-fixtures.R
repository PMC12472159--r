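# Shared test fixtures and independent oracles. Oracles are deliberately
# naive (loops, enumeration) and never call the code paths they check.

# ---- toy adapters ---------------------------------------------------------

# Affine two-class model: score_1(x) = sum(w * x) + b, score_0 = 0.
linear_adapter <- function(w, b = 0) {
  classifier_adapter(
    predict = function(image) {
      s <- sum(w * image) + b
      e <- exp(c(0, s) - max(0, s))
      e / sum(e)
    },
    input_gradient = function(image, class_index) {
      g <- image
      g[] <- if (class_index == 1L) w else 0
      g
    },
    n_classes = 2L, name = "linear"
  )
}

# Scalar quadratic model: score_1(x) = x^2 (1x1x1 "image").
quad_adapter <- function() {
  classifier_adapter(
    predict = function(image) c(0.5, 0.5),
    input_gradient = function(image, class_index) {
      g <- image
      g[] <- if (class_index == 1L) 2 * as.numeric(image) else 0
      g
    },
    n_classes = 2L, name = "quadratic"
  )
}

# Model whose class-1 score is the spatial mean of a single feature map
# that simply equals the (matrix) input.
meanmap_adapter <- function() {
  classifier_adapter(
    predict = function(image) c(0.5, 0.5),
    input_gradient = function(image, class_index) {
      g <- image
      g[] <- if (class_index == 1L) 1 / length(image) else 0
      g
    },
    conv_activations_and_gradients = function(image, class_index) {
      A <- array(image, c(dim(image), 1L))
      G <- array(if (class_index == 1L) 1 / length(image) else 0,
                 c(dim(image), 1L))
      list(activations = A, gradients = G)
    },
    n_classes = 2L, name = "meanmap"
  )
}

# Adapter with a fixed probability vector (for the class-policy tests).
const_prob_adapter <- function(p) {
  classifier_adapter(
    predict = function(image) p,
    input_gradient = function(image, class_index) image * 0,
    n_classes = length(p), name = "const"
  )
}

# ---- cached scenes / fixture model ---------------------------------------

.fx_cache <- new.env(parent = emptyenv())

cached_fixture <- function() {
  if (is.null(.fx_cache$adapter)) .fx_cache$adapter <- fixture_classifier()
  .fx_cache$adapter
}

cached_scene <- function(grade, seed) {
  key <- sprintf("g%d_s%d", grade, seed)
  if (is.null(.fx_cache[[key]])) {
    .fx_cache[[key]] <- generate_scene(sample_scene_spec(grade, seed = seed),
                                       image_id = key)
  }
  .fx_cache[[key]]
}

# ---- oracles --------------------------------------------------------------

# Cohen's kappa from an explicit 2x2 joint table (a=++, b=+-, c=-+, d=--).
kappa_oracle_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  po <- (a + d) / n
  pA <- (a + b) / n
  pB <- (a + c) / n
  pe <- pA * pB + (1 - pA) * (1 - pB)
  if (pe == 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

# binary vectors realizing a 2x2 joint table
vectors_from_2x2 <- function(a, b, c, d) {
  list(A = c(rep(1, a), rep(1, b), rep(0, c), rep(0, d)),
       B = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)))
}

# closed-form bilinear interpolation at input pixel-center coords (r, c)
bilinear_point_oracle <- function(m, r, c) {
  r <- min(max(r, 1), nrow(m)); c <- min(max(c, 1), ncol(m))
  r0 <- min(floor(r), nrow(m) - 1); c0 <- min(floor(c), ncol(m) - 1)
  if (nrow(m) == 1) r0 <- 1
  if (ncol(m) == 1) c0 <- 1
  fr <- r - r0; fc <- c - c0
  m[r0, c0] * (1 - fr) * (1 - fc) +
    m[r0, min(c0 + 1, ncol(m))] * (1 - fr) * fc +
    m[min(r0 + 1, nrow(m)), c0] * fr * (1 - fc) +
    m[min(r0 + 1, nrow(m)), min(c0 + 1, ncol(m))] * fr * fc
}

# exhaustive 8-connected component enumeration by repeated dilation
components_oracle <- function(m) {
  comps <- list()
  left <- which(m == 1, arr.ind = TRUE)
  seen <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(left))) {
    p <- left[i, ]
    if (seen[p[1], p[2]]) next
    members <- matrix(p, ncol = 2)
    seen[p[1], p[2]] <- TRUE
    repeat {
      grew <- FALSE
      for (j in seq_len(nrow(members))) {
        for (dr in -1:1) for (dc in -1:1) {
          r <- members[j, 1] + dr; c_ <- members[j, 2] + dc
          if (r >= 1 && r <= nrow(m) && c_ >= 1 && c_ <= ncol(m) &&
              m[r, c_] == 1 && !seen[r, c_]) {
            members <- rbind(members, c(r, c_))
            seen[r, c_] <- TRUE
            grew <- TRUE
          }
        }
      }
      if (!grew) break
    }
    comps[[length(comps) + 1L]] <- members
  }
  comps
}

# AUC by exhaustive pair enumeration (ties count 0.5)
auc_pairs_oracle <- function(labels, scores) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# rasterized disc as a plain matrix (test geometry helper)
disc_fixture <- function(size, row, col, radius) {
  d2 <- outer((seq_len(size) - row)^2, (seq_len(size) - col)^2, "+")
  (d2 <= radius^2) * 1
}

# linear-interpolation percentile by explicit sorting (quantile type 7)
percentile_oracle <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}
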