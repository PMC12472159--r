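# Synthetic fundus scenes: circular field of view, optic disc, macula, and
# planted lesions (microaneurysms, hard/soft exudates, hemorrhages,
# neovascular tufts) with pixel-exact per-lesion masks and an ICDR-consistent
# grade label. Not photorealistic: the point is controlled geometry and
# color contrast so attribution, thresholding and overlap logic can be
# validated end to end.

# Palette: RGB in [0,1]. Lesion classes are separated by deliberate color
# signatures so fixed linear templates can tell them apart (hemorrhages get
# a slight blue shift relative to microaneurysms; neovascular tufts a
# stronger one).
FUNDUS_COLORS <- list(
  background = c(0.80, 0.40, 0.10),
  OD = c(1.00, 0.92, 0.55),
  MC = c(0.55, 0.22, 0.06),
  MA = c(0.50, 0.10, 0.02),
  EX = c(1.00, 0.95, 0.30),
  SE = c(0.92, 0.88, 0.55),
  HE = c(0.40, 0.06, 0.18),
  NV = c(0.75, 0.05, 0.45),
  spot = c(0.75, 0.75, 0.85)
)

#' Scene specification for the synthetic fundus generator
#'
#' Geometry is expressed as fractions of the image side so specs scale.
#' Defaults give a 224 px macula-centered fundus: field of view radius 0.47,
#' optic disc (radius 0.08) nasally displaced, macula (radius 0.055) at the
#' center, no camera-artifact spot. Lesion counts default to zero (a DR-0
#' scene); hemorrhage placement cycles through the four axis-aligned
#' quadrants so per-quadrant counts stay balanced.
#'
#' @param image_size Side length in pixels.
#' @param seed Integer RNG seed; the generator is deterministic given the
#'   spec.
#' @param n_ma,n_ex,n_se,n_he,n_nv Lesion counts to plant.
#' @param ma_radius,ex_radius,se_radius,he_radius Radius ranges (px, at
#'   `image_size` 224; scaled proportionally otherwise).
#' @param nv_radius Radius of a neovascular tuft (its curly vessel strokes
#'   stay within this radius).
#' @param fov_radius_frac Field-of-view radius as a fraction of the side.
#' @param artifact_spot `NULL`, or `list(row_frac=, col_frac=, radius=)` for
#'   a bright camera-artifact spot that gets *no* mask (a confounder).
#' @param noise_sd Gaussian pixel noise added inside the FOV.
#' @return A `scene_spec`.
#' @export
scene_spec <- function(image_size = 224L, seed = 1L,
                       n_ma = 0L, n_ex = 0L, n_se = 0L, n_he = 0L, n_nv = 0L,
                       ma_radius = c(2, 4), ex_radius = c(2, 5),
                       se_radius = c(4, 8), he_radius = c(3, 6),
                       nv_radius = 11,
                       fov_radius_frac = 0.47,
                       artifact_spot = NULL,
                       noise_sd = 0.01) {
  counts <- c(n_ma, n_ex, n_se, n_he, n_nv)
  if (any(counts < 0)) {
    stop_fundus("scene_spec: lesion counts must be non-negative",
                "fundusXAI_input_error")
  }
  structure(
    list(image_size = as.integer(image_size), seed = as.integer(seed),
         n_ma = as.integer(n_ma), n_ex = as.integer(n_ex),
         n_se = as.integer(n_se), n_he = as.integer(n_he),
         n_nv = as.integer(n_nv),
         ma_radius = ma_radius, ex_radius = ex_radius, se_radius = se_radius,
         he_radius = he_radius, nv_radius = nv_radius,
         fov_radius_frac = fov_radius_frac,
         od_center_frac = c(0.48, 0.70), od_radius_frac = 0.080,
         mc_center_frac = c(0.50, 0.42), mc_radius_frac = 0.055,
         artifact_spot = artifact_spot, noise_sd = noise_sd),
    class = "scene_spec"
  )
}

#' ICDR-style grade from a lesion inventory
#'
#' Decision rule (a deliberately reduced reading of the clinical scale, see
#' the package vignette): grade 0 with no lesions at all; grade 1 when only
#' microaneurysms are present; grade 4 whenever neovascularization is
#' present; grade 3 when every one of the four quadrants holds at least
#' `severe_he_per_quadrant` hemorrhages (default 21, i.e. "more than 20")
#' and there is no neovascularization; grade 2 otherwise. Venous beading and
#' IRMA, which also enter the clinical severe-DR definition, are not
#' modeled.
#'
#' @param n_ma,n_ex,n_se,n_nv Non-negative lesion counts.
#' @param he Hemorrhage counts: either a length-4 vector of per-quadrant
#'   counts, or a scalar total (a scalar cannot certify the per-quadrant
#'   severe clause, so it can yield at most grade 2).
#' @param severe_he_per_quadrant Per-quadrant hemorrhage count at or above
#'   which (in all four quadrants) the scene is severe.
#' @return Integer grade 0-4.
#' @export
grade_rule <- function(n_ma = 0, n_ex = 0, n_se = 0, he = 0, n_nv = 0,
                       severe_he_per_quadrant = 21L) {
  counts <- c(n_ma, n_ex, n_se, he, n_nv)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_fundus("grade_rule: counts must be non-negative integers",
                "fundusXAI_input_error")
  }
  if (!length(he) %in% c(1L, 4L)) {
    stop_fundus("grade_rule: he must be a scalar total or 4 quadrant counts",
                "fundusXAI_input_error")
  }
  n_he <- sum(he)
  if (n_nv > 0) return(4L)
  if (n_ma + n_ex + n_se + n_he == 0) return(0L)
  if (n_ma > 0 && n_ex + n_se + n_he == 0) return(1L)
  if (length(he) == 4L && all(he >= severe_he_per_quadrant)) return(3L)
  2L
}

# quadrant of a point about the image center: 1 TL, 2 TR, 3 BL, 4 BR
point_quadrant <- function(row, col, size) {
  mid <- (size + 1) / 2
  1L + (col > mid) + 2L * (row > mid)
}

# rasterized disc: 0/1 matrix, pixel centers within `radius` of (row, col)
disc_mask <- function(size, row, col, radius) {
  dr <- outer((seq_len(size) - row)^2, (seq_len(size) - col)^2, "+")
  (dr <= radius^2) * 1
}

# Sample a blob center uniformly inside the FOV, outside landmarks, at least
# `sep` from previous same-type centers, optionally inside one quadrant.
place_blob <- function(size, fov_r, radius, od, mc, prev, sep,
                       quadrant = NULL, max_tries = 400L) {
  ctr <- (size + 1) / 2
  for (i in seq_len(max_tries)) {
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- sqrt(stats::runif(1)) * (fov_r - radius - 3)
    row <- ctr + rad * sin(ang)
    col <- ctr + rad * cos(ang)
    if (!is.null(quadrant) && point_quadrant(row, col, size) != quadrant) next
    if (sqrt(sum((c(row, col) - od$center)^2)) < od$radius + radius + 2) next
    if (sqrt(sum((c(row, col) - mc$center)^2)) < mc$radius + radius + 2) next
    ok <- TRUE
    for (p in prev) {
      if (sqrt(sum((c(row, col) - p$center)^2)) < p$radius + radius + sep) {
        ok <- FALSE; break
      }
    }
    if (ok) return(list(center = c(row, col), radius = radius))
  }
  stop_fundus("generate_scene: could not place a lesion inside the FOV",
              "fundusXAI_generation_error")
}

# Rasterize a neovascular tuft: a few curly strokes radiating from a center,
# all within `radius`. Returns the 0/1 mask of stroke pixels.
nv_tuft_mask <- function(size, center, radius, n_strokes = 5L) {
  m <- matrix(0, size, size)
  for (s in seq_len(n_strokes)) {
    theta0 <- stats::runif(1, 0, 2 * pi)
    curl <- stats::runif(1, -2, 2)
    t <- seq(0, 1, length.out = 80)
    rr <- center[1] + t * radius * 0.9 * sin(theta0 + curl * t)
    cc <- center[2] + t * radius * 0.9 * cos(theta0 + curl * t)
    for (i in seq_along(t)) {
      r0 <- round(rr[i]); c0 <- round(cc[i])
      for (dr in -1:1) for (dc in -1:1) {
        r <- r0 + dr; c_ <- c0 + dc
        if (r >= 1 && r <= size && c_ >= 1 && c_ <= size &&
            (rr[i] - r)^2 + (cc[i] - c_)^2 <= 1.3^2) {
          m[r, c_] <- 1
        }
      }
    }
  }
  m
}

paint <- function(img, mask, color) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask == 1] <- color[ch]
    img[, , ch] <- plane
  }
  img
}

#' Generate a synthetic fundus scene
#'
#' Deterministic for a fixed spec (including its seed): renders the
#' fundus-like background (dark outside the circular FOV, radial brightness
#' falloff inside, mild pixel noise), the optic disc and macula, all
#' requested lesions, and the optional camera-artifact spot; returns
#' pixel-exact binary masks for every lesion type plus the landmarks and the
#' ICDR-consistent grade from [grade_rule()]. Lesion blobs of the same type
#' do not overlap each other or the landmarks; hemorrhages are distributed
#' round-robin over the four quadrants.
#'
#' @param spec A [scene_spec()].
#' @param image_id Identifier stored in the sample and its masks.
#' @return A `synthetic_sample`: list with `image` (size x size x 3 array in
#'   `[0,1]`), `masks` (named list of `lesion_mask` for MA, EX, SE, HE, NV,
#'   OD, MC — empty types included), `grade`, `he_quadrants`, `spec`,
#'   `image_id`.
#' @export
generate_scene <- function(spec, image_id = sprintf("scene_%04d", spec$seed)) {
  stopifnot(inherits(spec, "scene_spec"))
  s <- spec$image_size
  scale <- s / 224
  ctr <- (s + 1) / 2
  fov_r <- spec$fov_radius_frac * s
  od <- list(center = spec$od_center_frac * s, radius = spec$od_radius_frac * s)
  mc <- list(center = spec$mc_center_frac * s, radius = spec$mc_radius_frac * s)

  with_seed(spec$seed, {
    dist2 <- outer((seq_len(s) - ctr)^2, (seq_len(s) - ctr)^2, "+")
    fov <- (dist2 <= fov_r^2) * 1
    falloff <- 1 - 0.25 * pmin(dist2 / fov_r^2, 1)
    img <- array(0, c(s, s, 3))
    for (ch in 1:3) {
      img[, , ch] <- FUNDUS_COLORS$background[ch] * falloff * fov
    }

    od_mask <- disc_mask(s, od$center[1], od$center[2], od$radius)
    mc_mask <- disc_mask(s, mc$center[1], mc$center[2], mc$radius)
    img <- paint(img, od_mask, FUNDUS_COLORS$OD)
    img <- paint(img, mc_mask, FUNDUS_COLORS$MC)

    blob_types <- list(
      MA = list(n = spec$n_ma, r = spec$ma_radius * scale),
      EX = list(n = spec$n_ex, r = spec$ex_radius * scale),
      SE = list(n = spec$n_se, r = spec$se_radius * scale),
      HE = list(n = spec$n_he, r = spec$he_radius * scale)
    )
    masks <- list()
    he_quadrants <- integer(4)
    all_placed <- list()  # cross-type: planted shapes never overlap
    for (lt in names(blob_types)) {
      bt <- blob_types[[lt]]
      mask <- matrix(0, s, s)
      for (j in seq_len(bt$n)) {
        radius <- stats::runif(1, bt$r[1], bt$r[2])
        quad <- if (lt == "HE") ((j - 1L) %% 4L) + 1L else NULL
        blob <- place_blob(s, fov_r, radius, od, mc, all_placed, sep = 2,
                           quadrant = quad)
        all_placed[[length(all_placed) + 1L]] <- blob
        mask <- pmax(mask, disc_mask(s, blob$center[1], blob$center[2],
                                     blob$radius))
        if (lt == "HE") {
          q <- point_quadrant(blob$center[1], blob$center[2], s)
          he_quadrants[q] <- he_quadrants[q] + 1L
        }
        img <- paint(img, disc_mask(s, blob$center[1], blob$center[2],
                                    blob$radius), FUNDUS_COLORS[[lt]])
      }
      masks[[lt]] <- new_lesion_mask(mask, lt, image_id)
    }

    nv_mask <- matrix(0, s, s)
    for (j in seq_len(spec$n_nv)) {
      blob <- place_blob(s, fov_r, spec$nv_radius * scale, od, mc, all_placed,
                         sep = 4)
      all_placed[[length(all_placed) + 1L]] <- blob
      tuft <- nv_tuft_mask(s, blob$center, blob$radius)
      nv_mask <- pmax(nv_mask, tuft)
      img <- paint(img, tuft, FUNDUS_COLORS$NV)
    }
    masks$NV <- new_lesion_mask(nv_mask, "NV", image_id)
    masks$OD <- new_lesion_mask(od_mask, "OD", image_id)
    masks$MC <- new_lesion_mask(mc_mask, "MC", image_id)

    if (!is.null(spec$artifact_spot)) {
      sp <- spec$artifact_spot
      spot <- disc_mask(s, sp$row_frac * s, sp$col_frac * s,
                        sp$radius * scale)
      img <- paint(img, spot * fov, FUNDUS_COLORS$spot)  # no mask on purpose
    }

    if (spec$noise_sd > 0) {
      noise <- array(stats::rnorm(s * s * 3, 0, spec$noise_sd), c(s, s, 3))
      for (ch in 1:3) noise[, , ch] <- noise[, , ch] * fov
      img <- pmin(pmax(img + noise, 0), 1)
    }

    grade <- grade_rule(
      n_ma = spec$n_ma, n_ex = spec$n_ex, n_se = spec$n_se,
      he = if (spec$n_he > 0) he_quadrants else 0L, n_nv = spec$n_nv)

    structure(
      list(image = img, masks = masks, grade = grade,
           he_quadrants = he_quadrants, spec = spec, image_id = image_id),
      class = "synthetic_sample"
    )
  })
}

#' @export
print.synthetic_sample <- function(x, ...) {
  planted <- names(Filter(function(m) sum(m$values) > 0, x$masks))
  cat(sprintf("<synthetic_sample %s: grade %d, %dpx, planted: %s>\n",
              x$image_id, x$grade, x$spec$image_size,
              paste(planted, collapse = " ")))
  invisible(x)
}

#' Draw a scene spec typical of a DR grade
#'
#' Convenience sampler producing lesion inventories whose [grade_rule()]
#' grade equals `grade`: DR-1 scenes carry only microaneurysms, DR-3 scenes
#' carry 96 hemorrhages (24 per quadrant, satisfying the "more than 20 in
#' each quadrant" clause), DR-4 scenes add neovascular tufts.
#'
#' @param grade Target DR grade 0-4.
#' @param seed RNG seed (also the scene seed).
#' @param image_size Image side in pixels.
#' @return A [scene_spec()].
#' @export
sample_scene_spec <- function(grade, seed = 1L, image_size = 224L) {
  stopifnot(grade %in% 0:4)
  with_seed(seed * 7L + grade, {
    ri <- function(lo, hi) sample(lo:hi, 1)
    args <- switch(as.character(grade),
      "0" = list(),
      "1" = list(n_ma = ri(3, 8)),
      "2" = list(n_ma = ri(2, 6), n_ex = ri(2, 6), n_se = ri(0, 2),
                 n_he = ri(3, 8)),
      "3" = list(n_ma = ri(2, 5), n_ex = ri(2, 5), n_se = ri(0, 2),
                 n_he = 96L, he_radius = c(2, 4)),
      "4" = list(n_ma = ri(2, 4), n_ex = ri(2, 4), n_he = ri(4, 8),
                 n_nv = ri(1, 2))
    )
    do.call(scene_spec, c(list(image_size = image_size, seed = seed), args))
  })
}

#' Write a synthetic sample to the on-disk layout the pipeline reads
#'
#' `images/<id>.png`, `masks/<lesion_type>/<id>.png`, and a row for the
#' manifest (`image_id`, `grade`).
#'
#' @param sample A `synthetic_sample`.
#' @param dir Output directory.
#' @return Named list with the manifest row, invisibly.
#' @export
write_scene <- function(sample, dir) {
  stopifnot(inherits(sample, "synthetic_sample"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(sample$image,
                file.path(dir, "images", paste0(sample$image_id, ".png")))
  for (lt in names(sample$masks)) {
    d <- file.path(dir, "masks", lt)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_mask_png(sample$masks[[lt]],
                   file.path(d, paste0(sample$image_id, ".png")))
  }
  invisible(list(image_id = sample$image_id, grade = sample$grade))
}
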