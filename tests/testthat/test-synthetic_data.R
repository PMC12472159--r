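# Scene generator, grade rule and fixture-classifier behavior.

test_that("grade rule follows the reduced ICDR decision table", {
  expect_equal(grade_rule(), 0L)
  expect_equal(grade_rule(n_ma = 3), 1L)
  expect_equal(grade_rule(n_ma = 1, n_ex = 1), 2L)
  expect_equal(grade_rule(he = 5), 2L)
  expect_equal(grade_rule(he = c(21, 21, 21, 21)), 3L)
  expect_equal(grade_rule(he = c(21, 21, 21, 20)), 2L)  # one quadrant short
  expect_equal(grade_rule(he = c(30, 30, 30, 30), n_nv = 1), 4L)
  expect_equal(grade_rule(n_nv = 1), 4L)
  expect_error(grade_rule(n_ma = -1), class = "fundusXAI_input_error")
  expect_error(grade_rule(he = c(1, 2)), class = "fundusXAI_input_error")
})

test_that("grade rule matches a hand-written decision-table oracle on a grid", {
  oracle <- function(ma, ex, he4, nv) {
    if (nv > 0) return(4L)
    if (ma + ex + sum(he4) == 0) return(0L)
    if (ma > 0 && ex + sum(he4) == 0) return(1L)
    if (min(he4) >= 21) return(3L)
    2L
  }
  for (ma in c(0, 1, 5)) for (ex in c(0, 2)) for (nv in c(0, 1)) {
    for (q in list(c(0, 0, 0, 0), c(5, 5, 5, 5), c(21, 21, 21, 21),
                   c(25, 25, 25, 20))) {
      expect_identical(grade_rule(n_ma = ma, n_ex = ex, he = q, n_nv = nv),
                       oracle(ma, ex, q, nv))
    }
  }
})

test_that("scene generation is bit-deterministic for a fixed spec", {
  spec <- scene_spec(seed = 17, n_ma = 4, n_ex = 3, n_he = 5)
  s1 <- generate_scene(spec)
  s2 <- generate_scene(spec)
  expect_identical(s1$image, s2$image)
  for (lt in names(s1$masks)) {
    expect_identical(s1$masks[[lt]]$values, s2$masks[[lt]]$values)
  }
})

test_that("zero-lesion specs give grade 0 and empty lesion masks", {
  s <- generate_scene(scene_spec(seed = 5))
  expect_equal(s$grade, 0L)
  for (lt in c("MA", "EX", "SE", "HE", "NV")) {
    expect_equal(sum(s$masks[[lt]]$values), 0)
  }
  expect_gt(sum(s$masks$OD$values), 0)  # landmarks always present
  expect_gt(sum(s$masks$MC$values), 0)
})

test_that("planted mask areas match the rasterized-disc oracle", {
  spec <- scene_spec(seed = 23, n_ma = 5, ma_radius = c(2, 2))
  s <- generate_scene(spec)
  area <- sum(s$masks$MA$values)
  expect_gte(area, 5 * pi * 1.5^2)
  expect_lte(area, 5 * pi * 2.5^2)
})

test_that("planted shapes lie inside the FOV and register with the image", {
  s <- generate_scene(scene_spec(seed = 31, n_ma = 3, n_ex = 3, n_se = 1,
                                 n_he = 6, n_nv = 1))
  size <- s$spec$image_size
  fov <- disc_fixture(size, (size + 1) / 2, (size + 1) / 2,
                      s$spec$fov_radius_frac * size)
  for (lt in c("MA", "EX", "SE", "HE", "NV")) {
    m <- s$masks[[lt]]$values
    expect_true(all(fov[m == 1] == 1))
    # image pixels under the mask carry the lesion color (pre-noise within
    # noise tolerance)
    col <- fundusXAI:::FUNDUS_COLORS[[lt]]
    for (ch in 1:3) {
      vals <- s$image[, , ch][m == 1]
      expect_lt(max(abs(vals - col[ch])), 6 * s$spec$noise_sd + 1e-9)
    }
  }
})

test_that("grade-3 scenes satisfy the per-quadrant hemorrhage clause", {
  s <- generate_scene(sample_scene_spec(3, seed = 41))
  expect_equal(s$grade, 3L)
  expect_true(all(s$he_quadrants >= 21))
  expect_equal(sum(s$he_quadrants), s$spec$n_he)
})

test_that("fixture classifier exposes a valid adapter contract", {
  adapter <- cached_fixture()
  sc <- cached_scene(0, 401)
  p <- adapter$predict(sc$image)
  expect_length(p, 5)
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  g <- adapter$input_gradient(sc$image, 0L)
  expect_identical(dim(g), dim(sc$image))
  ag <- adapter$conv_activations_and_gradients(sc$image, 0L)
  expect_identical(dim(ag$activations), dim(ag$gradients))
  expect_true(all(ag$activations >= 0))
})

test_that("fixture designed responses: blank scene grade 0, pure-MA grade 1", {
  adapter <- cached_fixture()
  blank <- generate_scene(scene_spec(seed = 51))
  expect_equal(target_class_policy(adapter, blank$image), 0L)

  ma_scene <- generate_scene(scene_spec(seed = 52, n_ma = 7))
  expect_equal(target_class_policy(adapter, ma_scene$image), 1L)
  # Grad-CAM at the 90th percentile hits the MA mask
  raw <- grad_cam(adapter, ma_scene$image, 1L)
  h <- normalize_heatmap(resize_to_image(raw, dim(ma_scene$image)[1:2]),
                         "gradcam")
  act <- percentile_threshold(h)
  expect_true(intersect_activation(act, ma_scene$masks$MA)$hit)
})

test_that("neovascular scenes drive the proliferative class", {
  adapter <- cached_fixture()
  nv_scene <- generate_scene(scene_spec(seed = 53, n_nv = 2))
  expect_equal(target_class_policy(adapter, nv_scene$image), 4L)
})

test_that("the camera-artifact spot attracts attribution without any mask", {
  adapter <- cached_fixture()
  spot <- list(row_frac = 0.78, col_frac = 0.5, radius = 8)
  s_spot <- generate_scene(scene_spec(seed = 54, artifact_spot = spot))
  expect_false("spot" %in% names(s_spot$masks))
  cls <- target_class_policy(adapter, s_spot$image)
  raw <- grad_cam(adapter, s_spot$image, cls)
  h <- normalize_heatmap(resize_to_image(raw, c(224, 224)), "gradcam")
  spot_mask <- disc_fixture(224, 0.78 * 224, 0.5 * 224, 8)
  act <- percentile_threshold(h)
  # the confounder region reaches the top-decile activation set
  expect_true(intersect_activation(act, spot_mask)$hit)
})

test_that("scene writing produces the expected file layout", {
  d <- withr::local_tempdir()
  s <- generate_scene(scene_spec(seed = 61, n_ma = 2), image_id = "demo")
  write_scene(s, d)
  expect_true(file.exists(file.path(d, "images", "demo.png")))
  for (lt in names(s$masks)) {
    expect_true(file.exists(file.path(d, "masks", lt, "demo.png")))
  }
  rt <- load_mask(file.path(d, "masks", "MA", "demo.png"), "MA")
  expect_identical(rt$values, s$masks$MA$values)
})
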