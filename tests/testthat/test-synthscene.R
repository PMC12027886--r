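test_that("grade assignment follows curvature and size thresholds", {
  th <- grade_thresholds()
  expect_equal(assign_grade(cucumber_params(26, 5, 3), th), "AL")
  expect_equal(assign_grade(cucumber_params(26, 90, 3), th), "CM")
  expect_equal(assign_grade(cucumber_params(17, 30, 3), th), "BS")
  # boundary behaviour: bend at the A cut-off stays A, length at the M
  # cut-off is M
  expect_equal(assign_grade(cucumber_params(18, 20, 3), th), "AM")
  # a long bent cucumber clamps to the M size class (no BL/CL grade exists)
  expect_equal(assign_grade(cucumber_params(25, 40, 3), th), "BM")
  expect_equal(assign_grade(cucumber_params(25, 100, 3), th), "CM")
})

test_that("non-monotone thresholds are a configuration error", {
  expect_error(grade_thresholds(bend_a_max_deg = 70), class = "cg_config_error")
  expect_error(grade_thresholds(size_m_min_cm = 30), class = "cg_config_error")
})

test_that("invalid cucumber parameters are rejected", {
  expect_error(cucumber_params(20, -1, 3), class = "cg_config_error")
  expect_error(cucumber_params(20, 190, 3), class = "cg_config_error")
  # radius of curvature 20*180/(pi*170) ~ 6.7/2 -> a 7 cm tube self-intersects
  expect_error(cucumber_params(20, 170, 14), class = "cg_config_error")
})

test_that("sampled parameters regrade to their target grade for all grades", {
  th <- grade_thresholds()
  for (g in GRADES) {
    set.seed(7)
    for (i in 1:25) {
      p <- sample_params(g, th)
      expect_equal(assign_grade(p, th), g)
    }
  }
})

test_that("parameter sampling is deterministic under a seed", {
  set.seed(123); a <- sample_params("BM")
  set.seed(123); b <- sample_params("BM")
  expect_identical(a, b)
  set.seed(1); p <- sample_params("AL")
  expect_lte(p$bend_angle_deg, 20)
  expect_gte(p$arc_length_cm, 24)
})

test_that("rendered marker centers span the board at the render scale", {
  sc <- render_scene(scene_spec(), canonical_tube())
  mk <- sc$truth$marker_centers
  expect_equal(unname(mk["tr", 1] - mk["tl", 1]), 400)
  expect_equal(unname(mk["bl", 2] - mk["tl", 2]), 300)
  expect_equal(dim(sc$image), c(340L, 440L, 3L))
})

test_that("straight tube rasterizes to its exact analytic footprint", {
  # grid-aligned 20 x 3 cm tube: mask bounding box is exactly length x
  # thickness and the pixel count matches the analytic area
  sc <- render_scene(scene_spec(), canonical_tube())
  mask <- sc$truth$mask
  rows <- which(rowSums(mask) > 0); cols <- which(colSums(mask) > 0)
  expect_equal(diff(range(rows)) + 1L, 200L)
  expect_equal(diff(range(cols)) + 1L, 30L)
  expect_equal(sum(mask), 6000L)
  expect_equal(sc$truth$analytic_area_cm2, 60)
})

test_that("rasterized area converges to the analytic arc-tube area", {
  for (p in grade_panel()[c("AM", "BM", "CM", "CS")]) {
    a10 <- sum(render_scene(scene_spec(), p)$truth$mask) / 100
    a20 <- sum(render_scene(scene_spec(render_px_per_cm = 20), p)$truth$mask) / 400
    truth <- p$arc_length_cm * p$thickness_cm
    expect_lt(abs(a10 - truth) / truth, 0.03)
    expect_lt(abs(a20 - truth) / truth, 0.015)
  }
})

test_that("rendering fails when the cucumber would hit a marker or border", {
  # centered over the top-left corner region: collides with the marker
  p <- cucumber_params(20, 0, 3, center = c(2, 3))
  expect_error(render_scene(scene_spec(), p), class = "cg_render_error")
})

test_that("background noise perturbs pixels but not the truth mask", {
  spec_noisy <- scene_spec(background_noise_sd = 5)
  set.seed(9)
  a <- render_scene(spec_noisy, canonical_tube())
  b <- render_scene(scene_spec(), canonical_tube())
  expect_identical(a$truth$mask, b$truth$mask)
  expect_gt(max(abs(a$image - b$image)), 0)
  expect_true(all(a$image >= 0 & a$image <= 255))
})

test_that("generate_dataset writes grade-prefixed files and a manifest", {
  out <- file.path(tempdir(), "cg_ds_small")
  counts <- c(2L, 3L, 2L, 2L, 3L, 2L, 2L)
  man <- generate_dataset(counts, out, spec = scene_spec(render_px_per_cm = 5),
                          seed = 42)
  expect_equal(nrow(man), sum(counts))
  expect_equal(as.vector(table(factor(man$grade, GRADES))), as.vector(counts))
  expect_true(all(grepl("^(AL|AM|AS|BM|BS|CM|CS)_\\d{4}\\.png$", man$filename)))
  expect_true(all(startsWith(man$filename, man$grade)))
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_true(all(file.exists(file.path(out, man$filename))))
  # same seed reproduces the manifest exactly
  out2 <- file.path(tempdir(), "cg_ds_small2")
  man2 <- generate_dataset(counts, out2, spec = scene_spec(render_px_per_cm = 5),
                           seed = 42)
  expect_identical(man, man2)
})
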