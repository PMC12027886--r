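test_that("marker detection recovers the true centers to sub-pixel accuracy", {
  for (ppcm in c(5, 10)) {
    sc <- render_scene(scene_spec(render_px_per_cm = ppcm), canonical_tube())
    mk <- detect_markers(sc$image)
    expect_lt(max(abs(mk$centers - sc$truth$marker_centers)), 1)
    expect_equal(rownames(mk$centers), c("tl", "tr", "bl", "br"))
  }
})

test_that("marker detection fails cleanly without markers", {
  white <- array(255, dim = c(60, 80, 3))
  expect_error(detect_markers(white), class = "cg_marker_detection_error")
})

test_that("a 180-degree rotation permutes labels but keeps the quadrilateral", {
  sc <- render_scene(scene_spec(render_px_per_cm = 5), canonical_tube())
  img <- sc$image
  rot <- img[rev(seq_len(nrow(img))), rev(seq_len(ncol(img))), , drop = FALSE]
  mk <- detect_markers(img)
  mkr <- detect_markers(rot)
  # rotated centers map to (W - x, H - y); tl of the rotation is the old br
  expected <- cbind(ncol(img) - mk$centers[c("br", "bl", "tr", "tl"), 1],
                    nrow(img) - mk$centers[c("br", "bl", "tr", "tl"), 2])
  expect_lt(max(abs(mkr$centers - expected)), 1e-6)
})

test_that("calibration is the marker spacing over the board size", {
  mk <- structure(list(centers = rbind(
    tl = c(50, 50), tr = c(450, 50), bl = c(50, 350), br = c(450, 350)),
    half_size_px = 10), class = "marker_set")
  cal <- compute_calibration(mk, 40, 30)
  expect_equal(cal$px_per_cm_x, 10)
  expect_equal(cal$px_per_cm_y, 10)
  cal2 <- compute_calibration(mk, 20, 15)
  expect_equal(cal2$px_per_cm_x, 20)
  expect_equal(cal2$px_per_cm_y, 20)
  # trapezoid: top and bottom distances average
  mk$centers["tr", 1] <- 440; mk$centers["br", 1] <- 460
  expect_equal(compute_calibration(mk, 40, 30)$px_per_cm_x, 10)
})

test_that("segmentation recovers the ground-truth mask exactly", {
  set.seed(31)
  for (g in c("AL", "BS", "CM")) {
    sc <- render_scene(scene_spec(), sample_params(g))
    mk <- detect_markers(sc$image)
    seg <- segment_cucumber(sc$image, mk)
    expect_identical(seg$mask, sc$truth$mask)
    expect_equal(seg$n_pixels, sum(sc$truth$mask))
    # bbox is tight and half-open
    rows <- which(rowSums(sc$truth$mask) > 0)
    cols <- which(colSums(sc$truth$mask) > 0)
    expect_equal(unname(seg$bbox),
                 c(min(cols) - 1L, min(rows) - 1L, max(cols), max(rows)))
  }
})

test_that("the largest green component wins over a distractor", {
  sc <- render_scene(scene_spec(), canonical_tube())
  img <- sc$image
  # small green blob inside the board, away from the cucumber
  img[60:70, 100:110, 1] <- 60; img[60:70, 100:110, 2] <- 170
  img[60:70, 100:110, 3] <- 70
  seg <- segment_cucumber(img, detect_markers(img))
  expect_identical(seg$mask, sc$truth$mask)
})

test_that("an empty board is a segmentation error", {
  sc <- render_scene(scene_spec(), canonical_tube())
  img <- sc$image
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[sc$truth$mask] <- c(245, 245, 245)[ch]
    img[, , ch] <- plane
  }
  expect_error(segment_cucumber(img, detect_markers(img)),
               class = "cg_segmentation_error")
})

test_that("measures follow their definitions arithmetically", {
  seg <- structure(list(mask = NULL,
                        bbox = c(x0 = 10L, y0 = 20L, x1 = 40L, y1 = 220L),
                        n_pixels = 4800L), class = "segmentation")
  cal <- structure(list(px_per_cm_x = 10, px_per_cm_y = 10),
                   class = "calibration")
  m <- measure_cucumber(seg, cal)
  expect_equal(m$height_cm, 20)
  expect_equal(m$width_cm, 3)
  expect_equal(m$area_cm2, 48)
})

test_that("cucumber pixels never touch marker pixels", {
  set.seed(17)
  for (g in c("AL", "CS")) {
    sc <- render_scene(scene_spec(), sample_params(g))
    blue <- sc$image[, , 3] - pmax(sc$image[, , 1], sc$image[, , 2])
    expect_false(any(sc$truth$mask & (blue > 40)))
  }
})

test_that("width grows with bend and height with length", {
  widths <- vapply(c(0, 30, 60, 90), function(b)
    scene_measures(cucumber_params(18, b, 3))$measure$width_cm, numeric(1))
  expect_true(all(diff(widths) >= 0))
  heights <- vapply(c(14, 20, 26), function(L)
    scene_measures(cucumber_params(L, 10, 3))$measure$height_cm, numeric(1))
  expect_true(all(diff(heights) >= 0))
})

test_that("calibrated measures are stable across render resolutions", {
  # operating-scale pair (10 and 20 px/cm): height and area within 2%;
  # width, quantized to one pixel per bounding-box side, within 2% or one
  # coarse-scale pixel (0.1 cm), whichever is larger
  for (p in grade_panel()[c("AS", "BM", "CM")]) {
    m10 <- scene_measures(p, 10)$measure
    m20 <- scene_measures(p, 20)$measure
    for (f in c("height_cm", "area_cm2"))
      expect_lt(abs(m10[[f]] - m20[[f]]) / m20[[f]], 0.02)
    expect_lt(abs(m10$width_cm - m20$width_cm),
              max(0.02 * m20$width_cm, 0.105))
  }
})
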