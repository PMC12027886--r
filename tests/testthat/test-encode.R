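fake_measure <- function(h, w, a) {
  structure(list(height_cm = h, width_cm = w, area_cm2 = a),
            class = "measure")
}

test_that("normalization divides by the range maxima and clips", {
  r <- norm_ranges()
  expect_equal(unname(normalize_measures(fake_measure(17, 5, 85), r)),
               c(0.5, 0.5, 0.5))
  expect_equal(unname(normalize_measures(fake_measure(100, 100, 1000), r)),
               c(1, 1, 1))
  expect_equal(unname(normalize_measures(fake_measure(3.4, 1, 17), r)),
               c(0.1, 0.1, 0.1))
})

test_that("the background encoding maps (h, w, a) onto (B, G, R)", {
  expect_equal(unname(encode_bg(c(1, 1, 1))), c(255, 255, 255))
  expect_equal(unname(encode_bg(c(0, 0, 0))), c(0, 0, 0))
  bg <- encode_bg(c(0.5, 0.2, 0.8))
  expect_equal(unname(bg["B"]), 128)  # height -> blue
  expect_equal(unname(bg["G"]), 51)   # width -> green
  expect_equal(unname(bg["R"]), 204)  # area -> red
  expect_error(encode_bg(c(1.2, 0, 0)), class = "cg_config_error")
})

test_that("encode/decode round trip is within one quantization step", {
  set.seed(5)
  crop <- array(90, dim = c(4, 4, 3)); mask <- matrix(TRUE, 4, 4)
  for (i in 1:200) {
    t <- stats::runif(3)
    cv <- compose_canvas(crop, mask, encode_bg(t))
    expect_lte(max(abs(decode_bg(cv) - t)), 1 / 255)
  }
  expect_equal(unname(decode_bg(compose_canvas(crop, mask, c(0, 0, 0)))),
               c(0, 0, 0))
})

test_that("a non-uniform background is a decode error", {
  px <- array(10, dim = c(340, 100, 3))
  px[1, 1, 2] <- 99
  expect_error(decode_bg(px), class = "cg_decode_error")
})

test_that("canvas composition keeps the background pure", {
  set.seed(8)
  crop <- array(stats::runif(30 * 20 * 3, 0, 255), dim = c(30, 20, 3))
  mask <- matrix(stats::runif(30 * 20) > 0.4, 30, 20)
  bg <- c(10, 20, 30)
  cv <- compose_canvas(crop, mask, bg)
  expect_equal(dim(cv$pixels), c(340L, 100L, 3L))
  expect_equal(unname(cv$pixels[1, 1, ]), bg)
  # non-object pixels equal bg exactly; object pixels are copied verbatim
  oy <- (340 - 30) %/% 2; ox <- (100 - 20) %/% 2
  full_mask <- matrix(FALSE, 340, 100)
  full_mask[oy + 1:30, ox + 1:20] <- mask
  for (ch in 1:3) {
    plane <- cv$pixels[, , ch]
    expect_true(all(plane[!full_mask] == bg[ch]))
    expect_equal(plane[oy + 1:30, ox + 1:20][mask], crop[, , ch][mask])
  }
})

test_that("crops rescale by the calibration ratio and overflow is caught", {
  cal20 <- structure(list(px_per_cm_x = 20, px_per_cm_y = 20),
                     class = "calibration")
  cal10 <- structure(list(px_per_cm_x = 10, px_per_cm_y = 10),
                     class = "calibration")
  img <- array(100, dim = c(120, 80, 3))
  mask <- matrix(FALSE, 120, 80); mask[21:80, 31:50] <- TRUE
  seg <- structure(list(mask = mask,
                        bbox = c(x0 = 30L, y0 = 20L, x1 = 50L, y1 = 80L),
                        n_pixels = sum(mask)), class = "segmentation")
  rc <- rescale_crop(img, seg, cal20, canvas_px_per_cm = 10)
  expect_equal(dim(rc$mask), c(30L, 10L))   # halved per axis
  rc2 <- rescale_crop(img, seg, cal10, canvas_px_per_cm = 10)
  expect_equal(dim(rc2$mask), c(60L, 20L))  # identity
  # a 40 cm object at canvas scale 10 px/cm would need 400 rows
  big <- matrix(TRUE, 400, 20)
  seg_big <- structure(list(mask = big,
                            bbox = c(x0 = 0L, y0 = 0L, x1 = 20L, y1 = 400L),
                            n_pixels = sum(big)), class = "segmentation")
  expect_error(rescale_crop(array(0, c(400, 20, 3)), seg_big, cal10, 10),
               class = "cg_crop_overflow_error")
})

test_that("build_sample round-trips measurements through the background", {
  sc <- render_scene(scene_spec(), canonical_tube())
  bs0 <- build_sample(sc$image, "without_rgb")
  expect_equal(unname(decode_bg(bs0$canvas)), c(0, 0, 0))
  bs1 <- build_sample(sc$image, "with_rgb")
  t_true <- normalize_measures(bs1$measure)
  expect_lte(max(abs(decode_bg(bs1$canvas) - t_true)), 1 / 255)
  expect_equal(bs1$measure$height_cm, 20)
  expect_equal(bs1$measure$width_cm, 3)
})

test_that("canvases hold the object at a fixed physical scale", {
  # same cucumber rendered at two camera distances lands on the canvas with
  # matching pixel footprints
  p <- grade_panel()$BM
  n_obj <- vapply(c(10, 20), function(ppcm) {
    sc <- render_scene(scene_spec(render_px_per_cm = ppcm), p)
    cv <- build_sample(sc$image, "without_rgb")$canvas
    sum(cv$pixels[, , 1] != 0 | cv$pixels[, , 2] != 0 | cv$pixels[, , 3] != 0)
  }, numeric(1))
  expect_lt(abs(n_obj[1] - n_obj[2]) / n_obj[2], 0.03)
  # and the footprint matches the measured area at the canvas scale
  sc <- render_scene(scene_spec(), p)
  bs <- build_sample(sc$image, "without_rgb")
  n_px <- sum(bs$canvas$pixels[, , 2] != 0)
  expect_lt(abs(n_px - bs$measure$area_cm2 * 100) / (bs$measure$area_cm2 * 100),
            0.03)
})
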