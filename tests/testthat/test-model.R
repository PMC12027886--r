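test_that("configuration contracts are enforced", {
  expect_error(model_config(dense_units = c(64L, 32L, 5L)),
               class = "cg_config_error")
  expect_error(model_config(dropout_conv = 1), class = "cg_config_error")
  expect_error(model_config(conv_filters = c(8L)), class = "cg_config_error")
})

test_that("the encoded-background variant has the published layer census", {
  s <- jsonlite::fromJSON(model_summary(build_model(model_config("with_rgb")),
                                        as_json = TRUE))
  expect_equal(s$n_conv, 2)
  expect_equal(s$n_pool, 2)
  expect_equal(s$n_dense, 3)
  expect_equal(s$n_dropout, 4)
  expect_equal(s$output_units, 7)
  expect_equal(s$input_hw, c(72, 24))
  expect_equal(s$conv_filters, c(8, 16))
  expect_equal(s$kernel, c(7, 7))
})

test_that("the baseline concatenates scalars and drops the dropout layers", {
  s <- model_summary(build_model(model_config("without_rgb")))
  expect_equal(s$n_dropout, 0L)
  expect_true("concat" %in% s$layers)
  s2 <- model_summary(build_model(model_config("image_only")))
  expect_equal(s2$n_dropout, 4L)
  expect_false("concat" %in% s2$layers)
})

test_that("forward output is a distribution over the 7 grades", {
  m <- build_model(model_config("with_rgb"), seed = 2)
  set.seed(4)
  x <- array(stats::runif(72 * 24 * 3 * 5), c(72, 24, 3, 5))
  p <- predict_proba(m, x)
  expect_equal(dim(p), c(5L, 7L))
  expect_equal(unname(rowSums(p)), rep(1, 5), tolerance = 1e-5)
  expect_true(all(p >= 0))
  # inference is deterministic: dropout inactive, running statistics fixed
  expect_identical(p, predict_proba(m, x))
})

test_that("the baseline refuses to run without its scalar input", {
  m <- build_model(model_config("without_rgb"), seed = 2)
  x <- array(0.5, c(72, 24, 3, 2))
  expect_error(predict_proba(m, x), class = "cg_config_error")
  expect_silent(predict_proba(m, x, feats = matrix(0.5, 2, 3)))
})

test_that("canvases become correctly shaped normalized inputs", {
  crop <- array(90, dim = c(40, 12, 3)); mask <- matrix(TRUE, 40, 12)
  cv <- compose_canvas(crop, mask, encode_bg(c(0.4, 0.3, 0.2)))
  pi <- prepare_input(cv, "with_rgb")
  expect_equal(dim(pi$x), c(72L, 24L, 3L))
  expect_null(pi$feats)
  expect_true(all(pi$x >= 0 & pi$x <= 1))
  # bilinear resize leaves the uniform background corner intact
  expect_lt(max(abs(pi$x[1, 1, ] * 255 - cv$bg_color)), 1)
  # black canvas resizes to an all-zero tensor
  cv0 <- compose_canvas(crop * 0, mask & FALSE, c(0, 0, 0))
  expect_true(all(prepare_input(cv0, "image_only")$x == 0))
  # the baseline needs the measurement triplet
  expect_error(prepare_input(cv, "without_rgb"), class = "cg_config_error")
  m <- structure(list(height_cm = 17, width_cm = 5, area_cm2 = 85),
                 class = "measure")
  pif <- prepare_input(cv, "without_rgb", measure = m)
  expect_equal(pif$feats, c(0.5, 0.5, 0.5))
})

test_that("analytic gradients match finite differences", {
  cfg <- model_config("without_rgb")  # exercises the concatenation path
  m <- build_model(cfg, seed = 7)
  set.seed(42)
  n <- 3L
  x <- array(stats::runif(72 * 24 * 3 * n), c(72, 24, 3, n))
  feats <- matrix(stats::runif(n * 3), n, 3)
  y <- c(1L, 4L, 7L)
  g <- cucumgrade:::cnn_grad(m$params, x, feats, y, cfg$kernel, TRUE, FALSE,
                             0, 0)
  lossfun <- function(params)
    cucumgrade:::cnn_grad(params, x, feats, y, cfg$kernel, TRUE, FALSE,
                          0, 0)$loss
  h <- 1e-3
  set.seed(99)
  for (nm in names(m$params)) {
    for (i in sample(length(m$params[[nm]]), 2)) {
      p2 <- m$params
      p2[[nm]][i] <- p2[[nm]][i] + h; lp <- lossfun(p2)
      p2[[nm]][i] <- m$params[[nm]][i] - h; lm <- lossfun(p2)
      fd <- (lp - lm) / (2 * h)
      an <- g$grads[[nm]][i]
      expect_lt(abs(fd - an), 0.05 * max(0.02, abs(fd) + abs(an)))
    }
  }
})

test_that("the cached training path computes the same gradients", {
  cfg <- model_config("with_rgb")
  m <- build_model(cfg, seed = 11)
  set.seed(13)
  n <- 6L
  x <- array(stats::runif(72 * 24 * 3 * n), c(72, 24, 3, n))
  y <- rep(1:3, 2)
  idx <- c(2L, 5L, 3L, 6L, 1L, 4L)
  direct <- cucumgrade:::cnn_grad(m$params, x[, , , idx, drop = FALSE], NULL,
                                  y[idx], cfg$kernel, FALSE, FALSE, 0, 0)
  cache <- cucumgrade:::make_conv_cache(m$params, x, cfg$kernel)
  cached <- cucumgrade:::cnn_grad_cached(m$params, cache, idx, NULL, y[idx],
                                         FALSE, FALSE, 0, 0)
  expect_equal(cached$loss, direct$loss, tolerance = 1e-6)
  for (nm in names(direct$grads))
    expect_equal(cached$grads[[nm]], direct$grads[[nm]], tolerance = 1e-5)
})
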