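#' Configuration of the shallow grading CNN
#'
#' Two 7x7 valid convolutions (8 then 16 filters, stride 1, batch norm, ReLU)
#' each followed by 2x2 max pooling, then dense layers of 64, 32 and 7 units
#' with a softmax output over the seven grades. The `"without_rgb"` baseline
#' concatenates the three normalized measurements to the flattened features
#' and uses no dropout; the `"with_rgb"` variant has no concatenation and
#' four dropout layers (after each pooling stage and after the first two
#' dense layers). `"image_only"` is the ablation: the `"with_rgb"`
#' architecture fed the masked crop stretched to the input size without the
#' size-preserving canvas, so neither pixels nor scalars carry the
#' measurements (see [image_only_input()]).
#'
#' @param variant One of `"with_rgb"`, `"without_rgb"`, `"image_only"`.
#' @param conv_filters Filter counts of the two convolution layers.
#' @param kernel Convolution kernel side (square).
#' @param dense_units Units of the three dense layers; the last must be 7.
#' @param dropout_conv,dropout_dense Drop rates of the convolutional-block
#'   and dense-block dropout layers (active variants only).
#' @param input_hw Input image size as `c(height, width)`.
#' @param learning_rate,batch_size Adam step size and batch size.
#' @param scalar_mode `"normalized"` feeds the normalized triplet to the
#'   baseline's concatenation; `"raw"` feeds centimetre values.
#' @return A `model_config` object.
#' @export
model_config <- function(variant = c("with_rgb", "without_rgb", "image_only"),
                         conv_filters = c(8L, 16L), kernel = 7L,
                         dense_units = c(64L, 32L, 7L),
                         dropout_conv = 0.1, dropout_dense = 0.1,
                         input_hw = c(72L, 24L), learning_rate = 0.001,
                         batch_size = 100L,
                         scalar_mode = c("normalized", "raw")) {
  variant <- match.arg(variant)
  scalar_mode <- match.arg(scalar_mode)
  if (length(dense_units) != 3L || dense_units[3] != 7L)
    config_error("'dense_units' must be three values ending in 7 (one unit per grade)")
  if (dropout_conv < 0 || dropout_conv >= 1 || dropout_dense < 0 || dropout_dense >= 1)
    config_error("dropout rates must be in [0, 1)")
  if (length(conv_filters) != 2L || any(conv_filters < 1))
    config_error("'conv_filters' must be two positive counts")
  structure(list(
    variant = variant,
    conv_filters = as.integer(conv_filters), kernel = as.integer(kernel),
    dense_units = as.integer(dense_units),
    dropout_conv = dropout_conv, dropout_dense = dropout_dense,
    input_hw = as.integer(input_hw), learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    loss = "cross-entropy", optimizer = "adam",
    scalar_mode = scalar_mode
  ), class = "model_config")
}

uses_feats   <- function(cfg) cfg$variant == "without_rgb"
uses_dropout <- function(cfg) cfg$variant %in% c("with_rgb", "image_only")

# Spatial bookkeeping for valid convolutions and floor-semantics 2x2 pooling.
model_dims <- function(cfg) {
  k <- cfg$kernel
  h1 <- cfg$input_hw[1] - k + 1L; w1 <- cfg$input_hw[2] - k + 1L
  p1h <- h1 %/% 2L; p1w <- w1 %/% 2L
  h2 <- p1h - k + 1L; w2 <- p1w - k + 1L
  p2h <- h2 %/% 2L; p2w <- w2 %/% 2L
  if (min(h1, w1, h2, w2, p2h, p2w) < 1L)
    config_error("input_hw too small for the kernel/pooling configuration")
  flat <- p2h * p2w * cfg$conv_filters[2]
  list(conv1 = c(h1, w1), pool1 = c(p1h, p1w), conv2 = c(h2, w2),
       pool2 = c(p2h, p2w), flat = flat,
       dense_in = flat + if (uses_feats(cfg)) 3L else 0L)
}

#' Build (initialize) a grading CNN
#'
#' He-normal initialization for convolution and dense weights, unit gamma /
#' zero beta for batch norm. Deterministic given `seed`.
#'
#' @param cfg A [model_config()] object.
#' @param seed Integer seed for weight initialization.
#' @return A `cucumber_cnn` object holding parameters, batch-norm running
#'   statistics, Adam state and the training step counter.
#' @export
build_model <- function(cfg = model_config(), seed = 1L) {
  d <- model_dims(cfg)
  k <- cfg$kernel; f1 <- cfg$conv_filters[1]; f2 <- cfg$conv_filters[2]
  set.seed(seed)
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  params <- list(
    W1 = he(k * k * 3L, f1),
    g1 = matrix(1, 1, f1), be1 = matrix(0, 1, f1),
    W2 = he(k * k * f1, f2),
    g2 = matrix(1, 1, f2), be2 = matrix(0, 1, f2),
    Wd1 = he(d$dense_in, cfg$dense_units[1]),
    bd1 = matrix(0, 1, cfg$dense_units[1]),
    Wd2 = he(cfg$dense_units[1], cfg$dense_units[2]),
    bd2 = matrix(0, 1, cfg$dense_units[2]),
    Wd3 = he(cfg$dense_units[2], cfg$dense_units[3]),
    bd3 = matrix(0, 1, cfg$dense_units[3])
  )
  bn_state <- list(
    rm1 = matrix(0, 1, f1), rv1 = matrix(1, 1, f1),
    rm2 = matrix(0, 1, f2), rv2 = matrix(1, 1, f2)
  )
  adam <- list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
  structure(list(config = cfg, params = params, bn_state = bn_state,
                 adam = adam, steps_trained = 0L, loss_trace = numeric(0)),
            class = "cucumber_cnn")
}

#' Architecture summary
#'
#' A machine-readable census of the network: layer list in order, counts per
#' layer type, parameter count, input/output sizes. `as_json = TRUE` returns
#' the JSON text used by tools and tests.
#'
#' @param model A `cucumber_cnn` from [build_model()].
#' @param as_json Return a JSON string instead of a list.
#' @return A list (or JSON string).
#' @export
model_summary <- function(model, as_json = FALSE) {
  cfg <- model$config
  drop <- uses_dropout(cfg)
  layers <- c(
    "conv", "batch_norm", "relu", "max_pool", if (drop) "dropout",
    "conv", "batch_norm", "relu", "max_pool", if (drop) "dropout",
    "flatten", if (uses_feats(cfg)) "concat",
    "dense", "relu", if (drop) "dropout",
    "dense", "relu", if (drop) "dropout",
    "dense", "softmax"
  )
  s <- list(
    variant = cfg$variant,
    layers = layers,
    n_conv = sum(layers == "conv"),
    n_pool = sum(layers == "max_pool"),
    n_dense = sum(layers == "dense"),
    n_dropout = sum(layers == "dropout"),
    conv_filters = cfg$conv_filters,
    kernel = c(cfg$kernel, cfg$kernel),
    input_hw = cfg$input_hw,
    output_units = cfg$dense_units[3],
    dense_units = cfg$dense_units,
    param_count = sum(vapply(model$params, length, integer(1))),
    steps_trained = model$steps_trained
  )
  if (as_json) jsonlite::toJSON(s, auto_unbox = FALSE) else s
}

#' Prepare a canvas as model input
#'
#' Resizes the 100x340 canvas to the network's input size (default 72 tall x
#' 24 wide, bilinear) and scales intensities to `[0, 1]`. For the
#' `"without_rgb"` baseline the measurement triplet must be supplied and is
#' carried as the side-channel scalar input.
#'
#' @param canvas A `canvas` from [compose_canvas()] / [build_sample()].
#' @param variant Model variant the input is meant for.
#' @param measure A `measure`, required iff `variant = "without_rgb"`.
#' @param ranges [norm_ranges()] used to normalize the scalars.
#' @param input_hw Target size `c(height, width)`.
#' @param scalar_mode `"normalized"` or `"raw"` scalars for the baseline.
#' @return List `x` (input_hw x 3 array in `[0, 1]`) and `feats` (numeric
#'   triplet or `NULL`).
#' @export
prepare_input <- function(canvas, variant = c("with_rgb", "without_rgb",
                                              "image_only"),
                          measure = NULL, ranges = norm_ranges(),
                          input_hw = c(72L, 24L),
                          scalar_mode = "normalized") {
  variant <- match.arg(variant)
  px <- if (inherits(canvas, "canvas")) canvas$pixels else canvas
  x <- resize_rgb(px, input_hw[1], input_hw[2]) / 255
  feats <- NULL
  if (variant == "without_rgb") {
    if (is.null(measure))
      config_error("variant 'without_rgb' requires 'measure'")
    feats <- if (scalar_mode == "raw")
      c(measure$height_cm, measure$width_cm, measure$area_cm2)
    else unname(normalize_measures(measure, ranges))
  }
  list(x = x, feats = feats)
}

#' Network input for the image-only ablation
#'
#' Pastes the crop onto black by its mask and stretches it to the network
#' input size directly, skipping the fixed-physical-scale canvas. The
#' uniform resize removes absolute size, so this input carries shape
#' (curvature, aspect) but no size channel — the ablation against which the
#' background encoding's size signal is demonstrated.
#'
#' @param crop h x w x 3 array, 0-255.
#' @param mask Logical h x w object mask.
#' @param input_hw Target size `c(height, width)`.
#' @return `input_hw x 3` array in `[0, 1]`.
#' @export
image_only_input <- function(crop, mask, input_hw = c(72L, 24L)) {
  black <- array(0, dim = dim(crop))
  for (k in 1:3) {
    plane <- black[, , k]
    plane[mask] <- crop[, , k][mask]
    black[, , k] <- plane
  }
  resize_rgb(black, input_hw[1], input_hw[2]) / 255
}

#' Predict class probabilities
#'
#' Inference pass (batch norm running statistics, dropout inactive), chunked
#' to bound memory. Output rows are proper distributions over the 7 grades.
#'
#' @param model A `cucumber_cnn`.
#' @param x Array `(h, w, 3, n)` of inputs in `[0, 1]` (a single `(h, w, 3)`
#'   array is promoted).
#' @param feats `n x 3` matrix of scalar features (baseline variant only).
#' @param chunk Images per inference batch.
#' @return `n x 7` matrix of probabilities, columns named by [GRADES].
#' @export
predict_proba <- function(model, x, feats = NULL, chunk = 128L) {
  cfg <- model$config
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[4]
  if (uses_feats(cfg)) {
    if (is.null(feats)) config_error("variant 'without_rgb' requires 'feats'")
    feats <- matrix(feats, nrow = n)
  }
  out <- matrix(NA_real_, n, 7L, dimnames = list(NULL, GRADES))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    xb <- x[, , , s:e, drop = FALSE]
    fb <- if (uses_feats(cfg)) feats[s:e, , drop = FALSE] else NULL
    out[s:e, ] <- cnn_forward(model$params, model$bn_state, xb, fb,
                              cfg$kernel, uses_feats(cfg))
  }
  out
}
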