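#' Run the vision stage over a dataset manifest
#'
#' Reads each scene, detects markers, calibrates, segments and measures the
#' cucumber, and keeps the rescaled crop so canvases for any variant can be
#' composed without repeating the vision pass.
#'
#' @param manifest Data frame with `filename` and `grade` columns (as written
#'   by [generate_dataset()]), or the path of a `manifest.csv`.
#' @param dir Directory holding the images.
#' @param board_width_cm,board_height_cm Known marker spacing.
#' @param canvas_px_per_cm Physical scale of the training canvas.
#' @return A `graded_samples` list: per-image crop, mask, measure and grade.
#' @export
load_graded_samples <- function(manifest, dir, board_width_cm = 40,
                                board_height_cm = 30, canvas_px_per_cm = 10) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) io_error(sprintf("no manifest at '%s'", manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (!all(c("filename", "grade") %in% names(manifest)))
    data_error("manifest needs 'filename' and 'grade' columns")
  if (!all(manifest$grade %in% GRADES))
    data_error("manifest contains labels outside the 7-grade set")
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_scene(file.path(dir, manifest$filename[i]))
    mk <- detect_markers(img)
    cal <- compute_calibration(mk, board_width_cm, board_height_cm)
    seg <- segment_cucumber(img, mk)
    m <- measure_cucumber(seg, cal)
    rc <- rescale_crop(img, seg, cal, canvas_px_per_cm)
    list(crop = rc$crop, mask = rc$mask, measure = m,
         grade = manifest$grade[i])
  })
  structure(list(samples = samples, manifest = manifest),
            class = "graded_samples")
}

#' Turn vision results into model-ready tensors
#'
#' Composes the variant's canvas per sample (encoded background for
#' `"with_rgb"`, black for `"without_rgb"`) and stacks the resized inputs,
#' scalar features and labels. For the `"image_only"` ablation the masked
#' crop is stretched to the network input directly — no canvas, so the
#' uniform resize erases absolute size and only shape remains.
#'
#' @param gs A `graded_samples` from [load_graded_samples()].
#' @param variant Model variant the tensors are meant for.
#' @param ranges [norm_ranges()] for encoding/normalizing.
#' @param input_hw Network input size.
#' @param scalar_mode Scalar mode for the baseline's side-channel numerics.
#' @return A `model_data` list: `x` `(h, w, 3, n)`, `feats` `n x 3`,
#'   `y` integer labels 1..7, `grades` character.
#' @export
as_model_data <- function(gs, variant = c("with_rgb", "without_rgb",
                                          "image_only"),
                          ranges = norm_ranges(), input_hw = c(72L, 24L),
                          scalar_mode = "normalized") {
  variant <- match.arg(variant)
  n <- length(gs$samples)
  if (n == 0L) data_error("empty sample set")
  x <- array(NA_real_, dim = c(input_hw[1], input_hw[2], 3L, n))
  feats <- matrix(NA_real_, n, 3L)
  grades <- character(n)
  for (i in seq_len(n)) {
    s <- gs$samples[[i]]
    if (variant == "image_only") {
      x[, , , i] <- image_only_input(s$crop, s$mask, input_hw)
      feats[i, ] <- c(0, 0, 0)
    } else {
      bg <- if (variant == "with_rgb")
        encode_bg(normalize_measures(s$measure, ranges)) else c(0, 0, 0)
      cv <- compose_canvas(s$crop, s$mask, bg, label = s$grade)
      pi <- prepare_input(cv, variant, measure = s$measure, ranges = ranges,
                          input_hw = input_hw, scalar_mode = scalar_mode)
      x[, , , i] <- pi$x
      feats[i, ] <- if (is.null(pi$feats)) c(0, 0, 0) else pi$feats
    }
    grades[i] <- s$grade
  }
  structure(list(x = x, feats = feats, y = match(grades, GRADES),
                 grades = grades), class = "model_data")
}

adam_update <- function(model, grads) {
  cfg <- model$config
  ad <- model$adam
  ad$t <- ad$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- cfg$learning_rate
  for (nm in names(model$params)) {
    g <- grads[[nm]]
    ad$m[[nm]] <- b1 * ad$m[[nm]] + (1 - b1) * g
    ad$v[[nm]] <- b2 * ad$v[[nm]] + (1 - b2) * g^2
    mhat <- ad$m[[nm]] / (1 - b1^ad$t)
    vhat <- ad$v[[nm]] / (1 - b2^ad$t)
    model$params[[nm]] <- model$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  model$adam <- ad
  model
}

#' Train a grading CNN
#'
#' Runs exactly `steps` Adam updates on batches of `batch_size` drawn with
#' replacement (so step counts below one epoch are well defined), under
#' `seed`. Batch-norm running statistics are updated with momentum 0.9.
#' `steps = 0` returns the model unchanged.
#'
#' @param model A `cucumber_cnn` from [build_model()].
#' @param data A `model_data` from [as_model_data()]; must cover all 7 grades.
#' @param steps Number of optimizer updates ("training cycles").
#' @param seed Integer seed controlling batch sampling and dropout.
#' @return The trained model; `model$loss_trace` grows by one entry per step.
#' @export
train_model <- function(model, data, steps, seed = 1L) {
  cfg <- model$config
  if (!all(data$y %in% 1:7)) data_error("labels outside the 7-grade set")
  if (length(unique(data$y)) < 7L)
    data_error("training data must cover all 7 grades")
  steps <- as.integer(steps)
  if (steps == 0L) return(model)
  n <- dim(data$x)[4]
  mom <- 0.9
  # first-layer patches of the fixed dataset are computed once; each step
  # only gathers the batch's rows
  cache <- make_conv_cache(model$params, data$x, cfg$kernel)
  set.seed(seed)
  trace <- numeric(steps)
  for (s in seq_len(steps)) {
    idx <- sample.int(n, cfg$batch_size, replace = TRUE)
    fb <- if (uses_feats(cfg)) data$feats[idx, , drop = FALSE] else NULL
    r <- cnn_grad_cached(model$params, cache, idx, fb, data$y[idx],
                         uses_feats(cfg), uses_dropout(cfg),
                         cfg$dropout_conv, cfg$dropout_dense)
    model <- adam_update(model, r$grads)
    bn <- r$bn
    st <- model$bn_state
    st$rm1 <- mom * st$rm1 + (1 - mom) * bn$mu1
    st$rv1 <- mom * st$rv1 + (1 - mom) * bn$var1
    st$rm2 <- mom * st$rm2 + (1 - mom) * bn$mu2
    st$rv2 <- mom * st$rv2 + (1 - mom) * bn$var2
    model$bn_state <- st
    trace[s] <- r$loss
  }
  model$steps_trained <- model$steps_trained + steps
  model$loss_trace <- c(model$loss_trace, trace)
  model
}

#' Evaluation report from true and predicted grades
#'
#' Builds the 7x7 confusion matrix (rows = true, columns = predicted) and the
#' four protocol metrics: accuracy, macro recall, macro precision and macro
#' F-measure (mean of per-class F1). A class never predicted contributes 0 to
#' macro precision; a class with undefined F1 contributes 0. On a balanced
#' test set macro recall equals accuracy exactly.
#'
#' @param truth,predicted Character vectors of grade labels.
#' @return An `eval_report`.
#' @export
eval_report <- function(truth, predicted) {
  if (length(truth) != length(predicted) || length(truth) == 0L)
    data_error("truth and predicted must be equal-length, non-empty")
  if (!all(truth %in% GRADES) || !all(predicted %in% GRADES))
    data_error("labels outside the 7-grade set")
  tf <- factor(truth, levels = GRADES)
  pf <- factor(predicted, levels = GRADES)
  confusion <- table(truth = tf, predicted = pf)
  n <- length(truth)
  tp <- diag(confusion)
  row_sums <- rowSums(confusion)   # true counts (TP + FN)
  col_sums <- colSums(confusion)   # predicted counts (TP + FP)
  recall <- ifelse(row_sums > 0, tp / row_sums, 0)
  precision <- ifelse(col_sums > 0, tp / col_sums, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(list(
    confusion = unclass(confusion),
    accuracy = sum(tp) / n,
    recall_macro = mean(recall),
    precision_macro = mean(precision),
    f_measure_macro = mean(f1),
    per_class = data.frame(grade = GRADES, recall = as.numeric(recall),
                           precision = as.numeric(precision),
                           f1 = as.numeric(f1)),
    n_test = n
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "Evaluation over %d images:\n  accuracy  %.4f\n  recall    %.4f (macro)\n  precision %.4f (macro)\n  F-measure %.4f (macro)\n",
    x$n_test, x$accuracy, x$recall_macro, x$precision_macro,
    x$f_measure_macro))
  invisible(x)
}

#' Evaluate a model on a test set
#'
#' Argmax prediction per sample, then [eval_report()].
#'
#' @param model A trained `cucumber_cnn`.
#' @param test A `model_data`.
#' @return An `eval_report`.
#' @export
evaluate_model <- function(model, test) {
  p <- predict_proba(model, test$x,
                     feats = if (uses_feats(model$config)) test$feats)
  pred <- GRADES[max.col(p, ties.method = "first")]
  eval_report(test$grades, pred)
}

#' Experiment grid definition
#'
#' @param training_cycles Step counts to train to (fresh model each).
#' @param n_replicates Independently seeded models per setting.
#' @param variants Model variants to compare.
#' @param base_seed Replicate `r` of any setting trains under
#'   `base_seed + r`.
#' @return An `experiment_grid`.
#' @export
experiment_grid <- function(training_cycles = c(10L, 100L, 1000L, 5000L,
                                                10000L),
                            n_replicates = 10L,
                            variants = c("with_rgb", "without_rgb"),
                            base_seed = 100L) {
  training_cycles <- as.integer(training_cycles)
  if (n_replicates < 1L) config_error("'n_replicates' must be >= 1")
  if (any(training_cycles <= 0) || is.unsorted(training_cycles, strictly = TRUE))
    config_error("'training_cycles' must be positive and increasing")
  structure(list(training_cycles = training_cycles,
                 n_replicates = as.integer(n_replicates),
                 variants = variants, base_seed = as.integer(base_seed)),
            class = "experiment_grid")
}

#' Run the replicated training-cycle grid
#'
#' For every (variant, cycle count, replicate) trains a fresh model under
#' seed `base_seed + replicate` and evaluates it on the test set, mirroring
#' the protocol of training several models per cycle setting and averaging
#' the four metrics.
#'
#' @param grid An [experiment_grid()].
#' @param train_data Named list of `model_data`, one per variant (a single
#'   `model_data` is reused for every variant).
#' @param test_data Same structure as `train_data`, for the test manifest.
#' @param cfg_for Optional function `variant -> model_config`; defaults to
#'   [model_config()] of that variant.
#' @param verbose Print one line per trained model.
#' @return A `grid_results` list: `results` (per-replicate data frame) and
#'   `summary` (means over replicates).
#' @export
run_grid <- function(grid, train_data, test_data, cfg_for = NULL,
                     verbose = FALSE) {
  pick <- function(lst, v) {
    if (inherits(lst, "model_data")) lst
    else if (!is.null(lst[[v]])) lst[[v]]
    else data_error(sprintf("no data for variant '%s'", v))
  }
  if (is.null(cfg_for)) cfg_for <- function(v) model_config(variant = v)
  rows <- list()
  for (v in grid$variants) {
    tr <- pick(train_data, v); te <- pick(test_data, v)
    cfg <- cfg_for(v)
    for (cycles in grid$training_cycles) {
      for (rep in seq_len(grid$n_replicates)) {
        seed <- grid$base_seed + rep
        model <- build_model(cfg, seed = seed)
        model <- train_model(model, tr, steps = cycles, seed = seed)
        ev <- evaluate_model(model, te)
        rows[[length(rows) + 1L]] <- data.frame(
          variant = v, cycles = cycles, replicate = rep, seed = seed,
          accuracy = ev$accuracy, recall_macro = ev$recall_macro,
          precision_macro = ev$precision_macro,
          f_measure_macro = ev$f_measure_macro,
          stringsAsFactors = FALSE)
        if (verbose)
          message(sprintf("%s cycles=%d rep=%d acc=%.3f",
                          v, cycles, rep, ev$accuracy))
      }
    }
  }
  results <- do.call(rbind, rows)
  agg <- stats::aggregate(
    results[, c("accuracy", "recall_macro", "precision_macro",
                "f_measure_macro")],
    by = list(variant = results$variant, cycles = results$cycles), mean)
  agg <- agg[order(agg$cycles, agg$variant), ]
  rownames(agg) <- NULL
  structure(list(results = results, summary = agg, grid = grid),
            class = "grid_results")
}

#' Write grid results as CSV
#'
#' Fixed 6-decimal formatting so identical runs are byte-identical files.
#'
#' @param gr A `grid_results` from [run_grid()].
#' @param path Output CSV path.
#' @param what `"results"` (per replicate) or `"summary"` (means).
#' @export
write_grid_csv <- function(gr, path, what = c("results", "summary")) {
  what <- match.arg(what)
  df <- gr[[what]]
  num <- vapply(df, is.numeric, logical(1)) &
    !names(df) %in% c("cycles", "replicate", "seed")
  df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Format grid means as a cycles-by-method text table
#'
#' Lays the four metrics out with one column pair (without / with RGB) per
#' training-cycle setting, the layout used to compare the two methods.
#'
#' @param gr A `grid_results`.
#' @return Character vector of report lines.
#' @export
format_grid_report <- function(gr) {
  s <- gr$summary
  cycles <- sort(unique(s$cycles))
  metrics <- c(accuracy = "Accuracy(%)", recall_macro = "Recall(%)",
               precision_macro = "Precision(%)",
               f_measure_macro = "F-measure(%)")
  header1 <- paste0(sprintf("%-14s", "Cycles"),
                    paste(sprintf("%13d", cycles), collapse = ""))
  header2 <- paste0(sprintf("%-14s", "Method"),
                    paste(rep(sprintf("%6s %6s", "w/o", "w/"),
                              length(cycles)), collapse = " "))
  lines <- c(header1, header2)
  get <- function(v, cy, m) {
    val <- s[s$variant == v & s$cycles == cy, m]
    if (length(val) == 0) NA_real_ else 100 * val
  }
  for (m in names(metrics)) {
    cells <- unlist(lapply(cycles, function(cy)
      sprintf("%6.1f %6.1f", get("without_rgb", cy, m), get("with_rgb", cy, m))))
    lines <- c(lines, paste0(sprintf("%-14s", metrics[[m]]),
                             paste(cells, collapse = " ")))
  }
  lines
}

#' Sweep the convolutional-block drop rate
#'
#' Trains one `"with_rgb"` model per convolutional drop rate with the dense
#' drop rate held fixed, and reports test accuracy per rate.
#'
#' @param rates Convolutional drop rates in `[0, 1)`.
#' @param train_data,test_data `model_data` for the `"with_rgb"` variant.
#' @param fixed_dense_rate Dense-block drop rate.
#' @param cycles Training steps per model.
#' @param seed Seed for each model (same for all rates, isolating the rate).
#' @return Data frame `rate`, `accuracy`.
#' @export
dropout_sweep <- function(rates, train_data, test_data,
                          fixed_dense_rate = 0.1, cycles = 1000L,
                          seed = 1L) {
  if (any(rates < 0 | rates >= 1))
    config_error("drop rates must be in [0, 1)")
  acc <- vapply(rates, function(r) {
    cfg <- model_config(variant = "with_rgb", dropout_conv = r,
                        dropout_dense = fixed_dense_rate)
    model <- build_model(cfg, seed = seed)
    model <- train_model(model, train_data, steps = cycles, seed = seed)
    evaluate_model(model, test_data)$accuracy
  }, numeric(1))
  data.frame(rate = rates, accuracy = acc)
}

#' Classify a single scene image end to end
#'
#' Runs marker detection, calibration, segmentation, measurement, canvas
#' composition and the network forward pass; any stage failure surfaces as
#' that stage's error class.
#'
#' @param image H x W x 3 scene array (0-255) or a PNG path.
#' @param model A trained `cucumber_cnn`.
#' @param ranges [norm_ranges()] shared with training.
#' @param board_width_cm,board_height_cm Known marker spacing.
#' @param canvas_px_per_cm Canvas scale shared with training.
#' @return List `grade` (argmax label) and `scores` (named 7-vector).
#' @export
classify <- function(image, model, ranges = norm_ranges(),
                     board_width_cm = 40, board_height_cm = 30,
                     canvas_px_per_cm = 10) {
  if (is.character(image)) image <- read_scene(image)
  cfg <- model$config
  if (cfg$variant == "image_only") {
    mk <- detect_markers(image)
    cal <- compute_calibration(mk, board_width_cm, board_height_cm)
    seg <- segment_cucumber(image, mk)
    rc <- rescale_crop(image, seg, cal, canvas_px_per_cm)
    x <- image_only_input(rc$crop, rc$mask, cfg$input_hw)
    feats <- NULL
  } else {
    bs <- build_sample(image, cfg$variant, ranges = ranges,
                       canvas_px_per_cm = canvas_px_per_cm,
                       board_width_cm = board_width_cm,
                       board_height_cm = board_height_cm)
    pi <- prepare_input(bs$canvas, cfg$variant, measure = bs$measure,
                        ranges = ranges, input_hw = cfg$input_hw,
                        scalar_mode = cfg$scalar_mode)
    x <- pi$x; feats <- pi$feats
  }
  p <- predict_proba(model, x, feats = feats)
  list(grade = GRADES[which.max(p[1, ])], scores = p[1, ])
}
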