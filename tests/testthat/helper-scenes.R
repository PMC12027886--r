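# Shared fixtures, all generated in code at test time.

# Canonical straight tube used in worked examples: 20 cm long, 3 cm thick,
# grid-aligned so its rasterization is exact at 5/10/20 px/cm.
canonical_tube <- function() cucumber_params(20, 0, 3)

# One representative parameter set per grade (cell midpoints, market-typical
# 3 cm thickness).
grade_panel <- function() {
  list(AL = cucumber_params(25, 10, 3), AM = cucumber_params(21, 10, 3),
       AS = cucumber_params(14, 10, 3), BM = cucumber_params(21, 40, 3),
       BS = cucumber_params(14, 40, 3), CM = cucumber_params(21, 90, 3),
       CS = cucumber_params(14, 90, 3))
}

# Render + full vision pass in one call.
scene_measures <- function(params, ppcm = 10, noise = 0) {
  sc <- render_scene(scene_spec(render_px_per_cm = ppcm,
                                background_noise_sd = noise), params)
  mk <- detect_markers(sc$image)
  cal <- compute_calibration(mk)
  seg <- segment_cucumber(sc$image, mk)
  list(scene = sc, markers = mk, cal = cal, seg = seg,
       measure = measure_cucumber(seg, cal))
}

# Random model_data (no vision pass) for optimizer/metric tests.
fake_model_data <- function(n, seed = 1) {
  set.seed(seed)
  grades <- rep(GRADES, length.out = n)
  structure(list(
    x = array(stats::runif(72 * 24 * 3 * n), c(72L, 24L, 3L, n)),
    feats = matrix(stats::runif(n * 3), n, 3),
    y = match(grades, GRADES), grades = grades
  ), class = "model_data")
}

# The scaled-down learning experiment (shared by the acceptance tests so the
# expensive grid is trained once and its determinism checked by a clean
# re-run). Cached per session.
.exp_cache <- new.env(parent = emptyenv())

experiment_fixture <- function() {
  if (!is.null(.exp_cache$fix)) return(.exp_cache$fix)
  tr_dir <- file.path(tempdir(), "cg_exp_train")
  te_dir <- file.path(tempdir(), "cg_exp_test")
  generate_dataset(70, tr_dir, seed = 20260101)
  generate_dataset(10, te_dir, seed = 20260102)
  gs_tr <- load_graded_samples(file.path(tr_dir, "manifest.csv"), tr_dir)
  gs_te <- load_graded_samples(file.path(te_dir, "manifest.csv"), te_dir)
  variants <- c("with_rgb", "without_rgb", "image_only")
  fix <- list(
    train = lapply(stats::setNames(variants, variants),
                   function(v) as_model_data(gs_tr, v)),
    test = lapply(stats::setNames(variants, variants),
                  function(v) as_model_data(gs_te, v)),
    grid = experiment_grid(training_cycles = c(10L, 1000L),
                           n_replicates = 3L, variants = variants,
                           base_seed = 500L)
  )
  .exp_cache$fix <- fix
  fix
}

experiment_results <- function() {
  if (is.null(.exp_cache$gr)) {
    fix <- experiment_fixture()
    .exp_cache$gr <- run_grid(fix$grid, fix$train, fix$test)
  }
  .exp_cache$gr
}
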