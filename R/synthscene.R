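#' The seven market grades
#'
#' Grade labels are the product of a curvature class (A straightest to C most
#' bent) and a size class (L largest to S smallest); bent cucumbers are never
#' graded L, so the B and C rows only carry M and S.
#'
#' @export
GRADES <- c("AL", "AM", "AS", "BM", "BS", "CM", "CS")

# Scene palette: chosen so the three colour populations (board, markers,
# cucumber) are separable by simple channel-dominance thresholds.
BOARD_COLOR    <- c(245, 245, 245)
MARKER_COLOR   <- c(40, 40, 230)
CUCUMBER_COLOR <- c(60, 170, 70)

#' Scene specification for the synthetic board
#'
#' Describes the white measurement board: its physical size, the corner
#' fiducial markers, and the rendering resolution. Marker *centers* sit
#' exactly at the corners of a `board_width_cm` x `board_height_cm` rectangle,
#' mirroring a real board with markers at 40 cm (width) and 30 cm (height)
#' spacing.
#'
#' @param board_width_cm,board_height_cm Physical spacing of the marker
#'   centers, in cm.
#' @param marker_size_cm Side length of the square markers, in cm.
#' @param render_px_per_cm Rendering resolution (pixels per cm).
#' @param margin_px Border, in pixels, outside the marker centers. Defaults to
#'   one marker size so the markers lie fully inside the image.
#' @param background_noise_sd Standard deviation of additive Gaussian pixel
#'   noise (8-bit intensity units); 0 disables noise.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(board_width_cm = 40, board_height_cm = 30,
                       marker_size_cm = 2, render_px_per_cm = 10,
                       margin_px = NULL, background_noise_sd = 0) {
  stopifnot_scalar_num(board_width_cm, "board_width_cm")
  stopifnot_scalar_num(board_height_cm, "board_height_cm")
  stopifnot_scalar_num(marker_size_cm, "marker_size_cm")
  stopifnot_scalar_num(render_px_per_cm, "render_px_per_cm")
  stopifnot_scalar_num(background_noise_sd, "background_noise_sd", positive = FALSE)
  if (background_noise_sd < 0) config_error("'background_noise_sd' must be >= 0")
  if (marker_size_cm >= min(board_width_cm, board_height_cm) / 4)
    config_error("'marker_size_cm' must be < min(board dims)/4")
  if (is.null(margin_px))
    margin_px <- ceiling(marker_size_cm * render_px_per_cm)
  margin_px <- as.integer(margin_px)
  if (margin_px < ceiling(marker_size_cm * render_px_per_cm / 2))
    config_error("'margin_px' too small: markers would be clipped")
  structure(list(
    board_width_cm = board_width_cm, board_height_cm = board_height_cm,
    marker_size_cm = marker_size_cm, render_px_per_cm = render_px_per_cm,
    margin_px = margin_px, background_noise_sd = background_noise_sd
  ), class = "scene_spec")
}

#' Parameters of one cucumber
#'
#' The cucumber is modelled as a tube of constant `thickness_cm` around a
#' circular-arc centerline of length `arc_length_cm` turning through
#' `bend_angle_deg` in total (0 = straight). Ends are square-capped, so the
#' analytic tube area is exactly `arc_length_cm * thickness_cm`.
#'
#' @param arc_length_cm Centerline length, cm.
#' @param bend_angle_deg Total turning angle of the centerline, degrees,
#'   in `[0, 180)`.
#' @param thickness_cm Tube diameter, cm.
#' @param color RGB triplet (0-255), greenish by default.
#' @param center Position of the shape center on the board, cm, relative to
#'   the top-left marker center; `NULL` places it at the board center.
#' @param orientation_deg Rotation of the chord away from vertical, degrees.
#' @return An object of class `cucumber_params`.
#' @export
cucumber_params <- function(arc_length_cm, bend_angle_deg, thickness_cm,
                            color = CUCUMBER_COLOR, center = NULL,
                            orientation_deg = 0) {
  stopifnot_scalar_num(arc_length_cm, "arc_length_cm")
  stopifnot_scalar_num(thickness_cm, "thickness_cm")
  stopifnot_scalar_num(bend_angle_deg, "bend_angle_deg", positive = FALSE)
  if (bend_angle_deg < 0 || bend_angle_deg >= 180)
    config_error("'bend_angle_deg' must be in [0, 180)")
  if (bend_angle_deg > 0) {
    radius <- arc_length_cm * 180 / (pi * bend_angle_deg)
    if (thickness_cm / 2 >= radius)
      config_error("tube self-intersects: thickness/2 must be < radius of curvature")
  }
  structure(list(
    arc_length_cm = arc_length_cm, bend_angle_deg = bend_angle_deg,
    thickness_cm = thickness_cm, color = color, center = center,
    orientation_deg = orientation_deg
  ), class = "cucumber_params")
}

#' Grade thresholds
#'
#' Numeric cut-offs separating the curvature classes (A/B/C by bend angle) and
#' size classes (L/M/S by arc length). Real cut-offs are cooperative-specific;
#' the defaults are plausible round values and every test exercises them
#' through this configurable object.
#'
#' @param bend_a_max_deg Largest bend still graded A (degrees).
#' @param bend_b_max_deg Largest bend still graded B (degrees).
#' @param size_l_min_cm Smallest length graded L (cm).
#' @param size_m_min_cm Smallest length graded M (cm).
#' @return An object of class `grade_thresholds`.
#' @export
grade_thresholds <- function(bend_a_max_deg = 20, bend_b_max_deg = 60,
                             size_l_min_cm = 24, size_m_min_cm = 18) {
  if (!(bend_a_max_deg < bend_b_max_deg))
    config_error("thresholds non-monotone: need bend_a_max_deg < bend_b_max_deg")
  if (!(size_m_min_cm < size_l_min_cm))
    config_error("thresholds non-monotone: need size_m_min_cm < size_l_min_cm")
  structure(list(
    bend_a_max_deg = bend_a_max_deg, bend_b_max_deg = bend_b_max_deg,
    size_l_min_cm = size_l_min_cm, size_m_min_cm = size_m_min_cm
  ), class = "grade_thresholds")
}

#' Assign a grade from cucumber parameters
#'
#' Curvature class comes from the bend angle, size class from the arc length.
#' Because the grade list has no BL/CL, a bent cucumber of L length clamps to
#' the M size class.
#'
#' @param params A [cucumber_params()] object.
#' @param thresholds A [grade_thresholds()] object.
#' @return One of the seven labels in [GRADES].
#' @export
assign_grade <- function(params, thresholds = grade_thresholds()) {
  if (!inherits(thresholds, "grade_thresholds"))
    thresholds <- do.call(grade_thresholds, thresholds)
  bend <- params$bend_angle_deg
  len  <- params$arc_length_cm
  curv <- if (bend <= thresholds$bend_a_max_deg) "A"
          else if (bend <= thresholds$bend_b_max_deg) "B" else "C"
  size <- if (len >= thresholds$size_l_min_cm) "L"
          else if (len >= thresholds$size_m_min_cm) "M" else "S"
  if (size == "L" && curv != "A") size <- "M"
  paste0(curv, size)
}

# Sampling cells in (bend, length) space for each grade. Upper bounds for the
# open-ended classes (C bend, S length floor, L length cap) are generator
# study conditions, fixed here: C bends up to 120 degrees, lengths span
# 10-26 cm so an L cucumber still fits inside the marker rectangle.
grade_cells <- function(thresholds, bend_c_max_deg = 120,
                        size_s_min_cm = 10, size_l_max_cm = 26) {
  th <- thresholds
  bend <- list(A = c(0, th$bend_a_max_deg),
               B = c(th$bend_a_max_deg, th$bend_b_max_deg),
               C = c(th$bend_b_max_deg, bend_c_max_deg))
  len <- list(S = c(size_s_min_cm, th$size_m_min_cm),
              M = c(th$size_m_min_cm, th$size_l_min_cm),
              L = c(th$size_l_min_cm, size_l_max_cm))
  cells <- list()
  for (g in GRADES) {
    curv <- substr(g, 1, 1); size <- substr(g, 2, 2)
    l <- len[[size]]
    # bent cucumbers of L length clamp to M, so the BM/CM cells extend to the
    # L cap and stay consistent with assign_grade's round trip
    if (size == "M" && curv != "A") l <- c(l[1], size_l_max_cm)
    cells[[g]] <- list(bend = bend[[curv]], len = l)
  }
  cells
}

#' Sample cucumber parameters for a target grade
#'
#' Draws uniformly within the grade's (bend, length) cell, with thickness
#' uniform in `thickness_range_cm`, and guarantees by rejection that
#' [assign_grade()] maps the result back to `grade`. Deterministic given the
#' RNG state (use `set.seed()`).
#'
#' @param grade One of [GRADES].
#' @param thresholds A [grade_thresholds()] object.
#' @param thickness_range_cm Range of tube diameters to draw from, cm.
#' @return A [cucumber_params()] object.
#' @export
sample_params <- function(grade, thresholds = grade_thresholds(),
                          thickness_range_cm = c(2, 3.5)) {
  if (!grade %in% GRADES)
    config_error(sprintf("unknown grade '%s'", grade))
  cell <- grade_cells(thresholds)[[grade]]
  if (diff(cell$bend) <= 0 || diff(cell$len) <= 0)
    config_error(sprintf("empty parameter cell for grade '%s'", grade))
  for (i in 1:100) {
    p <- cucumber_params(
      arc_length_cm  = stats::runif(1, cell$len[1], cell$len[2]),
      bend_angle_deg = stats::runif(1, cell$bend[1], cell$bend[2]),
      thickness_cm   = stats::runif(1, thickness_range_cm[1], thickness_range_cm[2])
    )
    if (assign_grade(p, thresholds) == grade) return(p)
  }
  config_error(sprintf("could not sample parameters for grade '%s'", grade))
}

# Centerline geometry in local cm coordinates (chord vertical, before
# orientation/translation). Returns a function point -> signed distances used
# by the rasterizer, plus the tight bounding box of the tube.
tube_geometry <- function(params) {
  L <- params$arc_length_cm
  th <- params$bend_angle_deg * pi / 180
  t2 <- params$thickness_cm / 2
  if (th == 0) {
    inside <- function(x, y) abs(x) <= t2 & abs(y) <= L / 2
    bbox <- c(-t2, -L / 2, t2, L / 2)
  } else {
    R <- L / th
    # circle center at (R, 0); arc spans angle phi in [-th/2, th/2] with
    # points (R(1-cos phi), R sin phi); square caps cut at |phi| = th/2
    inside <- function(x, y) {
      vx <- x - R; vy <- y
      r <- sqrt(vx^2 + vy^2)
      phi <- atan2(vy, -vx)
      abs(phi) <= th / 2 & abs(r - R) <= t2
    }
    xmax_center <- R * (1 - cos(th / 2))
    # extremes of the annular sector with square caps
    xmin <- -t2
    xmax <- xmax_center + t2 * cos(th / 2) +
      if (th / 2 > pi / 2) (R - t2) * 0 else 0
    # outer cap corner: (R - (R - t2) cos(th/2), ...) is the max-x point
    xmax <- R - (R - t2) * cos(th / 2)
    ymax <- (R + t2) * sin(th / 2)
    if (th / 2 > pi / 2) ymax <- R + t2  # arc passes the equator
    bbox <- c(xmin, -ymax, xmax, ymax)
  }
  list(inside = inside, bbox = bbox)
}

#' Render a synthetic board-and-cucumber scene
#'
#' Produces an 8-bit RGB raster of a white board with four solid blue square
#' markers whose centers form a rectangle of `board_width_cm x
#' board_height_cm` at `render_px_per_cm`, plus one green tube-shaped
#' cucumber, together with exact ground truth (pixel mask, analytic area,
#' grade).
#'
#' Pixel `(r, c)` (0-based) covers the unit square with center
#' `(c + 0.5, r + 0.5)`; a pixel belongs to the cucumber iff its center lies
#' within `thickness_cm / 2` of the arc centerline (square caps).
#'
#' @param spec A [scene_spec()] object.
#' @param params A [cucumber_params()] object.
#' @param thresholds A [grade_thresholds()] object used to label the truth.
#' @return A list with `image` (H x W x 3 array, 0-255) and `truth`, a
#'   `scene_truth` list carrying `mask`, `params`, `analytic_area_cm2`,
#'   `grade`, and the true marker centers.
#' @export
render_scene <- function(spec = scene_spec(), params,
                         thresholds = grade_thresholds()) {
  ppcm <- spec$render_px_per_cm
  m <- spec$margin_px
  W <- as.integer(round(spec$board_width_cm * ppcm)) + 2L * m
  H <- as.integer(round(spec$board_height_cm * ppcm)) + 2L * m

  # continuous image coordinates of the four marker centers
  mk <- rbind(
    tl = c(m, m),
    tr = c(m + spec$board_width_cm * ppcm, m),
    bl = c(m, m + spec$board_height_cm * ppcm),
    br = c(m + spec$board_width_cm * ppcm, m + spec$board_height_cm * ppcm)
  )

  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- BOARD_COLOR[ch]

  # Pixel centers, shifted by an infinitesimal so that boundaries landing
  # exactly on a center resolve half-open (left-closed): an interval of
  # integer pixel length then contains exactly that many centers at any
  # alignment, keeping rasterized extents free of double-tie overcounts.
  xs <- matrix(seq_len(W) - 0.5 + 1e-6, H, W, byrow = TRUE)
  ys <- matrix(seq_len(H) - 0.5 + 1e-6, H, W)

  half <- spec$marker_size_cm * ppcm / 2
  marker_mask <- matrix(FALSE, H, W)
  for (k in 1:4) {
    marker_mask <- marker_mask |
      (abs(xs - mk[k, 1]) <= half & abs(ys - mk[k, 2]) <= half)
  }
  for (ch in 1:3) {
    plane <- img[, , ch]; plane[marker_mask] <- MARKER_COLOR[ch]
    img[, , ch] <- plane
  }

  # cucumber placement: board-centered unless given, chord rotated by
  # orientation; rasterize only within the (inflated) local bounding box
  center_cm <- params$center
  if (is.null(center_cm))
    center_cm <- c(spec$board_width_cm / 2, spec$board_height_cm / 2)
  geom <- tube_geometry(params)
  bb <- geom$bbox
  shape_center <- c((bb[1] + bb[3]) / 2, (bb[2] + bb[4]) / 2)
  ang <- params$orientation_deg * pi / 180
  cx_px <- m + center_cm[1] * ppcm
  cy_px <- m + center_cm[2] * ppcm

  half_diag <- sqrt(max(abs(bb[c(1, 3)] - shape_center[1]))^2 +
                    max(abs(bb[c(2, 4)] - shape_center[2]))^2)
  r0 <- max(1L, floor(cy_px - half_diag * ppcm - 1))
  r1 <- min(H, ceiling(cy_px + half_diag * ppcm + 1))
  c0 <- max(1L, floor(cx_px - half_diag * ppcm - 1))
  c1 <- min(W, ceiling(cx_px + half_diag * ppcm + 1))

  mask <- matrix(FALSE, H, W)
  if (r1 >= r0 && c1 >= c0) {
    sub_x <- (xs[r0:r1, c0:c1] - cx_px) / ppcm
    sub_y <- (ys[r0:r1, c0:c1] - cy_px) / ppcm
    # undo orientation, then shift back to raw local coordinates
    lx <- cos(ang) * sub_x + sin(ang) * sub_y + shape_center[1]
    ly <- -sin(ang) * sub_x + cos(ang) * sub_y + shape_center[2]
    mask[r0:r1, c0:c1] <- geom$inside(lx, ly)
  }

  if (!any(mask))
    render_error("cucumber rasterized to zero pixels")
  if (any(mask & marker_mask))
    render_error("cucumber overlaps a marker")
  rows <- range(which(rowSums(mask) > 0)); cols <- range(which(colSums(mask) > 0))
  if (rows[1] == 1 || cols[1] == 1 || rows[2] == H || cols[2] == W)
    render_error("cucumber touches the image border")

  for (ch in 1:3) {
    plane <- img[, , ch]; plane[mask] <- params$color[ch]
    img[, , ch] <- plane
  }

  if (spec$background_noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, spec$background_noise_sd),
                       dim = dim(img))
    img <- round(pmin(pmax(img, 0), 255))
  }

  truth <- structure(list(
    mask = mask,
    params = params,
    analytic_area_cm2 = params$arc_length_cm * params$thickness_cm,
    grade = assign_grade(params, thresholds),
    marker_centers = mk
  ), class = "scene_truth")
  list(image = img, truth = truth)
}

#' Generate a graded synthetic dataset on disk
#'
#' Renders scenes for each grade, writes them as PNG files named
#' `<GRADE>_<sequence>.png` (the grade is embedded at the start of the file
#' name, with a sequence number to prevent duplication) and a `manifest.csv`
#' with the true geometry.
#'
#' @param n_per_grade Either a single count used for all grades or a vector of
#'   7 counts named/ordered as [GRADES].
#' @param out_dir Output directory (created if needed).
#' @param spec,thresholds Scene and threshold configuration.
#' @param seed Integer seed making the dataset fully reproducible.
#' @return The manifest as a data.frame (invisibly also written to
#'   `out_dir/manifest.csv`), columns `filename`, `grade`, `arc_length_cm`,
#'   `bend_deg`, `thickness_cm`.
#' @export
generate_dataset <- function(n_per_grade, out_dir, spec = scene_spec(),
                             thresholds = grade_thresholds(), seed = 1L) {
  if (length(n_per_grade) == 1L) n_per_grade <- rep(n_per_grade, 7L)
  if (length(n_per_grade) != 7L || any(n_per_grade < 1))
    config_error("'n_per_grade' must be one count or seven counts >= 1")
  n_per_grade <- as.integer(n_per_grade)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) io_error(sprintf("cannot create '%s'", out_dir))

  set.seed(seed)
  rows <- vector("list", sum(n_per_grade))
  k <- 0L
  for (gi in seq_along(GRADES)) {
    g <- GRADES[gi]
    for (i in seq_len(n_per_grade[gi])) {
      p <- sample_params(g, thresholds)
      sc <- render_scene(spec, p, thresholds)
      fn <- sprintf("%s_%04d.png", g, i)
      write_scene(sc$image, file.path(out_dir, fn))
      k <- k + 1L
      rows[[k]] <- data.frame(
        filename = fn, grade = g,
        arc_length_cm = p$arc_length_cm,
        bend_deg = p$bend_angle_deg,
        thickness_cm = p$thickness_cm,
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
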