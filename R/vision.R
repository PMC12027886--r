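# Default channel-dominance thresholds (8-bit intensity units) for marker and
# cucumber segmentation; suited to the controlled white-board setting.
TAU_BLUE  <- 40
TAU_GREEN <- 40

#' Detect the four corner markers
#'
#' Markers are found as the four largest blue-dominant connected components
#' (pixel `p` is blue-dominant iff `B(p) - max(R(p), G(p)) > tau_b`), and
#' labelled `tl`/`tr`/`bl`/`br` by their quadrant relative to the centroid of
#' the four centers.
#'
#' @param image H x W x 3 array, 0-255.
#' @param tau_b Blue-dominance threshold.
#' @return A `marker_set`: matrix `centers` (rows tl, tr, bl, br; columns x, y
#'   in continuous image coordinates where pixel `(r, c)` has center
#'   `(c - 0.5, r - 0.5)` for 1-based `r, c`), and `half_size_px`, the
#'   estimated marker half side used to erode the measurement region.
#' @export
detect_markers <- function(image, tau_b = TAU_BLUE) {
  dom <- image[, , 3] - pmax(image[, , 1], image[, , 2])
  bw <- dom > tau_b
  if (!any(bw)) marker_error("no blue-dominant pixels found")
  lab <- EBImage::bwlabel(bw * 1)
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) < 4L)
    marker_error(sprintf("found %d blue region(s), need 4", length(sizes)))
  keep <- order(sizes, decreasing = TRUE)[1:4]

  centers <- t(vapply(keep, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    c(mean(idx[, 2]) - 0.5, mean(idx[, 1]) - 0.5)  # (x, y) pixel-center coords
  }, numeric(2)))
  ctr <- colMeans(centers)
  quad <- paste0(ifelse(centers[, 2] < ctr[2], "t", "b"),
                 ifelse(centers[, 1] < ctr[1], "l", "r"))
  if (anyDuplicated(quad))
    marker_error("ambiguous marker layout: two centers share a quadrant")
  ord <- match(c("tl", "tr", "bl", "br"), quad)
  centers <- centers[ord, , drop = FALSE]
  rownames(centers) <- c("tl", "tr", "bl", "br")
  colnames(centers) <- c("x", "y")
  structure(list(
    centers = centers,
    half_size_px = sqrt(stats::median(sizes[keep])) / 2
  ), class = "marker_set")
}

#' Pixel-to-centimetre calibration from the marker rectangle
#'
#' The horizontal scale is the mean of the top and bottom inter-marker center
#' distances divided by the known board width; the vertical scale likewise
#' from the left and right distances and the board height. This ratio is what
#' makes all measurements independent of the camera distance.
#'
#' @param markers A `marker_set` from [detect_markers()].
#' @param board_width_cm,board_height_cm Known physical marker spacing, cm.
#' @return A `calibration` list with `px_per_cm_x` and `px_per_cm_y`.
#' @export
compute_calibration <- function(markers, board_width_cm = 40,
                                board_height_cm = 30) {
  cc <- markers$centers
  d <- function(a, b) sqrt(sum((cc[a, ] - cc[b, ])^2))
  top <- d("tl", "tr"); bottom <- d("bl", "br")
  left <- d("tl", "bl"); right <- d("tr", "br")
  if (min(top, bottom, left, right) <= 0)
    calibration_error("degenerate marker quadrilateral")
  structure(list(
    px_per_cm_x = mean(c(top, bottom)) / board_width_cm,
    px_per_cm_y = mean(c(left, right)) / board_height_cm
  ), class = "calibration")
}

# Half-plane test: TRUE for pixel centers inside the convex quadrilateral of
# marker centers shrunk inward by `erode_px`.
inside_eroded_quad <- function(H, W, centers, erode_px) {
  # order corners counter-clockwise in image coords (y down): tl, tr, br, bl
  poly <- centers[c("tl", "tr", "br", "bl"), , drop = FALSE]
  xs <- matrix(seq_len(W) - 0.5, H, W, byrow = TRUE)
  ys <- matrix(seq_len(H) - 0.5, H, W)
  inside <- matrix(TRUE, H, W)
  for (i in 1:4) {
    a <- poly[i, ]; b <- poly[if (i == 4) 1 else i + 1, ]
    e <- b - a; len <- sqrt(sum(e^2))
    n <- c(-e[2], e[1]) / len          # inward normal (y down, CW traversal)
    inside <- inside & ((xs - a[1]) * n[1] + (ys - a[2]) * n[2] >= erode_px)
  }
  inside
}

#' Segment the cucumber
#'
#' Green-dominance mask (`G - max(R, B) > tau_g`) restricted to the marker
#' quadrilateral interior eroded by the marker half-size; the largest
#' connected component is kept.
#'
#' @param image H x W x 3 array, 0-255.
#' @param markers A `marker_set` from [detect_markers()].
#' @param tau_g Green-dominance threshold.
#' @return A `segmentation` list: logical `mask`, `bbox` as
#'   `c(x0, y0, x1, y1)` (0-based, half-open), `n_pixels`.
#' @export
segment_cucumber <- function(image, markers, tau_g = TAU_GREEN) {
  H <- dim(image)[1]; W <- dim(image)[2]
  dom <- image[, , 2] - pmax(image[, , 1], image[, , 3])
  bw <- (dom > tau_g) &
    inside_eroded_quad(H, W, markers$centers, markers$half_size_px)
  if (!any(bw)) segmentation_error("no green-dominant pixels inside the board")
  lab <- EBImage::bwlabel(bw * 1)
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  rows <- which(rowSums(mask) > 0); cols <- which(colSums(mask) > 0)
  structure(list(
    mask = mask,
    bbox = c(x0 = min(cols) - 1L, y0 = min(rows) - 1L,
             x1 = max(cols), y1 = max(rows)),
    n_pixels = sum(mask)
  ), class = "segmentation")
}

#' Calibrated measurements of a segmented cucumber
#'
#' Height is the vertical bounding-box extent over the vertical scale, width
#' the horizontal extent over the horizontal scale, and area the pixel count
#' over the product of the scales. A bent cucumber widens its bounding box,
#' so width doubles as a curvature proxy.
#'
#' @param seg A `segmentation` from [segment_cucumber()].
#' @param cal A `calibration` from [compute_calibration()].
#' @return A `measure` list: `height_cm`, `width_cm`, `area_cm2`.
#' @export
measure_cucumber <- function(seg, cal) {
  b <- seg$bbox
  structure(list(
    height_cm = unname(b["y1"] - b["y0"]) / cal$px_per_cm_y,
    width_cm  = unname(b["x1"] - b["x0"]) / cal$px_per_cm_x,
    area_cm2  = seg$n_pixels / (cal$px_per_cm_x * cal$px_per_cm_y)
  ), class = "measure")
}
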