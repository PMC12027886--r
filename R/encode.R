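# Canvas geometry: 100 px wide x 340 px tall, portrait, matching a vertically
# placed cucumber pasted at a fixed physical scale (default 10 px/cm).
CANVAS_W <- 100L
CANVAS_H <- 340L

#' Normalization ranges for the background encoding
#'
#' Fixed physical maxima used to map measurements into `[0, 1]` before
#' quantization, chosen as the canvas's physical extent at 10 px/cm (34 cm
#' tall, 10 cm wide) plus a generous area bound, so the encoding is stable
#' across datasets rather than tied to one dataset's min-max.
#'
#' @param height_max_cm,width_max_cm,area_max_cm2 Upper ends of the ranges.
#' @return A `norm_ranges` list.
#' @export
norm_ranges <- function(height_max_cm = 34, width_max_cm = 10,
                        area_max_cm2 = 170) {
  stopifnot_scalar_num(height_max_cm, "height_max_cm")
  stopifnot_scalar_num(width_max_cm, "width_max_cm")
  stopifnot_scalar_num(area_max_cm2, "area_max_cm2")
  structure(list(height_max_cm = height_max_cm, width_max_cm = width_max_cm,
                 area_max_cm2 = area_max_cm2), class = "norm_ranges")
}

#' Normalize measurements to `[0, 1]`
#'
#' @param m A `measure` from [measure_cucumber()].
#' @param r A [norm_ranges()] object.
#' @return Numeric triplet `(h, w, a)`, each clipped to `[0, 1]`.
#' @export
normalize_measures <- function(m, r = norm_ranges()) {
  v <- c(h = m$height_cm / r$height_max_cm,
         w = m$width_cm / r$width_max_cm,
         a = m$area_cm2 / r$area_max_cm2)
  pmin(pmax(v, 0), 1)
}

#' Encode a normalized triplet as a background colour
#'
#' The normalized height, width and area are assigned to the B, G and R
#' channels respectively, quantized to 8 bits by round-half-up. The all-zero
#' triplet reproduces the plain black background of the baseline method, so
#' both flavours share one code path.
#'
#' @param t Numeric triplet in `[0, 1]^3` ordered (height, width, area).
#' @return Integer RGB triplet `c(R, G, B)` in 0-255.
#' @export
encode_bg <- function(t) {
  if (length(t) != 3L || any(!is.finite(t)) || any(t < 0) || any(t > 1))
    config_error("encode_bg() needs a triplet in [0,1]^3")
  q <- floor(255 * t + 0.5)
  c(R = q[[3]], G = q[[2]], B = q[[1]])
}

#' Decode the background colour of a canvas
#'
#' Reads the background from the canvas corners (which can never be object
#' pixels, since crops are pasted centered and overflow is an error) and
#' inverts [encode_bg()].
#'
#' @param canvas A `canvas` from [compose_canvas()], or a raw H x W x 3 array.
#' @return Numeric triplet (height, width, area) in `[0, 1]`.
#' @export
decode_bg <- function(canvas) {
  px <- if (inherits(canvas, "canvas")) canvas$pixels else canvas
  H <- dim(px)[1]; W <- dim(px)[2]
  corners <- rbind(px[1, 1, ], px[1, W, ], px[H, 1, ], px[H, W, ])
  if (any(apply(corners, 2, function(ch) max(ch) - min(ch)) > 0))
    decode_error("canvas corners disagree: background is not uniform")
  c(h = corners[1, 3], w = corners[1, 2], a = corners[1, 1]) / 255
}

#' Rescale a segmented crop to the canvas's physical scale
#'
#' Resamples the bounding-box contents (bilinear) and its mask (nearest) by
#' `canvas_px_per_cm / px_per_cm` per axis, so the object lands on the canvas
#' at a fixed physical scale regardless of the camera distance of the source
#' image.
#'
#' @param image Source H x W x 3 array, 0-255.
#' @param seg A `segmentation` from [segment_cucumber()].
#' @param cal A `calibration` from [compute_calibration()].
#' @param canvas_px_per_cm Target scale on the canvas.
#' @return List `crop` (h x w x 3) and `mask` (logical h x w).
#' @export
rescale_crop <- function(image, seg, cal, canvas_px_per_cm = 10) {
  b <- seg$bbox
  rows <- (b["y0"] + 1):b["y1"]; cols <- (b["x0"] + 1):b["x1"]
  crop <- image[rows, cols, , drop = FALSE]
  mask <- seg$mask[rows, cols, drop = FALSE]
  fy <- canvas_px_per_cm / cal$px_per_cm_y
  fx <- canvas_px_per_cm / cal$px_per_cm_x
  out_h <- max(1L, as.integer(round(nrow(mask) * fy)))
  out_w <- max(1L, as.integer(round(ncol(mask) * fx)))
  if (out_h > CANVAS_H || out_w > CANVAS_W)
    crop_overflow_error(sprintf(
      "rescaled crop %d x %d exceeds the %d x %d canvas",
      out_h, out_w, CANVAS_H, CANVAS_W))
  if (fy != 1 || fx != 1) {
    crop <- resize_rgb(crop, out_h, out_w)
    mask <- resize_mask(mask, out_h, out_w)
  }
  list(crop = crop, mask = mask)
}

#' Compose the training canvas
#'
#' Fills a 100 x 340 canvas with `bg_color` and pastes the crop centered,
#' copying only pixels where the mask is true, so every non-object pixel
#' equals `bg_color` exactly and the crop's rectangular background does not
#' leak.
#'
#' @param crop h x w x 3 array, 0-255.
#' @param crop_mask Logical h x w object mask.
#' @param bg_color RGB triplet `c(R, G, B)`, 0-255.
#' @param label Optional grade label carried along.
#' @return A `canvas` object: `pixels` (340 x 100 x 3), `bg_color`, `label`.
#' @export
compose_canvas <- function(crop, crop_mask, bg_color = c(0, 0, 0),
                           label = NULL) {
  ch <- nrow(crop_mask); cw <- ncol(crop_mask)
  if (ch > CANVAS_H || cw > CANVAS_W)
    crop_overflow_error(sprintf("crop %d x %d exceeds the %d x %d canvas",
                                ch, cw, CANVAS_H, CANVAS_W))
  px <- array(0, dim = c(CANVAS_H, CANVAS_W, 3))
  for (k in 1:3) px[, , k] <- bg_color[k]
  oy <- (CANVAS_H - ch) %/% 2L; ox <- (CANVAS_W - cw) %/% 2L
  for (k in 1:3) {
    plane <- px[oy + seq_len(ch), ox + seq_len(cw), k]
    plane[crop_mask] <- crop[, , k][crop_mask]
    px[oy + seq_len(ch), ox + seq_len(cw), k] <- plane
  }
  structure(list(pixels = px, bg_color = bg_color, label = label),
            class = "canvas")
}

#' Build one training sample from a scene image
#'
#' Runs segment, measure, rescale and compose. With `variant = "with_rgb"`
#' the background carries the encoded normalized measurements; otherwise it
#' is black and the raw measurements are returned for use as side-channel
#' numerics.
#'
#' @param image H x W x 3 scene array, 0-255.
#' @param variant `"with_rgb"` or `"without_rgb"` (the image-only ablation
#'   does not use canvases; see [image_only_input()]).
#' @param markers Optional pre-detected `marker_set`; detected if `NULL`.
#' @param cal Optional pre-computed `calibration`; computed if `NULL`.
#' @param ranges A [norm_ranges()] object.
#' @param canvas_px_per_cm Physical scale of the canvas.
#' @param board_width_cm,board_height_cm Marker spacing used if `cal` is NULL.
#' @param label Optional grade label attached to the canvas.
#' @return List `canvas` (a `canvas`) and `measure` (a `measure`).
#' @export
build_sample <- function(image, variant = c("with_rgb", "without_rgb"),
                         markers = NULL, cal = NULL, ranges = norm_ranges(),
                         canvas_px_per_cm = 10, board_width_cm = 40,
                         board_height_cm = 30, label = NULL) {
  variant <- match.arg(variant, c("with_rgb", "without_rgb", "image_only"))
  if (is.null(markers)) markers <- detect_markers(image)
  if (is.null(cal))
    cal <- compute_calibration(markers, board_width_cm, board_height_cm)
  seg <- segment_cucumber(image, markers)
  m <- measure_cucumber(seg, cal)
  rc <- rescale_crop(image, seg, cal, canvas_px_per_cm)
  bg <- if (variant == "with_rgb") encode_bg(normalize_measures(m, ranges))
        else c(0, 0, 0)
  list(canvas = compose_canvas(rc$crop, rc$mask, bg, label = label),
       measure = m)
}
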