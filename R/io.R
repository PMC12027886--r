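#' Read an 8-bit RGB scene image
#'
#' @param path PNG file path.
#' @return H x W x 3 numeric array with values 0-255.
#' @export
read_scene <- function(path) {
  if (!file.exists(path)) io_error(sprintf("no such file: '%s'", path))
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  round(a * 255)
}

#' Write an 8-bit RGB scene image
#'
#' @param img H x W x 3 numeric array, values 0-255.
#' @param path Destination PNG path.
#' @export
write_scene <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 255) / 255, path)
  invisible(path)
}

# EBImage uses (x, y, channel) storage; package arrays are (row=y, col=x, ch).
to_ebimage <- function(img) {
  EBImage::Image(aperm(img, c(2, 1, 3)) / 255, colormode = "Color")
}
from_ebimage <- function(ei) {
  aperm(EBImage::imageData(ei), c(2, 1, 3)) * 255
}

# Bilinear resize of an (H, W, 3) array; exact on uniform regions.
resize_rgb <- function(img, out_h, out_w) {
  from_ebimage(EBImage::resize(to_ebimage(img), w = out_w, h = out_h,
                               filter = "bilinear"))
}

# Nearest-neighbour resize of a logical mask so it stays boolean.
resize_mask <- function(mask, out_h, out_w) {
  m <- EBImage::resize(EBImage::Image(t(mask) * 1), w = out_w, h = out_h,
                       filter = "none")
  t(EBImage::imageData(m)) > 0.5
}
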