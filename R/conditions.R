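#' @useDynLib cucumgrade, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Structured conditions: every package error carries "cg_error" plus a
# stage-specific class so callers (and the CLI) can map failures to exit codes.
cg_abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "cg_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

config_error       <- function(msg) cg_abort(msg, "cg_config_error")
data_error         <- function(msg) cg_abort(msg, "cg_data_error")
render_error       <- function(msg) cg_abort(msg, "cg_render_error")
io_error           <- function(msg) cg_abort(msg, "cg_io_error")
marker_error       <- function(msg) cg_abort(msg, "cg_marker_detection_error")
calibration_error  <- function(msg) cg_abort(msg, "cg_calibration_error")
segmentation_error <- function(msg) cg_abort(msg, "cg_segmentation_error")
crop_overflow_error<- function(msg) cg_abort(msg, "cg_crop_overflow_error")
decode_error       <- function(msg) cg_abort(msg, "cg_decode_error")

stopifnot_scalar_num <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    config_error(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0)
    config_error(sprintf("'%s' must be > 0", name))
  invisible(x)
}
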