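#' B-scan time series container
#'
#' Wraps a 3-D array of non-negative OCT amplitude values ordered as
#' (frame, depth row, lateral column) together with the acquisition frame
#' rate and the physical pixel pitches. Depth increases downward: the
#' superficial epithelium sits at low row indices.
#'
#' @param data numeric array, dim = c(n_frames, n_depth, n_ascans); finite,
#'   non-negative amplitudes.
#' @param frame_rate_hz effective B-scan repetition rate in Hz.
#' @param axial_um_per_px axial pixel pitch in micrometres.
#' @param lateral_um_per_px lateral pixel pitch in micrometres.
#' @return an object of class `bscan_series`.
#' @export
bscan_series <- function(data, frame_rate_hz, axial_um_per_px = 1,
                         lateral_um_per_px = 1) {
  if (!is.array(data) || length(dim(data)) != 3L)
    validation_error("'data' must be a 3-D array (frame, depth, lateral)")
  if (anyNA(data) || any(!is.finite(data)))
    validation_error("amplitudes must be finite")
  if (any(data < 0))
    validation_error("amplitudes must be non-negative")
  check_scalar(frame_rate_hz, "frame_rate_hz", 0, strict = TRUE)
  check_scalar(axial_um_per_px, "axial_um_per_px", 0, strict = TRUE)
  check_scalar(lateral_um_per_px, "lateral_um_per_px", 0, strict = TRUE)
  structure(
    list(data = data, frame_rate_hz = frame_rate_hz,
         axial_um_per_px = axial_um_per_px,
         lateral_um_per_px = lateral_um_per_px),
    class = "bscan_series")
}

#' @export
dim.bscan_series <- function(x) dim(x$data)

#' @export
print.bscan_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<bscan_series> %d frames of %d x %d px @ %.6g Hz (%.3g s, Nyquist %.6g Hz)\n",
    d[1], d[2], d[3], x$frame_rate_hz, d[1] / x$frame_rate_hz,
    x$frame_rate_hz / 2))
  invisible(x)
}

n_frames <- function(series) dim(series$data)[1]

#' Region-of-interest mask
#'
#' A labelled boolean mask on the spatial grid of a single B-scan
#' (depth rows x lateral columns).
#'
#' @param mask logical matrix (depth x lateral).
#' @param label one of `"total_epithelium"`, `"basal_epithelium"`, `"stroma"`
#'   or a free-form label.
#' @return an object of class `roi_mask`.
#' @export
roi_mask <- function(mask, label = "roi") {
  if (is.numeric(mask)) mask <- mask > 0
  if (!is.matrix(mask) || !is.logical(mask))
    validation_error("'mask' must be a logical matrix")
  if (anyNA(mask)) validation_error("mask may not contain NA")
  structure(list(mask = mask, label = as.character(label)[1]),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s': %d / %d px\n", x$label,
              sum(x$mask), length(x$mask)))
  invisible(x)
}

# Check an roi_mask against the spatial grid of a series or image; returns
# the bare logical matrix.
mask_on_grid <- function(roi, grid_dim) {
  if (!inherits(roi, "roi_mask")) roi <- roi_mask(roi)
  if (!identical(dim(roi$mask), as.integer(grid_dim)))
    validation_error(sprintf(
      "mask grid %d x %d does not match image grid %d x %d",
      nrow(roi$mask), ncol(roi$mask), grid_dim[1], grid_dim[2]))
  roi$mask
}
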