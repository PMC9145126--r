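#' Motility coefficient of a region
#'
#' The normalized temporal standard deviation of the amplitude signal:
#' for each ROI pixel the temporal sample SD is divided by the temporal
#' mean, and the per-pixel coefficients of variation are averaged over the
#' region. A proxy for intracellular motion; scale-invariant in amplitude.
#'
#' @param series a [bscan_series()].
#' @param roi an [roi_mask()] on the same spatial grid with at least one
#'   pixel; every ROI pixel must have a positive temporal mean.
#' @return dimensionless non-negative scalar.
#' @export
motility_coefficient <- function(series, roi) {
  if (!inherits(series, "bscan_series")) validation_error("'series' must be a bscan_series")
  d <- dim(series$data)
  m <- mask_on_grid(roi, d[2:3])
  idx <- which(m)
  if (!length(idx)) validation_error("ROI is empty")
  x <- series$data
  dim(x) <- c(d[1], d[2] * d[3])
  x <- x[, idx, drop = FALSE]
  mu <- colMeans(x)
  nzero <- sum(mu <= 0)
  if (nzero > 0)
    validation_error(sprintf(
      "%d ROI pixel(s) have zero temporal mean; motility undefined there", nzero))
  sdv <- sqrt(colSums(sweep(x, 2, mu)^2) / (d[1] - 1))
  mean(sdv / mu)
}

#' Circular hue histogram of a region
#'
#' Converts the RGB dynamic-contrast image to HSV, drops pixels whose
#' saturation or value fall below the thresholds (hue is numerically
#' unstable there), and histograms the remaining hues on the wrapped domain
#' `[120, 480)` degrees. The wrap places green at both ends
#' (120 == 480) so blue (240), red (360) and yellow (420) are interior and a
#' yellow-to-red shift is continuous.
#'
#' @param image a `dynamic_image` with channels in [0, 1].
#' @param roi an [roi_mask()] on the image grid, non-empty after exclusion.
#' @param n_bins number of equal bins over [120, 480); default 360.
#' @param saturation_threshold,value_threshold exclusion thresholds in
#'   [0, 1]; defaults 0.1 and 0.05.
#' @return an object of class `hue_histogram`: list with `bin_edges`
#'   (length `n_bins + 1`), `counts`, `n_pixels_used` and the thresholds.
#' @export
hue_histogram <- function(image, roi, n_bins = 360L,
                          saturation_threshold = 0.1,
                          value_threshold = 0.05) {
  if (!inherits(image, "dynamic_image")) validation_error("'image' must be a dynamic_image")
  m <- mask_on_grid(roi, dim(image$r))
  idx <- which(m)
  if (!length(idx)) validation_error("ROI is empty")
  rgb <- rbind(image$r[idx], image$g[idx], image$b[idx])
  if (any(rgb < 0) || any(rgb > 1))
    validation_error("image channels must lie in [0, 1]")
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  keep <- hsv[2, ] >= saturation_threshold & hsv[3, ] >= value_threshold
  if (!any(keep))
    validation_error("all ROI pixels fall below the saturation/value thresholds")
  h <- hsv[1, keep] * 360
  h <- ifelse(h < 120, h + 360, h)        # wrap green-to-green
  edges <- seq(120, 480, length.out = n_bins + 1L)
  bin <- pmin(pmax(floor((h - 120) / (360 / n_bins)) + 1L, 1L), n_bins)
  structure(
    list(bin_edges = edges, counts = tabulate(bin, nbins = n_bins),
         n_pixels_used = sum(keep),
         saturation_threshold = saturation_threshold,
         value_threshold = value_threshold),
    class = "hue_histogram")
}

#' @export
print.hue_histogram <- function(x, ...) {
  cat(sprintf("<hue_histogram> %d bins on [120, 480) deg, %d pixels\n",
              length(x$counts), x$n_pixels_used))
  invisible(x)
}

#' Peaks of a circular hue histogram
#'
#' Smooths the counts with a circular moving average, finds local maxima,
#' suppresses any maximum closer than `min_separation_deg` (circular
#' distance) to a taller one, and returns up to `n_peaks` peaks tallest
#' first. Ties break toward the lower wrapped degree.
#'
#' @param hist a [hue_histogram()].
#' @param n_peaks maximum number of peaks to return (>= 1).
#' @param smooth_window odd moving-average width in bins; default 9.
#' @param min_separation_deg minimum circular separation between reported
#'   peaks in degrees; default 30.
#' @return data.frame with columns `hue_deg` (bin-center degrees on
#'   [120, 480)) and `height` (smoothed count), tallest first; may have
#'   fewer than `n_peaks` rows.
#' @export
find_hue_peaks <- function(hist, n_peaks = 1L, smooth_window = 9L,
                           min_separation_deg = 30) {
  if (!inherits(hist, "hue_histogram")) validation_error("'hist' must be a hue_histogram")
  if (!is_scalar_number(n_peaks) || n_peaks < 1)
    validation_error("'n_peaks' must be >= 1")
  if (!is_scalar_number(smooth_window) || smooth_window < 1 ||
      smooth_window %% 2 != 1)
    validation_error("'smooth_window' must be an odd positive integer")
  n <- length(hist$counts)
  deg_per_bin <- 360 / n
  centers <- hist$bin_edges[-(n + 1)] + deg_per_bin / 2
  s <- circular_smooth(hist$counts, as.integer(smooth_window))
  left <- s[c(n, 1:(n - 1))]
  right <- s[c(2:n, 1)]
  cand <- which(s >= left & s >= right & s > 0)
  if (!length(cand)) return(data.frame(hue_deg = numeric(0), height = numeric(0)))
  # collapse plateaus (contiguous candidate runs share one smoothed value)
  # to their central bin; runs may wrap across the circular boundary
  run_id <- cumsum(c(1, diff(cand) > 1))
  runs <- split(cand, run_id)
  if (length(runs) > 1 && cand[1] == 1L && cand[length(cand)] == n) {
    runs[[1]] <- c(runs[[length(runs)]], runs[[1]])
    runs[[length(runs)]] <- NULL
  }
  cand <- vapply(runs, function(r) r[ceiling(length(r) / 2)], integer(1))
  # order: height desc, then lower wrapped degree
  cand <- unname(cand[order(-s[cand], centers[cand])])
  picked <- integer(0)
  for (i in cand) {
    if (length(picked)) {
      dd <- abs(centers[i] - centers[picked])
      dd <- pmin(dd, 360 - dd)
      if (any(dd < min_separation_deg)) next
    }
    picked <- c(picked, i)
    if (length(picked) >= n_peaks) break
  }
  data.frame(hue_deg = centers[picked], height = s[picked])
}

circular_smooth <- function(counts, window) {
  if (window <= 1) return(as.numeric(counts))
  n <- length(counts)
  half <- (window - 1L) %/% 2L
  ext <- c(counts[(n - half + 1L):n], counts, counts[1:half])
  as.numeric(stats::filter(ext, rep(1 / window, window), sides = 2))[(half + 1L):(half + n)]
}

#' Mean columnwise thickness of a mask
#'
#' For each lateral column that contains mask pixels, the thickness is the
#' columnwise extent `(max row - min row + 1) * axial_um_per_px`; the mean
#' over those columns is returned. Column extent (rather than connected
#' height) is robust to small holes in the mask.
#'
#' @param roi an [roi_mask()] with at least one pixel.
#' @param axial_um_per_px axial pixel pitch in micrometres (> 0).
#' @return mean thickness in micrometres.
#' @export
thickness_from_mask <- function(roi, axial_um_per_px) {
  if (!inherits(roi, "roi_mask")) roi <- roi_mask(roi)
  check_scalar(axial_um_per_px, "axial_um_per_px", 0, strict = TRUE)
  m <- roi$mask
  if (!any(m)) validation_error("mask is empty")
  cols <- which(colSums(m) > 0)
  ext <- vapply(cols, function(j) {
    r <- which(m[, j])
    max(r) - min(r) + 1L
  }, integer(1))
  mean(ext) * axial_um_per_px
}

#' Repeatability statistics of repeated measurements
#'
#' Standard definitions: coefficient of variation `cv = sample SD / mean`
#' and coefficient of repeatability `cor = 1.96 * sqrt(2) * sample SD`
#' (the 95% limit for the difference between two repeated measurements).
#'
#' @param values numeric vector of at least 2 repeated measurements; the
#'   mean must be nonzero for `cv`.
#' @return list with elements `cv` and `cor`.
#' @export
repeatability_stats <- function(values) {
  if (!is.numeric(values) || length(values) < 2 || anyNA(values))
    validation_error("'values' must be >= 2 finite numbers")
  mu <- mean(values)
  if (mu == 0) validation_error("mean is zero; coefficient of variation undefined")
  s <- stats::sd(values)
  list(cv = s / mu, cor = 1.96 * sqrt(2) * s)
}
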