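#' Frequency-band specification
#'
#' Three ordered half-open frequency intervals mapped to output channels:
#' slow to blue, medium to green, fast to red. Defaults follow the standard
#' dmOCT coloring: blue 0-0.5 Hz (static tissue), green 0.5-5 Hz, red
#' 5-25 Hz.
#'
#' @param slow,medium,fast numeric length-2 vectors `[f_lo, f_hi)` in Hz,
#'   ordered `0 <= slow < medium < fast`.
#' @return an object of class `band_spec`.
#' @export
band_spec <- function(slow = c(0, 0.5), medium = c(0.5, 5), fast = c(5, 25)) {
  edges <- c(slow, medium, fast)
  if (length(edges) != 6L || !is.numeric(edges) || anyNA(edges))
    config_error("each band must be a numeric [lo, hi) pair")
  if (!(0 <= slow[1] && slow[1] < slow[2] && slow[2] <= medium[1] &&
        medium[1] < medium[2] && medium[2] <= fast[1] && fast[1] < fast[2]))
    config_error("bands must satisfy 0 <= slow.lo < slow.hi <= medium.lo < medium.hi <= fast.lo < fast.hi")
  structure(list(slow = as.numeric(slow), medium = as.numeric(medium),
                 fast = as.numeric(fast)),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> blue [%g, %g) Hz | green [%g, %g) Hz | red [%g, %g) Hz\n",
              x$slow[1], x$slow[2], x$medium[1], x$medium[2],
              x$fast[1], x$fast[2]))
  invisible(x)
}

#' Spectral bins belonging to each band
#'
#' Assigns the one-sided DFT bins `k = 0..floor(n/2)` (center frequencies
#' `k * frame_rate / n_frames`) to bands by half-open interval membership.
#' The DC bin (0 Hz) falls in the slow band when its interval starts at 0;
#' bins at or above the fast band's upper edge are discarded.
#'
#' @param bands a [band_spec()].
#' @param n_frames number of frames in the time series.
#' @param frame_rate_hz frame rate in Hz.
#' @return named list `slow`, `medium`, `fast` of 0-based bin indices.
#' @examples
#' band_bins(band_spec(), 150, 111)  # slow: 0; medium: 1..6; fast: 7..33
#' @export
band_bins <- function(bands, n_frames, frame_rate_hz) {
  if (!inherits(bands, "band_spec")) config_error("'bands' must be a band_spec")
  k <- 0:floor(n_frames / 2)
  f <- k * frame_rate_hz / n_frames
  lapply(bands[c("slow", "medium", "fast")],
         function(iv) k[f >= iv[1] & f < iv[2]])
}

#' Per-voxel temporal amplitude spectrum
#'
#' Fourier transforms each voxel's amplitude time series (no window, no
#' detrending, DC retained) and keeps the magnitudes of the one-sided
#' spectrum, bins `k = 0..floor(n/2)` at center frequencies
#' `k * frame_rate / n_frames` up to the Nyquist frequency `frame_rate / 2`.
#'
#' @param series a [bscan_series()] with at least 2 frames.
#' @return an object of class `temporal_spectrum`: list with `amplitude`
#'   (array bins x depth x lateral), `freq_hz`, `n_frames`, `frame_rate_hz`
#'   and the pixel pitches.
#' @export
temporal_spectrum <- function(series) {
  if (!inherits(series, "bscan_series")) validation_error("'series' must be a bscan_series")
  d <- dim(series$data)
  if (d[1] < 2) validation_error("temporal spectrum requires at least 2 frames")
  m <- series$data
  dim(m) <- c(d[1], d[2] * d[3])
  sp <- Mod(stats::mvfft(m))
  nb <- floor(d[1] / 2) + 1L
  sp <- sp[seq_len(nb), , drop = FALSE]
  dim(sp) <- c(nb, d[2], d[3])
  structure(
    list(amplitude = sp,
         freq_hz = (0:(nb - 1L)) * series$frame_rate_hz / d[1],
         n_frames = d[1], frame_rate_hz = series$frame_rate_hz,
         axial_um_per_px = series$axial_um_per_px,
         lateral_um_per_px = series$lateral_um_per_px),
    class = "temporal_spectrum")
}

#' Construct a dynamic-contrast image
#'
#' Low-level constructor for the three-channel dynamic-contrast container.
#' Normally produced by [band_integrals()] or [process_series()]; exposed for
#' building images directly (e.g. in tests or when importing external data).
#'
#' @param r,g,b numeric matrices (depth x lateral) sharing one grid.
#' @param bands the [band_spec()] the channels were computed with.
#' @param n_frames_used number of frames behind the integrals.
#' @param state provenance tag: `"raw_integrals"`, `"normalized"`,
#'   `"histogram_matched"` or `"averaged"`.
#' @param axial_um_per_px,lateral_um_per_px pixel pitches in micrometres.
#' @return an object of class `dynamic_image`.
#' @export
new_dynamic_image <- function(r, g, b, bands, n_frames_used, state,
                              axial_um_per_px = 1, lateral_um_per_px = 1) {
  if (!is.matrix(r) || !identical(dim(r), dim(g)) || !identical(dim(r), dim(b)))
    validation_error("channels must be matrices on one grid")
  structure(list(r = r, g = g, b = b, bands = bands,
                 n_frames_used = n_frames_used,
                 normalization_state = state,
                 axial_um_per_px = axial_um_per_px,
                 lateral_um_per_px = lateral_um_per_px),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  cat(sprintf("<dynamic_image> %d x %d px, state '%s', %d frames\n",
              nrow(x$r), ncol(x$r), x$normalization_state, x$n_frames_used))
  invisible(x)
}

#' Integral spectral amplitude per frequency band
#'
#' Sums the temporal spectral magnitudes of every voxel over the bins whose
#' center frequency falls in each band's half-open interval, producing the
#' raw three-channel dynamic-contrast image (fast -> red, medium -> green,
#' slow -> blue). Bins at or above the fast band's upper edge are discarded.
#'
#' @param spectrum a [temporal_spectrum()].
#' @param bands a [band_spec()]; the fast band's upper edge must not exceed
#'   the Nyquist frequency.
#' @return a `dynamic_image` in state `"raw_integrals"`.
#' @export
band_integrals <- function(spectrum, bands = band_spec()) {
  if (!inherits(spectrum, "temporal_spectrum"))
    validation_error("'spectrum' must be a temporal_spectrum")
  nyq <- spectrum$frame_rate_hz / 2
  if (bands$fast[2] > nyq + 1e-12)
    config_error(sprintf("fast band upper edge %.4g Hz exceeds Nyquist %.4g Hz",
                         bands$fast[2], nyq))
  bins <- band_bins(bands, spectrum$n_frames, spectrum$frame_rate_hz)
  for (bn in names(bins))
    if (!length(bins[[bn]]))
      config_error(sprintf("band '%s' contains no spectral bins at %d frames / %.4g Hz",
                           bn, spectrum$n_frames, spectrum$frame_rate_hz))
  amp <- spectrum$amplitude
  dims <- dim(amp)[2:3]
  integral <- function(kk) {
    sl <- amp[kk + 1L, , , drop = FALSE]
    out <- colSums(sl, dims = 1)
    matrix(out, dims[1], dims[2])
  }
  new_dynamic_image(r = integral(bins$fast), g = integral(bins$medium),
                    b = integral(bins$slow), bands = bands,
                    n_frames_used = spectrum$n_frames, state = "raw_integrals",
                    axial_um_per_px = spectrum$axial_um_per_px,
                    lateral_um_per_px = spectrum$lateral_um_per_px)
}

#' Min-max normalize each channel to [0, 1]
#'
#' Affine rescale of each channel over the whole image so its minimum maps
#' to 0 and its maximum to 1. A constant channel (no dynamics to display)
#' maps to all zeros.
#'
#' @param image a `dynamic_image` in state `"raw_integrals"`.
#' @return the image in state `"normalized"`.
#' @export
normalize_channels <- function(image) {
  if (!inherits(image, "dynamic_image")) validation_error("'image' must be a dynamic_image")
  if (image$normalization_state != "raw_integrals")
    validation_error(sprintf("normalize_channels expects state 'raw_integrals', got '%s'",
                             image$normalization_state))
  norm1 <- function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) return(matrix(0, nrow(x), ncol(x)))
    (x - rng[1]) / (rng[2] - rng[1])
  }
  out <- image
  out$r <- norm1(image$r); out$g <- norm1(image$g); out$b <- norm1(image$b)
  out$normalization_state <- "normalized"
  out
}

#' Moving standard-deviation reference image
#'
#' For every voxel, computes the sample SD within each contiguous window of
#' `window` frames (`n_frames - window + 1` windows) and averages the
#' windowed SDs, yielding a single 2-D reference image used as the
#' histogram-matching target.
#'
#' @param series a [bscan_series()].
#' @param window window width in frames, `2 <= window <= n_frames`;
#'   default 25.
#' @return numeric matrix (depth x lateral).
#' @export
moving_std_reference <- function(series, window = 25L) {
  if (!inherits(series, "bscan_series")) validation_error("'series' must be a bscan_series")
  d <- dim(series$data)
  if (!is_scalar_number(window) || window < 2 || window > d[1])
    validation_error(sprintf("'window' must be in [2, %d]", d[1]))
  w <- as.integer(window)
  x <- series$data
  dim(x) <- c(d[1], d[2] * d[3])
  s1 <- apply(x, 2, cumsum)
  s2 <- apply(x * x, 2, cumsum)
  s1 <- rbind(0, s1); s2 <- rbind(0, s2)
  starts <- 0:(d[1] - w)
  acc <- 0
  for (i in starts) {
    sw <- s1[i + w + 1L, ] - s1[i + 1L, ]
    qw <- s2[i + w + 1L, ] - s2[i + 1L, ]
    v <- (qw - sw * sw / w) / (w - 1)
    acc <- acc + sqrt(pmax(v, 0))
  }
  matrix(acc / length(starts), d[2], d[3])
}

#' Match channel histograms to a reference image
#'
#' Remaps each channel independently by monotone CDF matching so that its
#' value distribution approximates the reference image's distribution.
#' Both the channel and the (min-max rescaled) reference are quantized to
#' 256 levels; each source level maps to the lowest reference level whose
#' cumulative frequency attains the source level's cumulative frequency.
#' Pixel rank order within a channel is preserved.
#'
#' @param image a `dynamic_image` in state `"normalized"`.
#' @param reference numeric matrix on the same spatial grid, e.g. from
#'   [moving_std_reference()].
#' @return the image in state `"histogram_matched"`, channels in [0, 1].
#' @export
histogram_match <- function(image, reference) {
  if (!inherits(image, "dynamic_image")) validation_error("'image' must be a dynamic_image")
  if (image$normalization_state != "normalized")
    validation_error(sprintf("histogram_match expects state 'normalized', got '%s'",
                             image$normalization_state))
  if (!is.matrix(reference) || !identical(dim(reference), dim(image$r)))
    validation_error("reference grid does not match image grid")
  rng <- range(reference)
  refn <- if (rng[1] == rng[2]) reference * 0 else (reference - rng[1]) / (rng[2] - rng[1])
  ref_lvl <- as.integer(floor(refn * 255 + 0.5))
  cdf_ref <- cumsum(tabulate(ref_lvl + 1L, nbins = 256L)) / length(ref_lvl)
  match1 <- function(ch) {
    lvl <- as.integer(floor(ch * 255 + 0.5))
    cdf_src <- cumsum(tabulate(lvl + 1L, nbins = 256L)) / length(lvl)
    # lowest reference level whose CDF attains the source CDF value
    lut <- findInterval(cdf_src, cdf_ref, left.open = TRUE) + 1L
    lut <- pmin(lut, 256L)
    matrix((lut[lvl + 1L] - 1L) / 255, nrow(ch), ncol(ch))
  }
  out <- image
  out$r <- match1(image$r); out$g <- match1(image$g); out$b <- match1(image$b)
  out$normalization_state <- "histogram_matched"
  out
}

#' Average repeated dynamic-contrast images
#'
#' Per-pixel, per-channel arithmetic mean of repeated acquisitions, the way
#' the five dynamic-contrast scans per time point are combined for display.
#'
#' @param images list of `dynamic_image` objects with identical grids,
#'   bands and normalization states.
#' @return a `dynamic_image` in state `"averaged"`.
#' @export
average_repeats <- function(images) {
  if (!length(images) || !all(vapply(images, inherits, TRUE, "dynamic_image")))
    validation_error("'images' must be a non-empty list of dynamic_image objects")
  first <- images[[1]]
  for (im in images[-1]) {
    if (!identical(dim(im$r), dim(first$r)))
      validation_error("images must share one spatial grid")
    if (!identical(unclass(im$bands), unclass(first$bands)))
      validation_error("images must share one band_spec")
    if (!identical(im$normalization_state, first$normalization_state))
      validation_error("images must share one normalization_state")
  }
  out <- first
  out$r <- Reduce(`+`, lapply(images, `[[`, "r")) / length(images)
  out$g <- Reduce(`+`, lapply(images, `[[`, "g")) / length(images)
  out$b <- Reduce(`+`, lapply(images, `[[`, "b")) / length(images)
  out$normalization_state <- "averaged"
  out
}

#' Temporal projection of a B-scan stack
#'
#' Maximum-intensity or standard-deviation projection across frames, the two
#' conventional single-image summaries of a B-scan time series.
#'
#' @param series a [bscan_series()].
#' @param method `"max"` or `"std"` (sample SD; requires >= 2 frames).
#' @return numeric matrix (depth x lateral).
#' @export
projection <- function(series, method = c("max", "std")) {
  if (!inherits(series, "bscan_series")) validation_error("'series' must be a bscan_series")
  method <- match.arg(method)
  d <- dim(series$data)
  x <- series$data
  dim(x) <- c(d[1], d[2] * d[3])
  out <- switch(method,
    max = apply(x, 2, max),
    std = {
      if (d[1] < 2) validation_error("std projection requires >= 2 frames")
      m <- colMeans(x)
      sqrt(colSums(sweep(x, 2, m)^2) / (d[1] - 1))
    })
  matrix(out, d[2], d[3])
}

#' Full dynamic-contrast processing chain
#'
#' Runs the standard chain on one acquisition: per-voxel temporal spectrum,
#' band integrals, per-channel min-max normalization and (optionally)
#' histogram matching of each channel to the moving-SD reference image of
#' the same acquisition.
#'
#' @param series a [bscan_series()].
#' @param bands a [band_spec()].
#' @param window moving-SD window width in frames (used when
#'   `histmatch = TRUE`).
#' @param normalize apply min-max normalization (default `TRUE`).
#' @param histmatch apply histogram matching to the moving-SD reference
#'   (default `TRUE`). Requires `normalize = TRUE`.
#' @return a `dynamic_image`.
#' @export
process_series <- function(series, bands = band_spec(), window = 25L,
                           normalize = TRUE, histmatch = TRUE) {
  img <- band_integrals(temporal_spectrum(series), bands)
  if (normalize) img <- normalize_channels(img)
  if (histmatch) {
    if (!normalize) validation_error("histmatch requires normalize = TRUE")
    win <- min(as.integer(window), n_frames(series))
    img <- histogram_match(img, moving_std_reference(series, win))
  }
  img
}
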