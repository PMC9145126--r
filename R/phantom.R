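#' Layer specification for the cornea phantom
#'
#' Describes one horizontal tissue layer of the synthetic cornea: its depth
#' extent, mean backscattered amplitude, how its temporal fluctuation power is
#' distributed over the three dmOCT frequency bands, and optional cell
#' texture.
#'
#' `band_power_fractions` gives the fraction of the layer's fluctuation power
#' budget placed in the slow, medium and fast band; the remainder (1 - sum) is
#' static and contributes no temporal variance. `fluctuation_strength` is the
#' temporal coefficient of variation the layer would attain were all of its
#' power dynamic, so the realized per-pixel temporal CV is
#' `fluctuation_strength * sqrt(sum(band_power_fractions))`.
#'
#' @param name layer label; `"basal"` is recognized by the toxicity course.
#' @param z_range half-open depth interval in pixels, 0-based `[z0, z1)`.
#' @param mean_amplitude mean amplitude, arbitrary units > 0.
#' @param band_power_fractions length-3 non-negative weights (slow, medium,
#'   fast), sum <= 1.
#' @param fluctuation_strength dimensionless >= 0; see Details.
#' @param cell_diameter_px 0 for a homogeneous layer, otherwise the edge
#'   length in px of square "cells" given independent random brightness.
#' @param swell_group `"none"`, `"epithelium"` or `"stroma"`; selects which
#'   swelling factor of a toxicity course applies to this layer.
#' @param rayleigh_speckle if `TRUE` the layer is fully dynamic speckle:
#'   amplitudes are drawn i.i.d. Rayleigh per frame (temporal CV
#'   `sqrt(4/pi - 1)` ~ 0.5227) and the band fractions are ignored.
#' @param single_tone_hz optional single frequency at which to concentrate all
#'   dynamic power (testing aid); must be below Nyquist at synthesis time.
#' @return an object of class `layer_spec`.
#' @export
layer_spec <- function(name, z_range, mean_amplitude,
                       band_power_fractions = c(0, 0, 0),
                       fluctuation_strength = 0,
                       cell_diameter_px = 0L,
                       swell_group = c("none", "epithelium", "stroma"),
                       rayleigh_speckle = FALSE,
                       single_tone_hz = NULL) {
  swell_group <- match.arg(swell_group)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    config_error("layer 'name' must be a non-empty string")
  if (length(z_range) != 2L || !is.numeric(z_range) ||
      z_range[1] < 0 || z_range[2] <= z_range[1] ||
      any(z_range != floor(z_range)))
    config_error(sprintf("layer '%s': z_range must be integer [z0, z1) with 0 <= z0 < z1", name))
  check_scalar(mean_amplitude, "mean_amplitude", 0, strict = TRUE)
  if (length(band_power_fractions) != 3L || any(band_power_fractions < 0) ||
      any(band_power_fractions > 1) || sum(band_power_fractions) > 1 + 1e-12)
    config_error(sprintf(
      "layer '%s': band_power_fractions must be 3 weights in [0,1] summing to <= 1", name))
  check_scalar(fluctuation_strength, "fluctuation_strength", 0)
  check_scalar(cell_diameter_px, "cell_diameter_px", 0)
  if (!is.null(single_tone_hz)) check_scalar(single_tone_hz, "single_tone_hz", 0, strict = TRUE)
  structure(
    list(name = name, z_range = as.integer(z_range),
         mean_amplitude = mean_amplitude,
         band_power_fractions = as.numeric(band_power_fractions),
         fluctuation_strength = fluctuation_strength,
         cell_diameter_px = as.integer(cell_diameter_px),
         swell_group = swell_group,
         rayleigh_speckle = isTRUE(rayleigh_speckle),
         single_tone_hz = single_tone_hz),
    class = "layer_spec")
}

#' Phantom acquisition configuration
#'
#' Collects the layer stack and the acquisition geometry of the synthetic
#' cornea. Defaults mirror the imaging protocol the pipeline targets:
#' 150 B-scans of 512 A-scans over 0.5 mm at an effective B-scan rate of
#' 111 Hz, five repeated acquisitions per time point.
#'
#' @param layers list of [layer_spec()] with pairwise disjoint z ranges.
#' @param n_frames number of B-scans per acquisition (>= 2).
#' @param n_ascans lateral A-scans per B-scan.
#' @param n_depth depth pixels per A-scan.
#' @param frame_rate_hz effective B-scan rate in Hz.
#' @param lateral_extent_mm lateral field of view in mm.
#' @param axial_um_per_px axial pixel pitch in micrometres.
#' @param noise_sigma SD of additive Gaussian detector noise (amplitude units).
#' @param n_repeats repeated acquisitions per imaging time point.
#' @param seed master seed; all per-repeat streams derive from it.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(layers, n_frames = 150L, n_ascans = 512L,
                           n_depth = 320L, frame_rate_hz = 111,
                           lateral_extent_mm = 0.5, axial_um_per_px = 1,
                           noise_sigma = 0.005, n_repeats = 5L, seed = 1L) {
  if (!length(layers) || !all(vapply(layers, inherits, TRUE, "layer_spec")))
    config_error("'layers' must be a non-empty list of layer_spec objects")
  check_scalar(n_frames, "n_frames", 2)
  check_scalar(n_ascans, "n_ascans", 1)
  check_scalar(n_depth, "n_depth", 1)
  check_scalar(frame_rate_hz, "frame_rate_hz", 0, strict = TRUE)
  check_scalar(lateral_extent_mm, "lateral_extent_mm", 0, strict = TRUE)
  check_scalar(axial_um_per_px, "axial_um_per_px", 0, strict = TRUE)
  check_scalar(noise_sigma, "noise_sigma", 0)
  check_scalar(n_repeats, "n_repeats", 1)
  check_scalar(seed, "seed", 0)
  layers <- layers[order(vapply(layers, function(l) l$z_range[1], 0))]
  z <- vapply(layers, function(l) l$z_range, numeric(2))
  if (any(z[1, -1] < z[2, -ncol(z), drop = FALSE][1, ]))
    config_error("layer z ranges must be pairwise disjoint")
  if (max(z[2, ]) > n_depth)
    config_error("layer z ranges must lie within [0, n_depth)")
  structure(
    list(layers = layers, n_frames = as.integer(n_frames),
         n_ascans = as.integer(n_ascans), n_depth = as.integer(n_depth),
         frame_rate_hz = frame_rate_hz, lateral_extent_mm = lateral_extent_mm,
         axial_um_per_px = axial_um_per_px, noise_sigma = noise_sigma,
         n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
    class = "phantom_config")
}

#' Summary of acquisition-derived constants
#'
#' Reports quantities derived from the configured geometry: the total
#' recording time `n_frames / frame_rate_hz`, the Nyquist frequency limiting
#' the analyzable fluctuation range, and the lateral pixel pitch.
#'
#' @param object a [phantom_config()].
#' @param ... unused.
#' @return a list with elements `n_frames`, `frame_rate_hz`,
#'   `recording_time_s`, `nyquist_hz`, `n_ascans`, `lateral_um_per_px`,
#'   `axial_um_per_px`, `n_depth`, `n_repeats`.
#' @export
summary.phantom_config <- function(object, ...) {
  out <- list(
    n_frames = object$n_frames,
    frame_rate_hz = object$frame_rate_hz,
    recording_time_s = object$n_frames / object$frame_rate_hz,
    nyquist_hz = object$frame_rate_hz / 2,
    n_ascans = object$n_ascans,
    lateral_um_per_px = object$lateral_extent_mm * 1000 / object$n_ascans,
    axial_um_per_px = object$axial_um_per_px,
    n_depth = object$n_depth,
    n_repeats = object$n_repeats)
  class(out) <- "summary.phantom_config"
  out
}

#' @export
print.summary.phantom_config <- function(x, ...) {
  cat(sprintf(paste0(
    "phantom acquisition: %d frames @ %.6g Hz -> recording time %.4g s,\n",
    "  fluctuations analyzable up to %.6g Hz (Nyquist);\n",
    "  %d A-scans (%.4g um/px lateral), %d depth px (%.4g um/px axial),\n",
    "  %d repeats per time point\n"),
    x$n_frames, x$frame_rate_hz, x$recording_time_s, x$nyquist_hz,
    x$n_ascans, x$lateral_um_per_px, x$n_depth, x$axial_um_per_px,
    x$n_repeats))
  invisible(x)
}

#' @export
print.phantom_config <- function(x, ...) {
  print(summary(x))
  for (l in x$layers)
    cat(sprintf("  layer %-14s z [%3d,%3d) mean %.3g  bands (%.3g, %.3g, %.3g)  fs %.3g%s\n",
                l$name, l$z_range[1], l$z_range[2], l$mean_amplitude,
                l$band_power_fractions[1], l$band_power_fractions[2],
                l$band_power_fractions[3], l$fluctuation_strength,
                if (l$rayleigh_speckle) "  [rayleigh]" else ""))
  invisible(x)
}

#' Default layered-cornea phantom
#'
#' Builds the baseline (pre-exposure) cornea used throughout the package.
#' Four layers, superficial to deep:
#'
#' * `surface_film` - a thin, strongly fluctuating interface band (tear-film /
#'   surface analogue). It anchors the maxima of the green and red channels so
#'   that per-channel min-max normalization does not erase relative band
#'   amplitudes of the tissue layers; its medium and fast weights are chosen
#'   so its two channel integrals are equal, keeping it hue-neutral between
#'   green and red. It lies outside every analysis ROI.
#' * `superficial` - bright, nearly static epithelium; renders blue.
#' * `basal` - dimmer, strongly fluctuating epithelium with power split
#'   between the medium and fast bands such that the two band integrals are
#'   equal; renders yellow. Realized temporal CV is 0.42, and textured into
#'   8 px cells.
#' * `stroma` - weakly fluctuating; renders blue/dark.
#'
#' Baseline thicknesses at the default 1 um axial pitch are 40 um total
#' epithelium (15 superficial + 25 basal) and 84 um stroma, matching healthy
#' adult mouse cornea.
#'
#' @param overrides named list of [phantom_config()] fields to replace
#'   (e.g. `list(n_ascans = 64, n_depth = 64)` for a small test geometry).
#'   Layer geometry is rescaled proportionally when `n_depth` shrinks below
#'   the default layer extent.
#' @return a [phantom_config()].
#' @examples
#' cfg <- make_default_cornea()
#' summary(cfg)$recording_time_s  # 150 / 111 ~ 1.35 s
#' @export
make_default_cornea <- function(overrides = list()) {
  defaults <- list(n_frames = 150L, n_ascans = 512L, n_depth = 320L,
                   frame_rate_hz = 111, lateral_extent_mm = 0.5,
                   axial_um_per_px = 1, noise_sigma = 0.005,
                   n_repeats = 5L, seed = 1L)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      config_error("overrides must be named")
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad))
      config_error(sprintf("unknown configuration field(s): %s",
                           paste(bad, collapse = ", ")))
    defaults[names(overrides)] <- overrides
  }
  layers <- list(
    layer_spec("surface_film", c(8, 11), mean_amplitude = 0.8,
               band_power_fractions = c(0, 0.45, 0.10),
               fluctuation_strength = 0.48),
    layer_spec("superficial", c(11, 26), mean_amplitude = 1.0,
               band_power_fractions = c(0, 0.004, 0.002),
               fluctuation_strength = 0.2, swell_group = "epithelium"),
    layer_spec("basal", c(26, 51), mean_amplitude = 0.55,
               band_power_fractions = c(0, 0.225, 0.05),
               fluctuation_strength = 0.8, cell_diameter_px = 8,
               swell_group = "epithelium"),
    layer_spec("stroma", c(51, 135), mean_amplitude = 0.7,
               band_power_fractions = c(0, 0.02, 0.01),
               fluctuation_strength = 0.15, swell_group = "stroma"))
  # shrink geometry proportionally for small test grids
  if (defaults$n_depth < 160) {
    s <- defaults$n_depth / 320
    layers <- lapply(layers, function(l) {
      l$z_range <- as.integer(c(floor(l$z_range[1] * s),
                                max(floor(l$z_range[1] * s) + 1,
                                    floor(l$z_range[2] * s))))
      if (l$cell_diameter_px > 0)
        l$cell_diameter_px <- max(2L, as.integer(round(l$cell_diameter_px * s)))
      l
    })
  }
  do.call(phantom_config, c(list(layers = layers), defaults))
}

#' Parametric toxic-exposure time course
#'
#' Phenomenological model of the changes a preservative exposure induces in
#' the phantom: saturating epithelial swelling that plateaus, delayed
#' linear stromal swelling, exponential decay of basal fluctuation strength
#' (motility loss), and a gradual transfer of basal fluctuation power from
#' the medium to the fast band (hue red shift).
#'
#' Epithelial thickness factor:
#' `1 + (epi_swell_max - 1) * (1 - exp(-min(t, plateau)/tau)) / (1 - exp(-plateau/tau))`,
#' exactly `epi_swell_max` for `t >= plateau_min`. Stromal factor is 1 before
#' `stroma_onset_min` and grows linearly at `stroma_swell_per_min` after it.
#'
#' @param epi_swell_max epithelial thickness factor at plateau (> 1).
#' @param epi_swell_tau_min epithelial swelling time constant, minutes.
#' @param plateau_min exposure time at which epithelial thickness plateaus.
#' @param stroma_onset_min exposure time at which stromal swelling begins.
#' @param stroma_swell_per_min relative stromal thickness growth per minute
#'   after onset.
#' @param motility_decay_per_min relative loss rate of basal fluctuation
#'   strength per minute (>= 0).
#' @param redshift_rate_per_min band-power fraction transferred per minute
#'   from the basal medium band to the fast band (>= 0).
#' @return an object of class `toxicity_course`.
#' @export
toxicity_course <- function(epi_swell_max = 2, epi_swell_tau_min = 120,
                            plateau_min = 150, stroma_onset_min = 150,
                            stroma_swell_per_min = 0.01,
                            motility_decay_per_min = 0.0015,
                            redshift_rate_per_min = 0.0004) {
  check_scalar(epi_swell_max, "epi_swell_max", 1, strict = TRUE)
  check_scalar(epi_swell_tau_min, "epi_swell_tau_min", 0, strict = TRUE)
  check_scalar(plateau_min, "plateau_min", 0, strict = TRUE)
  check_scalar(stroma_onset_min, "stroma_onset_min", 0)
  check_scalar(stroma_swell_per_min, "stroma_swell_per_min", 0)
  check_scalar(motility_decay_per_min, "motility_decay_per_min", 0)
  check_scalar(redshift_rate_per_min, "redshift_rate_per_min", 0)
  structure(
    list(epi_swell_max = epi_swell_max, epi_swell_tau_min = epi_swell_tau_min,
         plateau_min = plateau_min, stroma_onset_min = stroma_onset_min,
         stroma_swell_per_min = stroma_swell_per_min,
         motility_decay_per_min = motility_decay_per_min,
         redshift_rate_per_min = redshift_rate_per_min),
    class = "toxicity_course")
}

epi_swell_factor <- function(course, t) {
  tau <- course$epi_swell_tau_min
  plateau <- course$plateau_min
  1 + (course$epi_swell_max - 1) *
    (1 - exp(-pmin(t, plateau) / tau)) / (1 - exp(-plateau / tau))
}

stroma_swell_factor <- function(course, t) {
  ifelse(t < course$stroma_onset_min, 1,
         1 + course$stroma_swell_per_min * (t - course$stroma_onset_min))
}

#' Apply a toxicity course to a phantom configuration
#'
#' Returns a new configuration describing the phantom after `exposure_min`
#' minutes of exposure: epithelial and stromal layer extents are scaled by
#' the course's swelling factors (layers restacked downward from the topmost
#' layer, extents rounded to whole pixels), the basal layer's
#' `fluctuation_strength` decays as `exp(-motility_decay_per_min * t)`, and
#' basal band power is transferred from the medium to the fast band at
#' `redshift_rate_per_min` (clamped so fractions stay valid). The input is
#' not modified; exposure 0 returns it unchanged.
#'
#' @param config a [phantom_config()].
#' @param course a [toxicity_course()].
#' @param exposure_min exposure time in minutes (>= 0).
#' @return a new [phantom_config()].
#' @export
apply_toxicity <- function(config, course, exposure_min) {
  if (!inherits(config, "phantom_config")) config_error("'config' must be a phantom_config")
  if (!inherits(course, "toxicity_course")) config_error("'course' must be a toxicity_course")
  if (!is_scalar_number(exposure_min) || exposure_min < 0)
    validation_error("'exposure_min' must be a single number >= 0")
  if (exposure_min == 0) return(config)
  f_epi <- epi_swell_factor(course, exposure_min)
  f_str <- stroma_swell_factor(course, exposure_min)
  layers <- config$layers
  z_next <- layers[[1]]$z_range[1]
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    th <- l$z_range[2] - l$z_range[1]
    fac <- switch(l$swell_group, epithelium = f_epi, stroma = f_str, 1)
    th_new <- max(1L, as.integer(round(th * fac)))
    layers[[i]]$z_range <- c(z_next, z_next + th_new)
    z_next <- z_next + th_new
    if (identical(l$name, "basal")) {
      layers[[i]]$fluctuation_strength <-
        l$fluctuation_strength * exp(-course$motility_decay_per_min * exposure_min)
      shift <- min(l$band_power_fractions[2],
                   course$redshift_rate_per_min * exposure_min)
      layers[[i]]$band_power_fractions <-
        l$band_power_fractions + c(0, -shift, shift)
    }
  }
  if (z_next > config$n_depth)
    config_error(sprintf(
      "swollen layer stack (%d px) exceeds n_depth = %d; enlarge the grid",
      z_next, config$n_depth))
  out <- config
  out$layers <- layers
  out
}

# Frequencies (Hz) of non-DC spectral bins falling in the half-open interval.
band_interior_bins <- function(interval, n_frames_count, frame_rate) {
  k <- seq_len(floor(n_frames_count / 2))
  f <- k * frame_rate / n_frames_count
  k[f >= interval[1] & f < interval[2]]
}

# Synthesize the relative fluctuation (frames x npix) of one layer as sums of
# bin-centered sinusoids with per-pixel random phases. Each band's variance
# share is fs^2 * p_b, realized by n_b equal-amplitude tones.
synth_band_limited <- function(layer, n_fr, rate, npix,
                               band_intervals) {
  fs <- layer$fluctuation_strength
  p <- layer$band_power_fractions
  freqs <- numeric(0); amps <- numeric(0)
  if (!is.null(layer$single_tone_hz)) {
    if (layer$single_tone_hz > rate / 2)
      config_error(sprintf(
        "layer '%s': single_tone_hz %.3g exceeds Nyquist %.3g Hz",
        layer$name, layer$single_tone_hz, rate / 2))
    ptot <- sum(p)
    if (ptot > 0 && fs > 0) {
      freqs <- layer$single_tone_hz
      amps <- fs * sqrt(2 * ptot)
    }
  } else {
    for (b in 1:3) {
      if (p[b] <= 0 || fs <= 0) next
      bins <- band_interior_bins(band_intervals[[b]], n_fr, rate)
      if (!length(bins))
        config_error(sprintf(
          "layer '%s': band %d requests fluctuation power but contains no non-DC spectral bins at %d frames / %.3g Hz",
          layer$name, b, n_fr, rate))
      f_b <- bins * rate / n_fr
      if (any(f_b > rate / 2))
        config_error("band allocation above Nyquist")
      freqs <- c(freqs, f_b)
      amps <- c(amps, rep(fs * sqrt(2 * p[b] / length(bins)), length(bins)))
    }
  }
  if (!length(freqs)) return(matrix(0, n_fr, npix))
  t_s <- (seq_len(n_fr) - 1) / rate
  theta <- outer(t_s, 2 * pi * freqs)                    # n_fr x K
  basis <- cbind(sweep(cos(theta), 2, amps, "*"),
                 sweep(-sin(theta), 2, amps, "*"))       # n_fr x 2K
  phi <- matrix(stats::runif(length(freqs) * npix, 0, 2 * pi),
                nrow = length(freqs))
  basis %*% rbind(cos(phi), sin(phi))                    # n_fr x npix
}

# Per-pixel multiplicative texture for a layer: square cells of edge
# cell_diameter_px with independent brightness factors.
cell_texture <- function(layer, nrow_l, ncol_l) {
  d <- layer$cell_diameter_px
  if (d <= 0) return(rep(1, nrow_l * ncol_l))
  ri <- ((seq_len(nrow_l) - 1) %/% d)
  ci <- ((seq_len(ncol_l) - 1) %/% d)
  nr <- max(ri) + 1; nc <- max(ci) + 1
  fac <- matrix(stats::runif(nr * nc, 0.8, 1.2), nr, nc)
  as.vector(fac[cbind(rep(ri + 1, ncol_l), rep(ci + 1, each = nrow_l))])
}

#' Simulate one dynamic-speckle B-scan acquisition
#'
#' Generates a B-scan time series of the phantom after `exposure_min`
#' minutes of the given toxicity course, together with ground-truth ROI
#' masks consistent with the exposure-adjusted geometry. Within each layer
#' the per-pixel signal is
#' `mean_amplitude * texture * (1 + band-limited fluctuation)` plus additive
#' Gaussian noise (clamped at zero); Rayleigh layers instead draw i.i.d.
#' Rayleigh amplitudes each frame. Identical
#' `(seed, exposure_min, repeat_index)` give bit-identical output.
#'
#' @param config a [phantom_config()] (baseline).
#' @param exposure_min exposure time in minutes, >= 0.
#' @param course a [toxicity_course()]; `NULL` keeps the baseline config at
#'   any exposure.
#' @param repeat_index which of the `n_repeats` repeated acquisitions,
#'   in `[0, n_repeats)`.
#' @return a list with elements `series` ([bscan_series()]), `masks` (named
#'   list of [roi_mask()]: `total_epithelium`, `basal_epithelium`, `stroma`,
#'   as applicable) and `config_used` (the exposure-adjusted config).
#' @export
simulate_series <- function(config, exposure_min = 0, course = NULL,
                            repeat_index = 0L) {
  if (!inherits(config, "phantom_config")) config_error("'config' must be a phantom_config")
  if (!is_scalar_number(exposure_min) || exposure_min < 0)
    validation_error("'exposure_min' must be >= 0")
  if (!is_scalar_number(repeat_index) || repeat_index < 0 ||
      repeat_index >= config$n_repeats)
    validation_error(sprintf("'repeat_index' must be in [0, %d)", config$n_repeats))
  cfg <- if (is.null(course)) config else apply_toxicity(config, course, exposure_min)

  n_fr <- cfg$n_frames; n_z <- cfg$n_depth; n_x <- cfg$n_ascans
  rate <- cfg$frame_rate_hz
  bands <- list(c(0, 0.5), c(0.5, 5), c(5, 25))  # synthesis band intervals
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, repeat_index, exposure_min))

  stack <- array(0, dim = c(n_fr, n_z, n_x))
  for (l in cfg$layers) {
    rows <- (l$z_range[1] + 1):l$z_range[2]
    npix <- length(rows) * n_x
    if (l$rayleigh_speckle) {
      sigma <- l$mean_amplitude * sqrt(2 / pi)
      vals <- sigma * sqrt(-2 * log(stats::runif(n_fr * npix)))
      sig <- matrix(vals, n_fr, npix)
    } else {
      fl <- synth_band_limited(l, n_fr, rate, npix, bands)
      tex <- cell_texture(l, length(rows), n_x)
      sig <- sweep(1 + fl, 2, l$mean_amplitude * tex, "*")
    }
    stack[, rows, ] <- sig
  }
  if (cfg$noise_sigma > 0)
    stack <- stack + stats::rnorm(length(stack), 0, cfg$noise_sigma)
  stack <- pmax(stack, 0)

  masks <- phantom_masks(cfg)
  series <- bscan_series(stack, rate,
                         axial_um_per_px = cfg$axial_um_per_px,
                         lateral_um_per_px = cfg$lateral_extent_mm * 1000 / n_x)
  list(series = series, masks = masks, config_used = cfg)
}

#' Ground-truth ROI masks for a phantom configuration
#'
#' @param config a [phantom_config()] (typically exposure-adjusted).
#' @return named list of [roi_mask()] objects covering the full lateral
#'   width: `total_epithelium` (all epithelium-group layers),
#'   `basal_epithelium` (the layer named "basal") and `stroma`.
#' @export
phantom_masks <- function(config) {
  blank <- function() matrix(FALSE, config$n_depth, config$n_ascans)
  rows_of <- function(sel) {
    r <- integer(0)
    for (l in config$layers[sel]) r <- c(r, (l$z_range[1] + 1):l$z_range[2])
    r
  }
  grp <- vapply(config$layers, function(l) l$swell_group, "")
  nm <- vapply(config$layers, function(l) l$name, "")
  out <- list()
  if (any(grp == "epithelium")) {
    m <- blank(); m[rows_of(grp == "epithelium"), ] <- TRUE
    out$total_epithelium <- roi_mask(m, "total_epithelium")
  }
  if (any(nm == "basal")) {
    m <- blank(); m[rows_of(nm == "basal"), ] <- TRUE
    out$basal_epithelium <- roi_mask(m, "basal_epithelium")
  }
  if (any(grp == "stroma")) {
    m <- blank(); m[rows_of(grp == "stroma"), ] <- TRUE
    out$stroma <- roi_mask(m, "stroma")
  }
  out
}

# save/restore the global RNG state so simulation is side-effect free
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
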