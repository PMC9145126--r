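# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately use naive direct computation, not the package's
# vectorized code paths.

# Direct DFT magnitude by summation: |sum_t x_t exp(-2*pi*i*k*t/n)|,
# one-sided bins k = 0..floor(n/2).
dft_mag_oracle <- function(x) {
  n <- length(x)
  t_idx <- 0:(n - 1)
  vapply(0:floor(n / 2), function(k) {
    Mod(sum(x * exp(-2i * pi * k * t_idx / n)))
  }, numeric(1))
}

# Brute-force moving-SD reference: loop over windows and voxels.
moving_sd_oracle <- function(arr, w) {
  d <- dim(arr)
  out <- matrix(0, d[2], d[3])
  for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    x <- arr[, i, j]
    sds <- vapply(1:(d[1] - w + 1), function(s) sd(x[s:(s + w - 1)]), numeric(1))
    out[i, j] <- mean(sds)
  }
  out
}

# Direct CDF-matching oracle on 256 quantized levels (independent of the
# package's findInterval implementation).
hist_match_oracle <- function(v, ref) {
  rng <- range(ref)
  refn <- if (rng[1] == rng[2]) ref * 0 else (ref - rng[1]) / (rng[2] - rng[1])
  vl <- floor(v * 255 + 0.5)
  rl <- floor(refn * 255 + 0.5)
  cdf_src <- sapply(0:255, function(L) mean(vl <= L))
  cdf_ref <- sapply(0:255, function(L) mean(rl <= L))
  out <- numeric(length(v))
  for (p in seq_along(v)) {
    cs <- cdf_src[vl[p] + 1]
    out[p] <- (which(cdf_ref >= cs - 1e-12)[1] - 1) / 255
  }
  out
}

# Build a bscan_series directly from a fill function of (frame) or constants.
const_series <- function(value, n_fr = 10, n_z = 4, n_x = 5, rate = 100) {
  bscan_series(array(value, c(n_fr, n_z, n_x)), rate)
}

# A deterministic random stack of positive amplitudes.
random_series <- function(n_fr, n_z, n_x, rate = 50, seed = 42, offset = 2) {
  set.seed(seed)
  bscan_series(array(offset + runif(n_fr * n_z * n_x), c(n_fr, n_z, n_x)), rate)
}

# Single-layer phantom config helper.
one_layer_config <- function(layer, n_frames = 150, n_ascans = 32,
                             n_depth = 32, noise_sigma = 0, seed = 7,
                             frame_rate_hz = 111) {
  phantom_config(list(layer), n_frames = n_frames, n_ascans = n_ascans,
                 n_depth = n_depth, frame_rate_hz = frame_rate_hz,
                 noise_sigma = noise_sigma, seed = seed)
}

full_mask <- function(n_z, n_x, label = "roi") roi_mask(matrix(TRUE, n_z, n_x), label)

# Small default cornea used by hue/pipeline tests: full layer layout on a
# reduced lateral grid.
small_cornea <- function(n_ascans = 64, n_frames = 150, seed = 1) {
  make_default_cornea(list(n_ascans = n_ascans, n_depth = 320,
                           n_frames = n_frames, seed = seed))
}
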