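test_that("motility coefficient: constants, gaussian CV and scale invariance", {
  expect_equal(motility_coefficient(const_series(5), full_mask(4, 5)), 0)
  set.seed(21)
  arr <- array(pmax(10 + rnorm(100 * 40 * 40, 0, 2), 0), c(100, 40, 40))
  s <- bscan_series(arr, 100)
  m <- motility_coefficient(s, full_mask(40, 40))
  expect_equal(m, 0.2, tolerance = 0.02)  # CV of N(10, 2)
  # scale invariance
  s2 <- bscan_series(arr * 7.3, 100)
  expect_equal(motility_coefficient(s2, full_mask(40, 40)), m, tolerance = 1e-12)
})

test_that("motility coefficient error contracts", {
  s <- const_series(1)
  expect_error(motility_coefficient(s, roi_mask(matrix(FALSE, 4, 5))),
               class = "dmoct_validation_error")
  expect_error(motility_coefficient(s, full_mask(3, 3)),
               class = "dmoct_validation_error")  # grid mismatch
  arr <- array(1, c(10, 4, 5)); arr[, 1, 1] <- 0; arr[, 2, 2] <- 0
  expect_error(motility_coefficient(bscan_series(arr, 10), full_mask(4, 5)),
               "2 ROI pixel", class = "dmoct_validation_error")
})

test_that("motility of static-plus-noise converges to noise_sigma / mean", {
  lay <- layer_spec("flat", c(0, 60), 4)
  cfg <- one_layer_config(lay, n_frames = 80, n_ascans = 100, n_depth = 60,
                          noise_sigma = 0.3)
  sim <- simulate_series(cfg)
  m <- motility_coefficient(sim$series, full_mask(60, 100))
  expect_equal(m, 0.3 / 4, tolerance = 0.01)
})

test_that("hue histogram wraps pure colors to the expected degrees", {
  mk <- function(r, g, b) new_dynamic_image(
    matrix(r, 2, 2), matrix(g, 2, 2), matrix(b, 2, 2),
    band_spec(), 10L, "normalized")
  m <- full_mask(2, 2)
  peak1 <- function(img) find_hue_peaks(hue_histogram(img, m), 1)$hue_deg
  expect_equal(peak1(mk(1, 0, 0)), 360.5)  # red 0 -> wraps to 360
  expect_equal(peak1(mk(0, 0, 1)), 240.5)  # blue
  expect_equal(peak1(mk(1, 1, 0)), 420.5)  # yellow 60 -> 420
  # counts sum to pixels used; all-excluded ROI errors
  h <- hue_histogram(mk(1, 1, 0), m)
  expect_equal(sum(h$counts), h$n_pixels_used)
  expect_error(hue_histogram(mk(0.01, 0.01, 0.01), m),
               class = "dmoct_validation_error")
  expect_error(hue_histogram(mk(2, 0, 0), m), class = "dmoct_validation_error")
})

test_that("hue peaks match a brute-force scan on a bimodal histogram", {
  set.seed(5)
  n <- 6000
  h <- c(rnorm(n, 420, 8), rnorm(n / 2, 240, 8))  # yellow mode twice blue mode
  counts <- tabulate(floor((h - 120) / 1) + 1, nbins = 360)
  hist <- structure(list(bin_edges = seq(120, 480, 1), counts = counts,
                         n_pixels_used = sum(counts),
                         saturation_threshold = 0.1, value_threshold = 0.05),
                    class = "hue_histogram")
  pk <- find_hue_peaks(hist, 2)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$hue_deg[1], 420, tolerance = 3)
  expect_equal(pk$hue_deg[2], 240, tolerance = 3)
  expect_gt(pk$height[1], pk$height[2])
  # brute-force oracle: tallest smoothed bin sits where peak 1 is reported
  centers <- seq(120.5, 479.5, 1)
  ext <- c(counts[357:360], counts, counts[1:4])
  sm <- sapply(1:360, function(i) mean(ext[i:(i + 8)]))
  expect_equal(pk$hue_deg[1], centers[which.max(sm)], tolerance = 1e-9)
})

test_that("mass straddling the green boundary yields exactly one peak", {
  h <- c(rep(478, 40), rep(479, 60), rep(120.2, 60), rep(121, 40))
  counts <- tabulate(floor((h - 120)) + 1, nbins = 360)
  hist <- structure(list(bin_edges = seq(120, 480, 1), counts = counts,
                         n_pixels_used = sum(counts),
                         saturation_threshold = 0.1, value_threshold = 0.05),
                    class = "hue_histogram")
  pk <- find_hue_peaks(hist, 3)
  expect_equal(nrow(pk), 1)  # circular smoothing merges the straddle
  d <- min(abs(pk$hue_deg - 480), abs(pk$hue_deg - 120))
  expect_lt(d, 6)
})

test_that("peak suppression honours minimum separation and requested count", {
  counts <- rep(0, 360); counts[100] <- 50; counts[110] <- 45; counts[200] <- 30
  hist <- structure(list(bin_edges = seq(120, 480, 1), counts = counts,
                         n_pixels_used = sum(counts),
                         saturation_threshold = 0.1, value_threshold = 0.05),
                    class = "hue_histogram")
  pk <- find_hue_peaks(hist, 3, smooth_window = 1, min_separation_deg = 30)
  # peaks at bins 100 and 110 are 10 deg apart: the lower is suppressed
  expect_equal(nrow(pk), 2)
  expect_equal(pk$hue_deg, c(219.5, 319.5))
  expect_equal(nrow(find_hue_peaks(hist, 1, smooth_window = 1)), 1)
})

test_that("thickness: rectangle, staircase, single pixel, holes", {
  m <- matrix(FALSE, 100, 30); m[11:50, ] <- TRUE
  expect_equal(thickness_from_mask(roi_mask(m), 1), 40)
  expect_equal(thickness_from_mask(roi_mask(m), 2.5), 100)
  # staircase of column heights 30..50 -> mean 40
  st <- matrix(FALSE, 100, 21)
  for (j in 0:20) st[1:(30 + j), j + 1] <- TRUE
  expect_equal(thickness_from_mask(roi_mask(st), 1), 40)
  # single-pixel column
  sp <- matrix(FALSE, 10, 3); sp[4, 2] <- TRUE
  expect_equal(thickness_from_mask(roi_mask(sp), 1.5), 1.5)
  # holes do not reduce columnwise extent
  hole <- m; hole[30, ] <- FALSE
  expect_equal(thickness_from_mask(roi_mask(hole), 1), 40)
  expect_error(thickness_from_mask(roi_mask(matrix(FALSE, 4, 4)), 1),
               class = "dmoct_validation_error")
})

test_that("repeatability statistics use the standard definitions", {
  r <- repeatability_stats(c(9, 10, 11))  # sample SD exactly 1
  expect_equal(r$cv, 0.1)
  expect_equal(r$cor, 1.96 * sqrt(2))
  expect_equal(repeatability_stats(c(4, 4, 4)), list(cv = 0, cor = 0))
  set.seed(8)
  v <- rnorm(50, 20, 3)
  expect_equal(repeatability_stats(v)$cor, 2.7719 * sd(v), tolerance = 1e-4)
  expect_error(repeatability_stats(5), class = "dmoct_validation_error")
  expect_error(repeatability_stats(c(-1, 1)), class = "dmoct_validation_error")
})

test_that("medium-to-fast power transfer red-shifts the basal hue peak monotonically", {
  # sweep basal band powers from (0, .5, .5) toward (0, .1, .9)
  shifts <- seq(0, 0.4, by = 0.1)
  hues <- vapply(shifts, function(d) {
    layers <- list(
      layer_spec("surface_film", c(0, 3), 0.8,
                 band_power_fractions = c(0, 0.45, 0.10),
                 fluctuation_strength = 0.9),
      layer_spec("superficial", c(3, 10), 1.0,
                 band_power_fractions = c(0, 0.004, 0.002),
                 fluctuation_strength = 0.2, swell_group = "epithelium"),
      layer_spec("basal", c(10, 20), 0.15,
                 band_power_fractions = c(0, 0.5 - d, 0.5 + d),
                 fluctuation_strength = 0.8, cell_diameter_px = 4,
                 swell_group = "epithelium"))
    cfg <- phantom_config(layers, n_frames = 150, n_ascans = 48, n_depth = 24,
                          noise_sigma = 0, seed = 30)
    sim <- simulate_series(cfg)
    img <- process_series(sim$series, histmatch = FALSE)
    find_hue_peaks(hue_histogram(img, sim$masks$basal_epithelium), 1)$hue_deg
  }, numeric(1))
  expect_true(all(diff(hues) <= 0))        # toward red (lower wrapped degree)
  expect_true(all(hues >= 300 & hues <= 480))
})
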