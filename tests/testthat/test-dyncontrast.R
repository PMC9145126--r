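test_that("band_spec validates interval ordering", {
  expect_error(band_spec(c(0, 1), c(0.5, 5), c(5, 25)), class = "dmoct_config_error")
  expect_error(band_spec(c(0, 0.5), c(5, 5), c(5, 25)), class = "dmoct_config_error")
  b <- band_spec()
  expect_equal(b$slow, c(0, 0.5))
  expect_equal(b$medium, c(0.5, 5))
  expect_equal(b$fast, c(5, 25))
})

test_that("constant series has a DC-only spectrum", {
  s <- const_series(2.5, n_fr = 12)
  sp <- temporal_spectrum(s)
  expect_equal(sp$amplitude[1, , ], matrix(2.5 * 12, 4, 5))
  expect_equal(max(abs(sp$amplitude[-1, , ])), 0, tolerance = 1e-10)
  expect_error(temporal_spectrum(const_series(1, n_fr = 1)),
               class = "dmoct_validation_error")
})

test_that("bin-centered sinusoid has closed-form magnitude b*n/2 at its bin", {
  n <- 150; rate <- 111; k <- 14; b <- 0.8
  f <- k * rate / n  # ~10.36 Hz
  x <- 5 + b * cos(2 * pi * f * (0:(n - 1)) / rate + 0.3)
  s <- bscan_series(array(rep(x, 2), c(n, 1, 2)), rate)
  sp <- temporal_spectrum(s)
  expect_equal(sp$amplitude[k + 1, 1, 1], b * n / 2, tolerance = 1e-9)
  expect_equal(sp$amplitude[1, 1, 1], 5 * n, tolerance = 1e-9)
  others <- sp$amplitude[-c(1, k + 1), 1, 1]
  expect_lt(max(others), 1e-9)
  # direct-summation oracle agrees bin by bin
  expect_equal(sp$amplitude[, 1, 1], dft_mag_oracle(x), tolerance = 1e-9)
  # frequency axis tops out at Nyquist
  expect_equal(max(sp$freq_hz), 55.5)
})

test_that("band integrals assign DC to slow and split AC by bin center", {
  n <- 150; rate <- 111; k <- 14; b <- 0.8
  f <- k * rate / n
  x <- 5 + b * cos(2 * pi * f * (0:(n - 1)) / rate)
  s <- bscan_series(array(x, c(n, 1, 1)), rate)
  img <- band_integrals(temporal_spectrum(s))
  expect_identical(img$normalization_state, "raw_integrals")
  expect_equal(img$b[1, 1], 5 * n, tolerance = 1e-8)   # DC -> blue
  expect_equal(img$r[1, 1], b * n / 2, tolerance = 1e-8)  # 10.36 Hz -> red
  expect_lt(img$g[1, 1], 1e-8)
  # DC-only signal: green and red exactly 0
  img0 <- band_integrals(temporal_spectrum(const_series(2, n_fr = 150, rate = 111)))
  expect_equal(max(img0$g), 0, tolerance = 1e-10)
  expect_equal(max(img0$r), 0, tolerance = 1e-10)
})

test_that("band completeness: integrals conserve amplitude below fast.hi", {
  s <- random_series(50, 6, 7)
  sp <- temporal_spectrum(s)
  img <- band_integrals(sp)
  covered <- sp$freq_hz < band_spec()$fast[2]
  total <- apply(sp$amplitude[covered, , , drop = FALSE], c(2, 3), sum)
  expect_equal(img$r + img$g + img$b, total, tolerance = 1e-12)
})

test_that("empty bands are rejected by name", {
  s <- random_series(10, 2, 2, rate = 111)  # df = 11.1 Hz: medium band empty
  expect_error(band_integrals(temporal_spectrum(s)), "medium",
               class = "dmoct_config_error")
  # fast band above Nyquist
  s2 <- random_series(50, 2, 2, rate = 40)
  expect_error(band_integrals(temporal_spectrum(s2)),
               class = "dmoct_config_error")
})

test_that("normalization maps min-max to [0,1], constants to 0, and is affine-invariant", {
  s <- random_series(30, 8, 8)
  img <- band_integrals(temporal_spectrum(s))
  nrm <- normalize_channels(img)
  expect_identical(nrm$normalization_state, "normalized")
  for (ch in c("r", "g", "b")) {
    expect_equal(range(nrm[[ch]]), c(0, 1))
  }
  # affine midpoint: min 2, max 10 -> 6 maps to 0.5
  img$r[] <- 4
  img$r[1:3] <- c(2, 10, 6)
  nr <- normalize_channels(img)$r
  expect_equal(nr[3], 0.5)
  # constant channel -> zeros
  img$g <- matrix(3, nrow(img$b), ncol(img$b))
  expect_true(all(normalize_channels(img)$g == 0))
  # normalize(a*x + b) == normalize(x) for a > 0
  img2 <- img
  img2$b <- 3.7 * img$b + 11
  expect_equal(normalize_channels(img2)$b, normalize_channels(img)$b,
               tolerance = 1e-12)
  expect_error(normalize_channels(nrm), class = "dmoct_validation_error")
})

test_that("moving SD reference matches the brute-force oracle", {
  s <- random_series(20, 4, 5)
  expect_equal(moving_std_reference(s, 7), moving_sd_oracle(s$data, 7),
               tolerance = 1e-9)
  # window = n equals the global SD image and the std projection
  expect_equal(moving_std_reference(s, 20), projection(s, "std"),
               tolerance = 1e-12)
  # constant stack -> zero image
  expect_true(all(moving_std_reference(const_series(4), 5) == 0))
  expect_error(moving_std_reference(s, 1), class = "dmoct_validation_error")
  expect_error(moving_std_reference(s, 21), class = "dmoct_validation_error")
})

test_that("moving SD of i.i.d. gaussian noise approximates sigma", {
  set.seed(11)
  arr <- array(10 + rnorm(60 * 60 * 40, 0, 2), c(60, 60, 40))  # 2400 voxels
  s <- bscan_series(abs(arr), 100)
  ref <- moving_std_reference(s, 25)
  expect_equal(mean(ref), 2, tolerance = 0.05)
})

test_that("histogram matching follows the CDF-mapping oracle and preserves ranks", {
  set.seed(3)
  n_z <- 40; n_x <- 50
  img <- new_img <- band_integrals(temporal_spectrum(random_series(16, n_z, n_x)))
  img <- normalize_channels(img)
  ref <- matrix(rbeta(n_z * n_x, 0.5, 2), n_z, n_x)  # skewed reference
  hm <- histogram_match(img, ref)
  expect_identical(hm$normalization_state, "histogram_matched")
  for (ch in c("r", "g", "b")) {
    expect_equal(as.vector(hm[[ch]]),
                 hist_match_oracle(as.vector(img[[ch]]), as.vector(ref)),
                 tolerance = 1e-12)
    # monotone: no rank inversions beyond quantization ties
    o <- order(img[[ch]])
    expect_true(all(diff(hm[[ch]][o]) >= 0))
    expect_true(all(hm[[ch]] >= 0 & hm[[ch]] <= 1))
  }
  # self-matching is identity up to 1/256 quantization
  self <- histogram_match(img, img$r)
  expect_lt(max(abs(self$r - img$r)), 1 / 255 + 1e-12)
  expect_error(histogram_match(img, ref[1:10, ]), class = "dmoct_validation_error")
  expect_error(histogram_match(new_img, ref), class = "dmoct_validation_error")
})

test_that("a uniform channel matched to a bimodal reference adopts its distribution", {
  set.seed(4)
  n_z <- 100; n_x <- 120  # >= 1e4 pixels
  u <- matrix(runif(n_z * n_x), n_z, n_x)
  img <- new_dynamic_image(u, u, u, band_spec(), 16L, "normalized")
  ref <- matrix(c(rnorm(6000, 0.25, 0.1), rnorm(6000, 0.75, 0.1)), n_z, n_x)
  ref <- pmin(pmax(ref, 0), 1)
  hm <- histogram_match(img, ref)
  ks <- suppressWarnings(ks.test(as.vector(hm$g), as.vector(ref)))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("average_repeats is the elementwise mean and order-invariant", {
  imgs <- lapply(1:5, function(i)
    normalize_channels(band_integrals(temporal_spectrum(
      random_series(12, 6, 6, seed = i)))))
  avg <- average_repeats(imgs)
  expect_identical(avg$normalization_state, "averaged")
  brute <- Reduce(`+`, lapply(imgs, `[[`, "g")) / 5
  expect_equal(avg$g, brute, tolerance = 1e-12)
  expect_equal(average_repeats(rev(imgs))$r, avg$r, tolerance = 1e-12)
  # five identical images -> the same image
  same <- average_repeats(imgs[c(1, 1, 1, 1, 1)])
  expect_equal(same$b, imgs[[1]]$b, tolerance = 1e-12)
  # mixed states and grids rejected
  raw <- band_integrals(temporal_spectrum(random_series(12, 6, 6)))
  expect_error(average_repeats(list(imgs[[1]], raw)), class = "dmoct_validation_error")
  small <- normalize_channels(band_integrals(temporal_spectrum(random_series(12, 3, 6))))
  expect_error(average_repeats(list(imgs[[1]], small)), class = "dmoct_validation_error")
})

test_that("projections: max and std behave on constant and spiked stacks", {
  s <- const_series(3, n_fr = 8)
  expect_true(all(projection(s, "max") == 3))
  expect_true(all(projection(s, "std") == 0))
  arr <- array(1, c(8, 3, 3)); arr[5, 2, 2] <- 9
  sp <- projection(bscan_series(arr, 100), "max")
  expect_equal(sp[2, 2], 9)
  expect_equal(sp[1, 1], 1)
  expect_error(projection(s, "median"))
})

test_that("the processing chain is deterministic", {
  s <- random_series(40, 10, 12)
  a <- process_series(s)
  b <- process_series(s)
  expect_identical(a, b)
  expect_identical(a$normalization_state, "histogram_matched")
})
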