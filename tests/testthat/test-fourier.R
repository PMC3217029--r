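test_that("constant index map has zero power after DC removal", {
  im <- make_index_map(matrix(1.56, 32, 32))
  ps <- power_spectrum_2d(im)
  expect_true(all(ps$power == 0))
  expect_equal(ps$total_power, 0)
})

test_that("a vertical sinusoid concentrates power at +-1/period on the axis", {
  n <- 884  # 4 periods of 221 px
  y <- sin(2 * pi * (seq_len(n) - 1) / 221)
  im <- make_index_map(matrix(rep(y, n), n, n))
  ps <- power_spectrum_2d(im)
  idx <- which(ps$power >= max(ps$power) * (1 - 1e-9), arr.ind = TRUE)
  peaks <- cbind(ps$freq[idx[, 1]], ps$freq[idx[, 2]])
  expect_equal(nrow(idx), 2)  # symmetric pair
  expect_equal(sort(peaks[, 1]), c(-1 / 221, 1 / 221), tolerance = 1e-9)
  expect_equal(peaks[, 2], c(0, 0))
  # point symmetry of the spectrum for real input (the unpaired Nyquist
  # row/column of an even-sized transform is excluded)
  sub <- ps$power[-1, -1]
  expect_equal(sub, sub[rev(seq_len(n - 1)), rev(seq_len(n - 1))],
               tolerance = 1e-8)
  prof <- radial_average(ps)
  expect_equal(prof$freq[which.max(prof$power)], 4 / 884, tolerance = 1e-9)
  expect_equal(1 / 221, 0.004525, tolerance = 1e-4)
})

test_that("power normalization satisfies Parseval's identity", {
  for (seed in 1:3) {
    m <- withr::with_seed(seed, matrix(sample(c(1.0, 1.56), 64^2, TRUE), 64))
    ps <- power_spectrum_2d(make_index_map(m))
    expect_equal(ps$total_power, sum((m - mean(m))^2), tolerance = 1e-8)
  }
})

test_that("non-square or tiny inputs are rejected", {
  expect_error(power_spectrum_2d(make_index_map(matrix(1.56, 32, 16))),
               "square")
  expect_error(power_spectrum_2d(make_index_map(matrix(1.56, 8, 8))),
               "16 x 16")
})

test_that("radial profile is invariant to rotation and transposition", {
  m <- withr::with_seed(1, matrix(sample(c(1.0, 1.56), 64^2, TRUE), 64))
  prof <- function(x) radial_average(power_spectrum_2d(make_index_map(x)))
  base <- prof(m)
  expect_equal(prof(t(m))$power, base$power, tolerance = 1e-10)
  rot90 <- t(m[nrow(m):1, ])
  expect_equal(prof(rot90)$power, base$power, tolerance = 1e-10)
  rot180 <- m[nrow(m):1, ncol(m):1]
  expect_equal(prof(rot180)$power, base$power, tolerance = 1e-10)
})

test_that("radial profile percentages sum to 100 and bins validate", {
  m <- withr::with_seed(2, matrix(sample(c(1.0, 1.56), 64^2, TRUE), 64))
  ps <- power_spectrum_2d(make_index_map(m))
  prof <- radial_average(ps)
  expect_equal(sum(prof$power_pct), 100, tolerance = 1e-9)
  expect_true(all(diff(prof$freq) > 0))
  expect_error(radial_average(ps, bin_width = 0), "bin_width")
  expect_error(radial_average(ps, bin_width = 1), "Nyquist")
  # all-zero spectrum gives an all-zero profile
  flat <- radial_average(power_spectrum_2d(make_index_map(matrix(1.56, 32, 32))))
  expect_true(all(flat$power == 0))
})

test_that("frequency-to-wavelength mapping is the round-trip backscatter law", {
  expect_equal(frequency_to_wavelength(1 / 221, (1.56 * 110 + 111) / 221),
               565.2, tolerance = 1e-10)
  expect_equal(frequency_to_wavelength(0.004, 1.28), 640)
  f <- 0.005
  expect_equal(frequency_to_wavelength(2 * f, 1.3),
               frequency_to_wavelength(f, 1.3) / 2)
  expect_error(frequency_to_wavelength(0, 1.3), "> 0")
  expect_error(frequency_to_wavelength(-1, 1.3), "> 0")
})

test_that("predicted spectrum peaks exactly at the single populated annulus", {
  m <- withr::with_seed(3, matrix(sample(c(1.0, 1.56), 64^2, TRUE), 64))
  prof <- radial_average(power_spectrum_2d(make_index_map(m)))
  one <- prof
  one$power <- ifelse(seq_len(nrow(one)) == 10, 5, 0)
  one$power_sum <- one$power
  one$power_pct <- ifelse(seq_len(nrow(one)) == 10, 100, 0)
  spec <- predicted_reflectance(one, n_bar = 1.28)
  expect_equal(spec$lambda_max_unrestricted, 2 * 1.28 / one$freq[10],
               tolerance = 1e-10)
  expect_equal(spec$visible_freq_band, c(2 * 1.28 / 700, 2 * 1.28 / 350))
  expect_equal(spec$visible_freq_band, c(0.003657, 0.007314),
               tolerance = 1e-4)
})

test_that("full pipeline reproduces the ideal-multilayer closed form", {
  a <- analyze_image(generate_multilayer_image(bilayer(110, 111), periods = 5))
  expect_equal(a$lambda_max, 565.2, tolerance = 1e-6)
  expect_equal(a$n_bar, (1.56 * 110 + 111) / 221, tolerance = 1e-12)
  tol <- mapped_bin_tolerance(565.2, a$n_bar, attr(a$profile, "bin_width"))
  expect_lt(abs(a$lambda_max - 565.2), tol)
})

test_that("pipeline peak wavelength increases strictly with multilayer period", {
  periods <- c(80, 95, 110, 125, 140)
  peaks <- vapply(periods, function(d) {
    pipeline_lambda_max(d, d + 1, which = "unrestricted")
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("hann window moves peak widths, not peak locations", {
  img <- generate_multilayer_image(bilayer(110, 111), periods = 5)
  raw <- analyze_image(img, window = "none")
  win <- analyze_image(img, window = "hann")
  tol <- mapped_bin_tolerance(565.2, raw$n_bar, attr(raw$profile, "bin_width"))
  expect_lt(abs(win$lambda_max - raw$lambda_max), tol)
})

test_that("tidy and glance expose the predicted spectrum tables", {
  a <- analyze_image(generate_multilayer_image(bilayer(110, 111), periods = 5))
  td <- tidy(a)
  expect_true(all(c("wavelength", "reflectance", "visible") %in% names(td)))
  expect_true(all(diff(td$wavelength) > 0))
  g <- glance(a)
  expect_equal(nrow(g), 1)
  expect_equal(g$lambda_max, a$lambda_max)
})
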