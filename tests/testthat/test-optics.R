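test_that("perforation factor is the open-area pixel fraction", {
  solid <- make_phase_map(matrix(TRUE, 50, 50))
  expect_equal(perforation_factor(solid)$p, 0)
  open <- make_phase_map(matrix(FALSE, 50, 50))
  expect_equal(perforation_factor(open)$p, 1)
  mixed <- make_phase_map(matrix(rep(c(TRUE, FALSE), c(30, 70)), 10, 10))
  st <- perforation_factor(mixed)
  expect_equal(st$p, 0.7)
  expect_equal(st$p, st$open_pixels / st$total_pixels)
  expect_equal(perforation_factor(mixed, invert = TRUE)$p, 0.3)
})

test_that("synthetic disc-grid laminae reproduce the distal and proximal factors", {
  distal <- generate_perforated_lamina(500, 500, 50, 16)
  p_distal <- perforation_factor(distal)$p
  expect_equal(p_distal, distal$ground_truth$open_fraction)
  expect_lt(abs(p_distal - 0.32), 0.01)
  proximal <- generate_perforated_lamina(504, 504, 63, 8)
  expect_lt(abs(perforation_factor(proximal)$p - 0.05), 0.005)
})

test_that("sub-wavelength gratings admit no nonzero propagating order", {
  expect_true(all(propagating_orders(140, seq(350, 700, 1)) == 0))
  # lambda > d at normal incidence never diffracts
  expect_equal(propagating_orders(400, 401), 0L)
  expect_equal(propagating_orders(100, 5000), 0L)
})

test_that("order counting enumerates the grating equation", {
  expect_equal(propagating_orders(1800, 565), 6L)  # m = +-1, +-2, +-3
  expect_equal(propagating_orders(1000, 500), 4L)  # m = +-1, +-2
  # oblique incidence breaks the +- symmetry but keeps the bound
  expect_equal(propagating_orders(1000, 700, incidence_deg = 30),
               sum(abs(sin(pi / 6) + setdiff(-10:10, 0) * 0.7) <= 1))
  # non-decreasing in period at fixed wavelength
  counts <- propagating_orders_vec <- vapply(
    seq(100, 4000, 100), function(d) propagating_orders(d, 565), integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(propagating_orders(0, 500))
  expect_error(propagating_orders(500, 500, incidence_deg = 95))
})

test_that("ideal multilayer peak follows 2(n1 d1 + n2 d2)", {
  expect_equal(ideal_multilayer_peak(110, 1.56, 111, 1.0), 565.2)
  expect_equal(ideal_multilayer_peak(86, 1.56, 86, 1.0), 440.32)
  # quarter-wave layers peak exactly at the design wavelength
  l0 <- 612
  expect_equal(ideal_multilayer_peak(l0 / (4 * 1.56), 1.56,
                                     l0 / (4 * 1.0), 1.0), l0)
})

test_that("transfer matrix reflects nothing without an interface and stays bounded", {
  empty <- stack_spec(numeric(0), numeric(0), n_ambient = 1, n_substrate = 1)
  tm <- transfer_matrix_reflectance(empty, seq(350, 700, 50))
  expect_true(all(tm$reflectance == 0))
  st <- withr::with_seed(4, stack_spec(runif(8, 1, 1.6), runif(8, 40, 160)))
  r <- transfer_matrix_reflectance(st, seq(300, 900, 10))$reflectance
  expect_true(all(r >= 0 & r <= 1))
})

test_that("a quarter-wave chitin/air stack peaks at its design wavelength below 100%", {
  qs <- quarter_wave_stack(565, bilayers = 5)
  tm <- transfer_matrix_reflectance(qs, seq(400, 750, 1))
  expect_equal(tm$wavelength[which.max(tm$reflectance)], 565, tolerance = 2)
  expect_lt(max(tm$reflectance), 1)
  expect_gt(max(tm$reflectance), 0.5)
})

test_that("peak reflectance sharpens monotonically with bilayer count", {
  peaks <- vapply(2:10, function(k) {
    tm <- transfer_matrix_reflectance(quarter_wave_stack(565, bilayers = k),
                                      seq(450, 700, 1))
    max(tm$reflectance)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
  expect_lt(max(peaks), 1)
  # and the peak location converges to the ideal closed form
  tm10 <- transfer_matrix_reflectance(quarter_wave_stack(565, bilayers = 10),
                                      seq(450, 700, 0.5))
  expect_lt(abs(tm10$wavelength[which.max(tm10$reflectance)] - 565), 2)
})
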