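test_that("single-period multilayer rasterizes exactly as specified", {
  img <- generate_multilayer_image(bilayer(110, 111), periods = 1,
                                   width_px = 64,
                                   intensity_high = 200, intensity_low = 60)
  expect_equal(dim(img$pixels), c(221, 64))
  expect_true(all(img$pixels[1:110, ] == 200))
  expect_true(all(img$pixels[111:221, ] == 60))
  expect_equal(img$ground_truth$period_nm, 221)
  expect_equal(sort(unique(as.vector(img$pixels))), c(60, 200))
})

test_that("ground-truth ideal peak follows 2*sum(n_j d_j) and ignores pixel size", {
  img <- generate_multilayer_image(bilayer(110, 111), periods = 5)
  expect_equal(img$ground_truth$ideal_peak_nm, 2 * (1.56 * 110 + 1.0 * 111))
  fine <- generate_multilayer_image(bilayer(110, 111), periods = 5,
                                    pixel_size = 0.5, width_px = 32)
  expect_equal(fine$ground_truth$ideal_peak_nm, img$ground_truth$ideal_peak_nm)
  expect_equal(nrow(fine$pixels), 2 * nrow(img$pixels))
})

test_that("cumulative rounding keeps total stack height within one pixel", {
  img <- generate_multilayer_image(bilayer(93.4, 61.7), periods = 7,
                                   pixel_size = 2.3, width_px = 32)
  expect_lte(abs(nrow(img$pixels) - 7 * (93.4 + 61.7) / 2.3), 1)
})

test_that("noisy generation is deterministic given the seed and clipped to range", {
  a <- generate_multilayer_image(bilayer(100, 100), periods = 3,
                                 width_px = 50, noise_sd = 30, seed = 7)
  b <- generate_multilayer_image(bilayer(100, 100), periods = 3,
                                 width_px = 50, noise_sd = 30, seed = 7)
  expect_identical(a$pixels, b$pixels)
  c2 <- generate_multilayer_image(bilayer(100, 100), periods = 3,
                                  width_px = 50, noise_sd = 30, seed = 8)
  expect_false(identical(a$pixels, c2$pixels))
  expect_true(all(a$pixels >= 0 & a$pixels <= 255))
})

test_that("invalid multilayer specs are rejected", {
  expect_error(generate_multilayer_image(bilayer(110, 111), periods = 0),
               "positive integer")
  expect_error(generate_multilayer_image(bilayer(110, 111), periods = 100,
                                         max_px = 1000),
               "raster bound")
  expect_error(generate_multilayer_image(bilayer(110, 111), periods = 1,
                                         intensity_high = 80,
                                         intensity_low = 80))
})

test_that("curvature displaces band midlines but keeps two phases", {
  flat <- generate_multilayer_image(bilayer(110, 111), periods = 3,
                                    width_px = 400)
  curved <- generate_multilayer_image(bilayer(110, 111), periods = 3,
                                      width_px = 400,
                                      curvature_radius = 2000)
  expect_false(identical(flat$pixels, curved$pixels))
  expect_equal(sort(unique(as.vector(curved$pixels))),
               sort(unique(as.vector(flat$pixels))))
  # the central column is undisplaced
  mid <- ncol(curved$pixels) %/% 2
  expect_equal(curved$pixels[, mid], flat$pixels[, mid])
})

test_that("perforated lamina open fraction matches the disc-grid geometry", {
  expect_equal(
    generate_perforated_lamina(200, 200, 50, 0)$ground_truth$open_fraction, 0)
  lam <- generate_perforated_lamina(500, 500, 50, 16)
  expect_equal(lam$ground_truth$open_fraction, pi * 16^2 / 50^2,
               tolerance = 0.02)
  expect_equal(lam$ground_truth$open_pixels +
                 sum(lam$pixels == 255), lam$ground_truth$total_pixels)
})

test_that("rasterized open fraction converges to pi r^2 / pitch^2 on refinement", {
  coarse <- generate_perforated_lamina(500, 500, 50, 16)
  fine <- generate_perforated_lamina(1000, 1000, 100, 32)
  expect_lt(abs(fine$ground_truth$open_fraction - pi * 32^2 / 100^2), 0.005)
  expect_lt(abs(fine$ground_truth$open_fraction -
                  coarse$ground_truth$open_fraction), 0.005)
})

test_that("lamina jitter is deterministic and bounded", {
  a <- generate_perforated_lamina(300, 300, 60, 10, jitter_sd_px = 2, seed = 3)
  b <- generate_perforated_lamina(300, 300, 60, 10, jitter_sd_px = 2, seed = 3)
  expect_identical(a$pixels, b$pixels)
  expect_error(
    generate_perforated_lamina(300, 300, 60, 25, jitter_sd_px = 20, seed = 1),
    "overlap")
  expect_error(generate_perforated_lamina(300, 300, 60, 30), "pitch")
  expect_error(generate_perforated_lamina(100, 100, 120, 10), "dimensions")
})

test_that("images round-trip through PNG/TIFF with a ground-truth sidecar", {
  img <- generate_multilayer_image(bilayer(110, 111), periods = 2,
                                   width_px = 64)
  for (ext in c(".png", ".tif")) {
    path <- withr::local_tempfile(fileext = ext)
    write_synthetic_image(img, path)
    back <- load_image(path, pixel_size = 1)
    expect_equal(back$pixels, img$pixels, tolerance = 1 / 255)
    sidecar <- jsonlite::read_json(paste0(path, ".json"),
                                   simplifyVector = TRUE)
    expect_equal(sidecar$pixel_size_nm, 1)
    expect_equal(sidecar$ground_truth$ideal_peak_nm, 565.2)
  }
})
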