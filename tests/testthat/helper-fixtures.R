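# fixture builders shared across test files

# index map constructed directly from a numeric matrix (bypasses segmentation)
make_index_map <- function(n_matrix, pixel_size = 1,
                           n_high = 1.56, n_low = 1.0) {
  fill <- mean(n_matrix == n_high)
  structure(
    list(n = n_matrix, n_high = n_high, n_low = n_low, fill = fill,
         n_bar = fill * n_high + (1 - fill) * n_low,
         pixel_size = pixel_size),
    class = "index_map"
  )
}

# phase map from a logical matrix
make_phase_map <- function(mask, pixel_size = 1) {
  structure(list(mask = mask, pixel_size = pixel_size), class = "phase_map")
}

# raster image from a gray matrix (0-255)
make_raster <- function(pixels, pixel_size = 1) {
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "raster_image")
}

# full pipeline lambda_max for a two-phase stack (d_high, d_low nm at 1 nm/px)
pipeline_lambda_max <- function(d_high, d_low, periods = 5,
                                which = c("visible", "unrestricted")) {
  which <- match.arg(which)
  a <- analyze_image(generate_multilayer_image(bilayer(d_high, d_low),
                                               periods = periods))
  if (which == "visible") a$lambda_max else a$lambda_max_unrestricted
}

# wavelength tolerance of one radial frequency bin at the mapped peak
mapped_bin_tolerance <- function(lambda_peak, n_bar, bin_width) {
  f <- 2 * n_bar / lambda_peak
  2 * n_bar / (f - bin_width / 2) - 2 * n_bar / (f + bin_width / 2)
}

# two-column spectrum file on disk
write_spectrum_file <- function(wavelength, intensity, header = NULL,
                                sep = ",") {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  lines <- paste(wavelength, intensity, sep = sep)
  if (!is.null(header)) lines <- c(header, lines)
  writeLines(lines, path)
  path
}
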