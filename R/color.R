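#' Convert a wavelength to an RGB color
#'
#' Three conversions of a monochromatic wavelength to display RGB:
#'
#' * `"bruton"`: Dan Bruton's piecewise-linear approximation of the visible
#'   spectrum on 380--780 nm, with intensity falloff near the band edges and
#'   a display gamma of 0.8.
#' * `"bruton_linear"`: the same piecewise hue model with gamma 1 (no
#'   companding) — a deliberately simple variant so that three independent
#'   conversions can be averaged.
#' * `"cie"`: CIE 1931 2-degree color-matching functions (piecewise-Gaussian
#'   analytic fits of Wyman, Sloan & Shirley 2013) evaluated at the single
#'   wavelength, giving tristimulus XYZ, converted to sRGB with out-of-gamut
#'   components clipped to zero, normalized to full brightness, and
#'   sRGB-encoded.
#'
#' Wavelengths outside 380--780 nm map to black (0, 0, 0) in every method.
#'
#' @param lambda Wavelength(s) in nm (> 0); vectorized.
#' @param method One of `"bruton"`, `"cie"`, `"bruton_linear"`.
#' @return A tibble with columns `wavelength`, `r`, `g`, `b` (integers
#'   0--255), `method`.
#' @examples
#' wavelength_to_rgb(565, "bruton")  # (210, 255, 0): yellow-green
#' @export
wavelength_to_rgb <- function(lambda, method = c("bruton", "cie", "bruton_linear")) {
  method <- match.arg(method)
  if (any(lambda <= 0)) stop("wavelength must be > 0", call. = FALSE)
  rgb01 <- switch(method,
    bruton = bruton_rgb(lambda, gamma = 0.8),
    bruton_linear = bruton_rgb(lambda, gamma = 1),
    cie = cie_rgb(lambda)
  )
  tibble::tibble(
    wavelength = lambda,
    r = round_half_up(255 * rgb01[, 1]),
    g = round_half_up(255 * rgb01[, 2]),
    b = round_half_up(255 * rgb01[, 3]),
    method = method
  )
}

round_half_up <- function(x) as.integer(floor(x + 0.5))

# Bruton's piecewise-linear visible spectrum, rows = wavelengths, cols = RGB in [0,1]
bruton_rgb <- function(lambda, gamma = 0.8) {
  r <- g <- b <- numeric(length(lambda))
  w <- lambda
  i <- w >= 380 & w < 440
  r[i] <- (440 - w[i]) / (440 - 380); b[i] <- 1
  i <- w >= 440 & w < 490
  g[i] <- (w[i] - 440) / (490 - 440); b[i] <- 1
  i <- w >= 490 & w < 510
  g[i] <- 1; b[i] <- (510 - w[i]) / (510 - 490)
  i <- w >= 510 & w < 580
  r[i] <- (w[i] - 510) / (580 - 510); g[i] <- 1
  i <- w >= 580 & w < 645
  r[i] <- 1; g[i] <- (645 - w[i]) / (645 - 580)
  i <- w >= 645 & w <= 780
  r[i] <- 1
  # intensity falloff toward the band edges
  s <- numeric(length(w))
  i <- w >= 380 & w < 420
  s[i] <- 0.3 + 0.7 * (w[i] - 380) / (420 - 380)
  i <- w >= 420 & w <= 700
  s[i] <- 1
  i <- w > 700 & w <= 780
  s[i] <- 0.3 + 0.7 * (780 - w[i]) / (780 - 700)
  cbind((s * r)^gamma, (s * g)^gamma, (s * b)^gamma)
}

# piecewise Gaussian with separate left/right widths
pw_gauss <- function(x, mu, s1, s2) {
  s <- ifelse(x < mu, s1, s2)
  exp(-((x - mu)^2) / (2 * s^2))
}

# CIE 1931 2-deg color-matching functions, analytic multi-lobe Gaussian fits
cie_cmf <- function(lambda) {
  xbar <- 1.056 * pw_gauss(lambda, 599.8, 37.9, 31.0) +
          0.362 * pw_gauss(lambda, 442.0, 16.0, 26.7) -
          0.065 * pw_gauss(lambda, 501.1, 20.4, 26.2)
  ybar <- 0.821 * pw_gauss(lambda, 568.8, 46.9, 40.5) +
          0.286 * pw_gauss(lambda, 530.9, 16.3, 31.1)
  zbar <- 1.217 * pw_gauss(lambda, 437.0, 11.8, 36.0) +
          0.681 * pw_gauss(lambda, 459.0, 26.0, 13.8)
  cbind(xbar, ybar, zbar)
}

cie_rgb <- function(lambda) {
  xyz <- cie_cmf(lambda)
  m <- matrix(c(3.2406, -1.5372, -0.4986,
                -0.9689, 1.8758, 0.0415,
                0.0557, -0.2040, 1.0570),
              nrow = 3, byrow = TRUE)
  lin <- xyz %*% t(m)
  lin[lin < 0] <- 0  # gamut clipping, not normalization
  mx <- apply(lin, 1, max)
  lin <- lin / ifelse(mx > 0, mx, 1)  # monochromatic: scale to full brightness
  out <- ifelse(lin <= 0.0031308, 12.92 * lin,
                1.055 * lin^(1 / 2.4) - 0.055)
  out[lambda < 380 | lambda > 780, ] <- 0
  out
}

#' Consensus RGB over several conversion methods
#'
#' Converts a peak wavelength with each requested method and averages the
#' RGB components (arithmetic mean, rounded half-up). Averaging several
#' imperfect wavelength-to-color conversions is more robust than trusting
#' any single one.
#'
#' @param lambda Wavelength(s) in nm; vectorized.
#' @param methods Character vector of methods accepted by
#'   [wavelength_to_rgb()]; must be non-empty.
#' @return A tibble with columns `wavelength`, `r`, `g`, `b`, `method`
#'   (`"consensus"`), and `methods` (collapsed label).
#' @export
consensus_rgb <- function(lambda, methods = c("bruton", "cie", "bruton_linear")) {
  if (length(methods) < 1) stop("need at least one method", call. = FALSE)
  per <- purrr::map(methods, function(m) wavelength_to_rgb(lambda, m))
  r <- rowMeans(do.call(cbind, purrr::map(per, "r")))
  g <- rowMeans(do.call(cbind, purrr::map(per, "g")))
  b <- rowMeans(do.call(cbind, purrr::map(per, "b")))
  tibble::tibble(
    wavelength = lambda,
    r = round_half_up(r), g = round_half_up(g), b = round_half_up(b),
    method = "consensus",
    methods = paste(methods, collapse = "+")
  )
}

#' Zone color map from peak wavelengths
#'
#' Builds the tabular reconstruction: one row per wing zone with its peak
#' wavelength and consensus RGB color.
#'
#' @param zone Character vector of unique zone names, in display order.
#' @param lambda_max Peak wavelength per zone in nm (> 0).
#' @param methods Conversion methods passed to [consensus_rgb()].
#' @return A `zone_color_map` tibble: `zone`, `lambda_max`, `r`, `g`, `b`,
#'   `hex`.
#' @export
zone_color_map <- function(zone, lambda_max,
                           methods = c("bruton", "cie", "bruton_linear")) {
  stopifnot(length(zone) == length(lambda_max), !anyDuplicated(zone),
            all(lambda_max > 0))
  cons <- consensus_rgb(lambda_max, methods)
  out <- tibble::tibble(
    zone = zone, lambda_max = lambda_max,
    r = cons$r, g = cons$g, b = cons$b,
    hex = grDevices::rgb(cons$r, cons$g, cons$b, maxColorValue = 255)
  )
  structure(out, class = c("zone_color_map", class(out)))
}

#' Render a zone color reconstruction as a swatch panel
#'
#' Writes one rectangular swatch per zone, in map order, as a PNG (composed
#' directly as a raster, so it works headless) and/or returns a labeled
#' ggplot via [autoplot.zone_color_map()].
#'
#' @param map A `zone_color_map` (or tibble with `zone`, `r`, `g`, `b`).
#' @param out_path Optional PNG path to write.
#' @param swatch_px Height and width of each swatch in pixels.
#' @return The raster array (height x width x 3, values 0--1), invisibly.
#' @export
render_reconstruction <- function(map, out_path = NULL,
                                  swatch_px = c(80, 120)) {
  if (nrow(map) == 0) stop("empty zone color map", call. = FALSE)
  h <- swatch_px[1]; w <- swatch_px[2]
  arr <- array(0, dim = c(h, w * nrow(map), 3))
  for (k in seq_len(nrow(map))) {
    cols <- ((k - 1) * w + 1):(k * w)
    arr[, cols, 1] <- map$r[k] / 255
    arr[, cols, 2] <- map$g[k] / 255
    arr[, cols, 3] <- map$b[k] / 255
  }
  if (!is.null(out_path)) png::writePNG(arr, out_path)
  invisible(arr)
}
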