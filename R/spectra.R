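#' Read a measured reflectance spectrum
#'
#' Parses a two-column delimited text file (wavelength in nm, intensity),
#' comma-, tab-, or whitespace-separated, with an optional header line that
#' is skipped automatically when non-numeric.
#'
#' @param path Path to the file.
#' @param medium Optional label for the immersion medium the spectrum was
#'   recorded in (`"air"`, `"glycerine"`, `"ethanol"`, ...).
#' @return A `reflectance_spectrum` tibble with columns `wavelength` and
#'   `intensity`; attributes `normalized` (FALSE) and `medium`.
#' @export
read_spectrum <- function(path, medium = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- data.table::fread(path, header = "auto", data.table = FALSE)
  if (ncol(d) != 2) {
    stop("expected two columns (wavelength, intensity), found ", ncol(d),
         call. = FALSE)
  }
  if (!all(vapply(d, is.numeric, logical(1)))) {
    stop("non-numeric spectrum data in ", path, call. = FALSE)
  }
  new_reflectance_spectrum(d[[1]], d[[2]], normalized = FALSE, medium = medium)
}

new_reflectance_spectrum <- function(wavelength, intensity,
                                     normalized = FALSE,
                                     medium = NA_character_) {
  if (length(wavelength) != length(intensity)) {
    stop("wavelength and intensity must have equal length", call. = FALSE)
  }
  if (length(wavelength) < 3) {
    stop("a spectrum needs at least 3 points", call. = FALSE)
  }
  if (any(diff(wavelength) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  out <- tibble::tibble(wavelength = wavelength, intensity = intensity)
  structure(out, class = c("reflectance_spectrum", class(out)),
            normalized = normalized, medium = medium)
}

#' Build a reflectance spectrum from vectors
#'
#' @param wavelength Strictly increasing wavelengths in nm (>= 3 points).
#' @param intensity Intensities (counts or normalized reflectance).
#' @inheritParams read_spectrum
#' @return A `reflectance_spectrum` tibble.
#' @export
reflectance_spectrum <- function(wavelength, intensity,
                                 medium = NA_character_) {
  new_reflectance_spectrum(wavelength, intensity, normalized = FALSE,
                           medium = medium)
}

#' Normalize a spectrum against a white standard
#'
#' Divides a sample spectrum pointwise by the spectrum of the light source
#' recorded from a white diffuse standard, removing the source and detector
#' response. The standard is linearly interpolated onto the sample's grid
#' over the overlapping wavelength range; no extrapolation is performed.
#' Wavelengths where the standard reads zero are masked (`NA`) with a
#' warning rather than producing infinities.
#'
#' @param sample,standard `reflectance_spectrum` objects (or tibbles with
#'   `wavelength` and `intensity` columns).
#' @return A normalized `reflectance_spectrum` restricted to the overlap,
#'   with the `normalized` attribute set.
#' @export
normalize_to_white_standard <- function(sample, standard) {
  sw <- sample$wavelength; si <- sample$intensity
  tw <- standard$wavelength; ti <- standard$intensity
  lo <- max(min(sw), min(tw)); hi <- min(max(sw), max(tw))
  if (lo >= hi) stop("sample and standard wavelength ranges do not overlap",
                     call. = FALSE)
  keep <- sw >= lo & sw <= hi
  if (sum(keep) < 3) stop("fewer than 3 points in the overlap", call. = FALSE)
  std_on_sample <- stats::approx(tw, ti, xout = sw[keep])$y
  ratio <- si[keep] / std_on_sample
  zero <- std_on_sample == 0
  if (any(zero)) {
    warning(sum(zero), " wavelength(s) masked where the white standard is zero")
    ratio[zero] <- NA_real_
  }
  new_reflectance_spectrum(sw[keep], ratio, normalized = TRUE,
                           medium = attr(sample, "medium"))
}

#' Peak wavelength of a reflectance spectrum
#'
#' Smooths the spectrum with a centered moving average and returns the
#' wavelength of its maximum, refined by a parabolic fit through the peak
#' point and its neighbors. Invariant to positive affine rescaling of the
#' intensities.
#'
#' @param spec A `reflectance_spectrum` (or tibble with `wavelength`,
#'   `intensity`).
#' @param smooth_window Odd moving-average window in points (default 5;
#'   1 disables smoothing). The spectrum must have at least this many points.
#' @return Peak wavelength in nm.
#' @export
find_peak <- function(spec, smooth_window = 5) {
  w <- spec$wavelength
  y <- spec$intensity
  if (smooth_window %% 2 != 1 || smooth_window < 1) {
    stop("smooth_window must be odd and >= 1", call. = FALSE)
  }
  if (length(y) < smooth_window) {
    stop("spectrum shorter than the smoothing window", call. = FALSE)
  }
  ok <- !is.na(y)
  w <- w[ok]; y <- y[ok]
  if (length(y) < 3) stop("too few points after masking", call. = FALSE)
  if (diff(range(y)) == 0) {
    stop("no unique peak: spectrum is flat", call. = FALSE)
  }
  if (smooth_window > 1) {
    k <- rep(1 / smooth_window, smooth_window)
    ys <- stats::filter(y, k, sides = 2)
    half <- (smooth_window - 1) / 2
    core <- (half + 1):(length(y) - half)
    y2 <- as.numeric(ys[core]); w2 <- w[core]
  } else {
    y2 <- y; w2 <- w
  }
  if (diff(range(y2)) == 0) {
    stop("no unique peak: spectrum is flat after smoothing", call. = FALSE)
  }
  i <- which.max(y2)
  if (i == 1 || i == length(y2)) return(w2[i])
  y1 <- y2[i - 1]; ym <- y2[i]; y3 <- y2[i + 1]
  den <- y1 - 2 * ym + y3
  delta <- if (den == 0) 0 else 0.5 * (y1 - y3) / den
  delta <- max(min(delta, 0.5), -0.5)
  # local grid spacing; spectrometer grids are near-uniform
  step <- (w2[i + 1] - w2[i - 1]) / 2
  w2[i] + delta * step
}
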