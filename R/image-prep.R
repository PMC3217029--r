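#' Load a grayscale micrograph
#'
#' Reads an 8- or 16-bit grayscale PNG or TIFF and attaches the caller's
#' pixel scale. TEM calibration lives in figure scale bars, not in the file,
#' so `pixel_size` must always be supplied explicitly.
#'
#' @param path Path to a PNG or TIFF file.
#' @param pixel_size Image scale in nm per pixel (> 0); required.
#' @param as_gray Set `TRUE` to average the channels of a color input;
#'   without it a color image is an error, to force an explicit decision
#'   about contrast polarity.
#' @return A `raster_image`: list with `pixels` (matrix, 0--255 scale) and
#'   `pixel_size`.
#' @export
load_image <- function(path, pixel_size, as_gray = FALSE) {
  if (missing(pixel_size) || is.null(pixel_size)) {
    stop("`pixel_size` (nm per pixel) must be supplied explicitly: TEM ",
         "rasters do not carry their own scale", call. = FALSE)
  }
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1)
  if (pixel_size <= 0) stop("`pixel_size` must be > 0", call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  if (length(dim(arr)) == 3) {
    if (dim(arr)[3] == 2) {
      arr <- arr[, , 1]  # gray + alpha: drop alpha
    } else if (as_gray) {
      arr <- (arr[, , 1] + arr[, , 2] + arr[, , 3]) / 3
    } else {
      stop("color image: pass as_gray = TRUE to convert by channel mean",
           call. = FALSE)
    }
  }
  if (nrow(arr) < 2 || ncol(arr) < 2) {
    stop("image must be at least 2 x 2 pixels", call. = FALSE)
  }
  structure(list(pixels = arr * 255, pixel_size = pixel_size),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat("<raster_image> ", nrow(x$pixels), " x ", ncol(x$pixels),
      " px @ ", x$pixel_size, " nm/px\n", sep = "")
  invisible(x)
}

#' Segment a micrograph into two phases
#'
#' Thresholds a grayscale image into a binary phase map: 1 for the
#' high-index (chitin) phase, 0 for the low-index (air/resin) phase. By
#' default the brighter phase maps to 1; TEM contrast polarity varies with
#' staining, so `invert = TRUE` flips the assignment.
#'
#' @param img A `raster_image` or `synthetic_image`.
#' @param method `"otsu"` (default; parameter-free between-class variance
#'   threshold) or `"fixed"`.
#' @param threshold Gray level (0--255) for `method = "fixed"`.
#' @param invert Map the darker phase to 1 instead.
#' @return A `phase_map`: list with `mask` (logical matrix, TRUE = high
#'   phase) and `pixel_size`.
#' @export
binarize_phases <- function(img, method = c("otsu", "fixed"),
                            threshold = NULL, invert = FALSE) {
  stopifnot(inherits(img, "raster_image"))
  method <- match.arg(method)
  px <- img$pixels
  rng <- range(px)
  if (rng[1] == rng[2]) {
    stop("degenerate: single phase (constant image cannot be segmented)",
         call. = FALSE)
  }
  thr <- if (method == "otsu") {
    EBImage::otsu(px / 255, range = c(0, 1), levels = 256) * 255
  } else {
    if (is.null(threshold)) {
      stop("method = \"fixed\" requires `threshold`", call. = FALSE)
    }
    threshold
  }
  mask <- px > thr
  if (invert) mask <- !mask
  if (all(mask) || !any(mask)) {
    stop("degenerate: single phase after thresholding", call. = FALSE)
  }
  structure(list(mask = mask, pixel_size = img$pixel_size),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat("<phase_map> ", nrow(x$mask), " x ", ncol(x$mask), " px @ ",
      x$pixel_size, " nm/px, fill ", signif(mean(x$mask), 4), "\n", sep = "")
  invisible(x)
}

#' Build a refractive-index map from a phase map
#'
#' Assigns refractive indices to the two phases and computes the
#' volume-weighted mean index \eqn{\bar n = f\,n_{high} + (1-f)\,n_{low}},
#' where \eqn{f} is the high-phase area fraction. \eqn{\bar n} is the
#' effective index the coherent-scattering wavelength mapping uses. Defaults
#' are chitin (1.56) against air (1.0).
#'
#' @param phase A `phase_map`.
#' @param n_high,n_low Refractive indices of the two phases;
#'   `n_high > n_low > 0`.
#' @return An `index_map`: list with `n` (numeric matrix), `n_high`, `n_low`,
#'   `fill` (high-phase fraction), `n_bar`, `pixel_size`.
#' @export
build_index_map <- function(phase, n_high = 1.56, n_low = 1.0) {
  stopifnot(inherits(phase, "phase_map"))
  if (!(n_high > n_low && n_low > 0)) {
    stop("need n_high > n_low > 0", call. = FALSE)
  }
  fill <- mean(phase$mask)
  n <- matrix(n_low, nrow = nrow(phase$mask), ncol = ncol(phase$mask))
  n[phase$mask] <- n_high
  structure(
    list(n = n, n_high = n_high, n_low = n_low, fill = fill,
         n_bar = fill * n_high + (1 - fill) * n_low,
         pixel_size = phase$pixel_size),
    class = "index_map"
  )
}

#' @export
print.index_map <- function(x, ...) {
  cat("<index_map> ", nrow(x$n), " x ", ncol(x$n), " px @ ", x$pixel_size,
      " nm/px\n  n_high ", x$n_high, ", n_low ", x$n_low, ", fill ",
      signif(x$fill, 4), ", n_bar ", signif(x$n_bar, 5), "\n", sep = "")
  invisible(x)
}

#' Crop a square analysis region
#'
#' Fourier analysis operates on square crops; this extracts a
#' `size_px` x `size_px` submatrix from any of the raster-backed objects,
#' preserving the pixel scale (and mask/index semantics).
#'
#' @param x A `raster_image`, `phase_map`, or `index_map`.
#' @param size_px Side of the square crop; must fit in both dimensions.
#' @param origin `"centered"` (default) or a length-2 integer vector
#'   `c(row, col)` giving the top-left corner (1-based).
#' @return An object of the same class, cropped.
#' @export
select_square_region <- function(x, size_px, origin = "centered") {
  field <- if (inherits(x, "phase_map")) "mask"
           else if (inherits(x, "index_map")) "n"
           else if (inherits(x, "raster_image")) "pixels"
           else stop("unsupported object", call. = FALSE)
  m <- x[[field]]
  if (size_px > nrow(m) || size_px > ncol(m)) {
    stop("crop size ", size_px, " exceeds image dimensions ",
         nrow(m), " x ", ncol(m), call. = FALSE)
  }
  if (identical(origin, "centered")) {
    r0 <- floor((nrow(m) - size_px) / 2) + 1L
    c0 <- floor((ncol(m) - size_px) / 2) + 1L
  } else {
    stopifnot(length(origin) == 2, all(origin >= 1))
    r0 <- origin[1]; c0 <- origin[2]
    if (r0 + size_px - 1 > nrow(m) || c0 + size_px - 1 > ncol(m)) {
      stop("crop extends beyond image", call. = FALSE)
    }
  }
  out <- x
  out[[field]] <- m[r0:(r0 + size_px - 1L), c0:(c0 + size_px - 1L)]
  if (inherits(x, "index_map")) {
    out$fill <- mean(out$n == x$n_high)
    out$n_bar <- out$fill * x$n_high + (1 - out$fill) * x$n_low
  }
  if (inherits(x, "synthetic_image") && !is.null(x$ground_truth$mask)) {
    out$ground_truth$mask <-
      x$ground_truth$mask[r0:(r0 + size_px - 1L), c0:(c0 + size_px - 1L)]
  }
  out
}
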