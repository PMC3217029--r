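#' Layer table for a two-phase periodic multilayer
#'
#' Convenience constructor for the `layers` argument of
#' [generate_multilayer_image()]: one high-index (chitin) lamina followed by
#' one low-index (air) gap per period.
#'
#' @param d_high Thickness of the high-index lamina in nm.
#' @param d_low Thickness of the low-index gap in nm.
#' @return A tibble with columns `thickness_nm` and `phase` (`"high"`/`"low"`).
#' @examples
#' bilayer(110, 111)
#' @export
bilayer <- function(d_high, d_low) {
  stopifnot(d_high > 0, d_low > 0)
  tibble::tibble(thickness_nm = c(d_high, d_low), phase = c("high", "low"))
}

#' Generate a synthetic multilayer cross-section image
#'
#' Emulates a TEM longitudinal section through a chitin/air multilayer
#' reflector: horizontal bands of alternating intensity whose thicknesses are
#' given in nm and rasterized at `pixel_size` nm per pixel. The true geometry
#' (period, fill fraction, ideal reflectance peak) is recorded as ground truth
#' so downstream Fourier analysis can be validated against closed-form optics.
#'
#' Layer boundaries are placed by cumulative rounding: the running sum of
#' thicknesses is converted to pixels and rounded, so the total stack height
#' never drifts by more than one pixel regardless of the number of periods.
#' Optional concave curvature displaces band midlines downwards by the sagitta
#' of a circular arc of radius `curvature_radius`; Gaussian noise is added
#' after the geometry and clipped (not wrapped) to 0--255.
#'
#' @param layers Data frame with columns `thickness_nm` (> 0) and `phase`
#'   (`"high"` or `"low"`) describing one period of the stack, top to bottom.
#'   See [bilayer()].
#' @param periods Number of repeats of `layers` (positive integer).
#' @param pixel_size Image scale in nm per pixel (> 0).
#' @param width_px Image width in pixels. `NA` (default) makes the image
#'   square (width equal to the rasterized stack height), which is the shape
#'   the Fourier pipeline analyzes without cropping.
#' @param intensity_high,intensity_low Gray levels (0--255) for the two
#'   phases; must differ. TEM contrast polarity varies between instruments,
#'   so either may be the brighter.
#' @param noise_sd Standard deviation of additive Gaussian noise in gray
#'   levels (>= 0).
#' @param curvature_radius Radius in nm of the concave bending arc applied to
#'   the band midlines; `Inf` (default) keeps the laminae flat.
#' @param seed Integer seed for the noise generator (default 0). The same
#'   spec and seed always give a bit-identical image.
#' @param n_high,n_low Refractive indices attached to the two phases when
#'   recording the ground-truth ideal peak wavelength
#'   \eqn{\lambda = 2 \sum_j n_j d_j} (defaults 1.56 chitin, 1.0 air).
#' @param max_px Practical raster bound: error if the stack exceeds this many
#'   pixels in height.
#' @return A `synthetic_image`: list with `pixels` (matrix, gray 0--255),
#'   `pixel_size`, and `ground_truth` (list with `period_nm`, `fill_fraction`,
#'   `ideal_peak_nm`, `n_high`, `n_low`, and the noiseless phase `mask`).
#' @examples
#' img <- generate_multilayer_image(bilayer(110, 111), periods = 5)
#' img$ground_truth$ideal_peak_nm  # 2 * (1.56*110 + 1.0*111) = 565.2
#' @export
generate_multilayer_image <- function(layers,
                                      periods = 5,
                                      pixel_size = 1,
                                      width_px = NA,
                                      intensity_high = 200,
                                      intensity_low = 60,
                                      noise_sd = 0,
                                      curvature_radius = Inf,
                                      seed = 0,
                                      n_high = 1.56,
                                      n_low = 1.0,
                                      max_px = 8192) {
  layers <- tibble::as_tibble(layers)
  stopifnot(
    all(c("thickness_nm", "phase") %in% names(layers)),
    nrow(layers) >= 1,
    all(layers$thickness_nm > 0),
    all(layers$phase %in% c("high", "low")),
    pixel_size > 0, noise_sd >= 0,
    intensity_high != intensity_low,
    curvature_radius > 0
  )
  if (!is.numeric(periods) || periods < 1 || periods != round(periods)) {
    stop("`periods` must be a positive integer", call. = FALSE)
  }

  thick_all <- rep(layers$thickness_nm, periods)
  phase_all <- rep(layers$phase, periods)
  bounds_px <- round(cumsum(thick_all) / pixel_size)
  height_px <- bounds_px[length(bounds_px)]
  if (height_px > max_px) {
    stop("stack height ", height_px, " px exceeds raster bound ", max_px,
         " px", call. = FALSE)
  }
  if (is.na(width_px)) width_px <- height_px
  stopifnot(width_px >= 1)

  # phase label per row, from the cumulative-rounded boundaries
  row_phase <- character(height_px)
  start <- 0L
  for (j in seq_along(bounds_px)) {
    if (bounds_px[j] > start) row_phase[(start + 1L):bounds_px[j]] <- phase_all[j]
    start <- bounds_px[j]
  }
  col_phase <- matrix(row_phase, nrow = height_px, ncol = width_px)

  if (is.finite(curvature_radius)) {
    r_px <- curvature_radius / pixel_size
    x <- seq_len(width_px) - (width_px + 1) / 2
    if (max(abs(x)) >= r_px) {
      stop("curvature radius too small for image width", call. = FALSE)
    }
    sag <- round(r_px - sqrt(r_px^2 - x^2))  # concave: edges displaced down
    for (cc in seq_len(width_px)) {
      s <- sag[cc]
      if (s > 0) {
        src <- pmax(seq_len(height_px) - s, 1L)
        col_phase[, cc] <- row_phase[src]
      }
    }
  }

  mask <- col_phase == "high"
  pixels <- matrix(ifelse(mask, intensity_high, intensity_low),
                   nrow = height_px, ncol = width_px)
  if (noise_sd > 0) {
    noise <- withr::with_seed(seed,
      matrix(stats::rnorm(length(pixels), 0, noise_sd), nrow = height_px))
    pixels <- pmin(pmax(pixels + noise, 0), 255)
  }

  period_nm <- sum(layers$thickness_nm)
  d_high <- sum(layers$thickness_nm[layers$phase == "high"])
  gt <- list(
    period_nm = period_nm,
    fill_fraction = d_high / period_nm,
    ideal_peak_nm = 2 * sum(layers$thickness_nm *
                              ifelse(layers$phase == "high", n_high, n_low)),
    n_high = n_high, n_low = n_low,
    mask = mask
  )
  new_synthetic_image(pixels, pixel_size, gt)
}

#' Generate a synthetic perforated lamina image
#'
#' Emulates a surface view of a scale's internal lamina: a solid sheet bearing
#' circular perforations centered on a square grid. The rasterized open-area
#' fraction (the lamina perforation factor) is recorded as ground truth.
#'
#' @param width_px,height_px Raster dimensions in pixels.
#' @param pitch_px Grid spacing of perforation centers in pixels; must not
#'   exceed either image dimension.
#' @param hole_radius_px Perforation radius in pixels (>= 0); must be less
#'   than `pitch_px / 2` so unjittered holes cannot touch.
#' @param jitter_sd_px Standard deviation of Gaussian jitter applied to hole
#'   centers (default 0). Jittered centers are checked against the pitch
#'   bound; displacements that would let neighboring holes overlap are an
#'   error.
#' @param pixel_size nm per pixel recorded on the output (default 1).
#' @param seed Integer seed for the jitter (default 0).
#' @return A `synthetic_image` whose pixels are binary (255 solid, 0 open)
#'   and whose `ground_truth$open_fraction` is the exact open-pixel fraction.
#' @examples
#' lam <- generate_perforated_lamina(500, 500, pitch_px = 50, hole_radius_px = 16)
#' lam$ground_truth$open_fraction  # ~ pi * 16^2 / 50^2 = 0.32
#' @export
generate_perforated_lamina <- function(width_px, height_px,
                                       pitch_px, hole_radius_px,
                                       jitter_sd_px = 0,
                                       pixel_size = 1,
                                       seed = 0) {
  stopifnot(width_px >= 1, height_px >= 1, pitch_px >= 1,
            hole_radius_px >= 0, jitter_sd_px >= 0, pixel_size > 0)
  if (hole_radius_px >= pitch_px / 2) {
    stop("hole_radius_px must be < pitch_px / 2", call. = FALSE)
  }
  if (pitch_px > min(width_px, height_px)) {
    stop("pitch_px exceeds image dimensions", call. = FALSE)
  }

  nx <- floor(width_px / pitch_px)
  ny <- floor(height_px / pitch_px)
  cx <- (seq_len(nx) - 0.5) * pitch_px + 0.5
  cy <- (seq_len(ny) - 0.5) * pitch_px + 0.5
  centers <- expand.grid(x = cx, y = cy)
  if (jitter_sd_px > 0) {
    jit <- withr::with_seed(seed,
      matrix(stats::rnorm(2 * nrow(centers), 0, jitter_sd_px), ncol = 2))
    if (any(abs(jit) > pitch_px / 2 - hole_radius_px)) {
      stop("jitter displaces holes beyond the pitch bound (holes would ",
           "overlap); reduce jitter_sd_px", call. = FALSE)
    }
    centers$x <- centers$x + jit[, 1]
    centers$y <- centers$y + jit[, 2]
  }

  open <- matrix(FALSE, nrow = height_px, ncol = width_px)
  if (hole_radius_px > 0) {
    xs <- seq_len(width_px)
    ys <- seq_len(height_px)
    r2 <- hole_radius_px^2
    for (k in seq_len(nrow(centers))) {
      dx2 <- (xs - centers$x[k])^2
      dy2 <- (ys - centers$y[k])^2
      sel_x <- which(dx2 <= r2)
      sel_y <- which(dy2 <= r2)
      if (length(sel_x) && length(sel_y)) {
        open[sel_y, sel_x] <- open[sel_y, sel_x] |
          outer(dy2[sel_y], dx2[sel_x], "+") <= r2
      }
    }
  }

  pixels <- matrix(255, nrow = height_px, ncol = width_px)
  pixels[open] <- 0
  gt <- list(
    open_fraction = sum(open) / length(open),
    open_pixels = sum(open),
    total_pixels = length(open),
    pitch_px = pitch_px,
    hole_radius_px = hole_radius_px
  )
  new_synthetic_image(pixels, pixel_size, gt)
}

new_synthetic_image <- function(pixels, pixel_size, ground_truth) {
  structure(
    list(pixels = pixels, pixel_size = pixel_size, ground_truth = ground_truth),
    class = c("synthetic_image", "raster_image")
  )
}

#' @export
print.synthetic_image <- function(x, ...) {
  cat("<synthetic_image> ", nrow(x$pixels), " x ", ncol(x$pixels),
      " px @ ", x$pixel_size, " nm/px\n", sep = "")
  gt <- x$ground_truth
  if (!is.null(gt$period_nm)) {
    cat("  multilayer: period ", gt$period_nm, " nm, fill ",
        signif(gt$fill_fraction, 4), ", ideal peak ",
        signif(gt$ideal_peak_nm, 5), " nm\n", sep = "")
  }
  if (!is.null(gt$open_fraction)) {
    cat("  lamina: open fraction ", signif(gt$open_fraction, 4), "\n", sep = "")
  }
  invisible(x)
}

#' Write a synthetic image and its ground truth to disk
#'
#' Writes an 8-bit grayscale PNG or TIFF plus a JSON sidecar
#' (`<path>.json`) recording the pixel size and the generator's ground truth,
#' so fixtures are self-describing.
#'
#' @param img A `synthetic_image` or `raster_image`.
#' @param path Output path; extension selects the format (`.png` or
#'   `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_synthetic_image <- function(img, path) {
  stopifnot(inherits(img, "raster_image"))
  m <- img$pixels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(m, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, path, bits.per.sample = 8L)
  } else {
    stop("unsupported extension: ", ext, call. = FALSE)
  }
  gt <- img$ground_truth
  gt$mask <- NULL  # pixel mask stays in memory, not in the sidecar
  sidecar <- list(pixel_size_nm = img$pixel_size, ground_truth = gt)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
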