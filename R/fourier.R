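#' 2-D Fourier power spectrum of a refractive-index map
#'
#' Computes the centered squared-magnitude 2-D discrete Fourier transform of
#' the index matrix. The mean index (DC component) is removed before the
#' transform, so the spectrum measures spatial *variation* in refractive
#' index — the quantity that scatters light coherently. Power is normalized
#' as \eqn{|F|^2 / N^2}, under which the total power equals the sum of
#' squared mean-removed index values (Parseval).
#'
#' @param index_map An `index_map` (square, at least 16 x 16 pixels). A
#'   `phase_map` is also accepted and analyzed as a 0/1 matrix.
#' @param window `"none"` (default) or `"hann"`. Apodization changes peak
#'   widths, not locations; the default is the raw transform.
#' @return A `power_spectrum`: list with `power` (matrix, zero-frequency
#'   centered), `freq` (vector of per-axis frequencies in cycles/nm, centered
#'   order), `freq_step` (1 / (N * pixel_size)), `total_power`, `dc_removed`
#'   flag, `pixel_size`, and `n_bar` when available from the input.
#' @export
power_spectrum_2d <- function(index_map, window = c("none", "hann")) {
  window <- match.arg(window)
  if (inherits(index_map, "phase_map")) {
    m <- index_map$mask * 1
    n_bar <- NA_real_
  } else if (inherits(index_map, "index_map")) {
    m <- index_map$n
    n_bar <- index_map$n_bar
  } else {
    stop("expected an index_map or phase_map", call. = FALSE)
  }
  if (nrow(m) != ncol(m)) {
    stop("index map must be square; crop with select_square_region() first",
         call. = FALSE)
  }
  if (nrow(m) < 16) stop("index map must be at least 16 x 16", call. = FALSE)

  n_px <- nrow(m)
  x <- m - mean(m)
  if (window == "hann") {
    w <- 0.5 * (1 - cos(2 * pi * (seq_len(n_px) - 1) / (n_px - 1)))
    x <- x * outer(w, w)
  }
  p <- Mod(stats::fft(x))^2 / length(x)

  # center the zero-frequency bin
  k <- seq_len(n_px) - 1L
  k[k >= ceiling(n_px / 2)] <- k[k >= ceiling(n_px / 2)] - n_px
  ord <- order(k)
  p <- p[ord, ord]
  freq_step <- 1 / (n_px * index_map$pixel_size)

  structure(
    list(power = p, freq = sort(k) * freq_step, freq_step = freq_step,
         total_power = sum(p), dc_removed = TRUE,
         pixel_size = index_map$pixel_size, n_bar = n_bar),
    class = "power_spectrum"
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat("<power_spectrum> ", nrow(x$power), " x ", ncol(x$power),
      " bins, freq step ", signif(x$freq_step, 4),
      " cycles/nm, total power ", signif(x$total_power, 5), "\n", sep = "")
  invisible(x)
}

#' Radial average of a 2-D power spectrum
#'
#' Averages the centered power spectrum over annuli of constant spatial
#' frequency magnitude \eqn{|k| \in [c - w/2, c + w/2)}. Because the annuli
#' are rotation-symmetric, the profile is invariant to image rotation and
#' transposition. Power per annulus is reported both as the annulus mean and
#' as a percentage of total power (computed from annulus sums, so the
#' percentages add to 100), which makes profiles from different crops
#' comparable.
#'
#' @param ps A `power_spectrum` with the DC component removed.
#' @param bin_width Annulus width in cycles/nm; default one frequency step.
#'   Must be positive and no larger than the Nyquist frequency.
#' @return A `radial_profile` tibble with columns `freq` (annulus center,
#'   cycles/nm), `power` (annulus mean), `power_sum`, `power_pct`, `n_bins`
#'   (pixels per annulus). Attributes `bin_width`, `n_bar`, `freq_step` are
#'   attached for downstream mapping.
#' @export
radial_average <- function(ps, bin_width = ps$freq_step) {
  stopifnot(inherits(ps, "power_spectrum"))
  if (!isTRUE(ps$dc_removed)) stop("power spectrum must be DC-removed", call. = FALSE)
  nyquist <- 1 / (2 * ps$pixel_size)
  if (bin_width <= 0 || bin_width > nyquist) {
    stop("bin_width must be in (0, Nyquist = ", signif(nyquist, 4),
         "] cycles/nm", call. = FALSE)
  }
  r <- sqrt(outer(ps$freq^2, ps$freq^2, "+"))
  bin <- as.integer(floor(r / bin_width + 0.5))
  keep <- bin > 0L  # the DC annulus carries no structural signal
  bins <- bin[keep]
  n_annuli <- max(bins)
  counts <- tabulate(bins, nbins = n_annuli)
  sums <- numeric(n_annuli)
  rs <- rowsum(ps$power[keep], bins)
  sums[as.integer(rownames(rs))] <- rs[, 1]
  # empty annuli (possible near the spectrum corners) carry zero power
  means <- ifelse(counts > 0, sums / pmax(counts, 1L), 0)
  total <- sum(sums)
  out <- tibble::tibble(
    freq = seq_len(n_annuli) * bin_width,
    power = means,
    power_sum = sums,
    power_pct = if (total > 0) 100 * sums / total else sums,
    n_bins = counts
  )
  structure(out, class = c("radial_profile", class(out)),
            bin_width = bin_width, n_bar = ps$n_bar,
            freq_step = ps$freq_step)
}

#' Map a spatial frequency to a backscattered wavelength
#'
#' Normal-incidence constructive interference from refractive-index
#' periodicity at spatial frequency `f` (cycles/nm) peaks at
#' \eqn{\lambda = 2 \bar n / f}: light travels the period twice, weighted by
#' the tissue's volume-averaged index. With the volume-weighted \eqn{\bar n}
#' this reproduces the ideal-multilayer peak \eqn{2(n_1 d_1 + n_2 d_2)}
#' exactly for a two-phase stack.
#'
#' @param f Spatial frequency in cycles/nm (> 0); vectorized.
#' @param n_bar Volume-weighted mean refractive index.
#' @return Wavelength(s) in nm.
#' @examples
#' frequency_to_wavelength(1 / 221, 1.2787)  # ~565 nm
#' @export
frequency_to_wavelength <- function(f, n_bar) {
  if (any(f <= 0)) stop("frequency must be > 0", call. = FALSE)
  stopifnot(n_bar > 0)
  2 * n_bar / f
}

#' Predicted reflectance spectrum from a radial power profile
#'
#' Maps each frequency annulus to a wavelength via
#' \eqn{\lambda = 2\bar n / f} and re-expresses the (percent) power on the
#' wavelength grid as the predicted normal-incidence reflectance. The peak
#' wavelength is reported both restricted to the visible band (350--700 nm,
#' the default headline value) and unrestricted — reflectors tuned into the
#' near infrared are physically meaningful and appear in the unrestricted
#' value.
#'
#' @param profile A `radial_profile`.
#' @param n_bar Volume-weighted mean refractive index in (1, 2); defaults to
#'   the value carried on the profile.
#' @param lambda_max_method `"parabolic"` (default): the peak frequency is
#'   refined by a parabolic fit through the peak annulus and its neighbors
#'   before mapping to wavelength; `"bin"` uses the raw annulus center.
#' @param visible_band Two-element nm range defining the visible window.
#' @return A `predicted_spectrum`: list with `data` (tibble: `wavelength`,
#'   `reflectance` in % power, `freq`, `visible` flag), `lambda_max`
#'   (visible-restricted), `lambda_max_unrestricted`, `n_bar`,
#'   `visible_band`, and `visible_freq_band` (the coherent-scattering
#'   frequency window `2 n_bar / rev(visible_band)`).
#' @export
predicted_reflectance <- function(profile, n_bar = attr(profile, "n_bar"),
                                  lambda_max_method = c("parabolic", "bin"),
                                  visible_band = c(350, 700)) {
  stopifnot(inherits(profile, "radial_profile"), nrow(profile) > 0)
  lambda_max_method <- match.arg(lambda_max_method)
  if (is.null(n_bar) || is.na(n_bar) || n_bar <= 1 || n_bar >= 2) {
    stop("n_bar must be supplied and lie in (1, 2)", call. = FALSE)
  }
  f <- profile$freq
  pw <- profile$power
  pct <- profile$power_pct
  visible_freq_band <- 2 * n_bar / rev(visible_band)

  peak_freq <- function(idx_set) {
    if (!length(idx_set)) return(NA_real_)
    i <- idx_set[which.max(pw[idx_set])]
    if (lambda_max_method == "bin" || i == 1L || i == length(f)) return(f[i])
    y1 <- pw[i - 1L]; y2 <- pw[i]; y3 <- pw[i + 1L]
    den <- y1 - 2 * y2 + y3
    delta <- if (den == 0) 0 else 0.5 * (y1 - y3) / den
    delta <- max(min(delta, 0.5), -0.5)
    f[i] + delta * (f[2] - f[1])
  }

  f_peak_all <- peak_freq(seq_along(f))
  vis_idx <- which(f >= visible_freq_band[1] & f <= visible_freq_band[2])
  f_peak_vis <- peak_freq(vis_idx)
  if (is.na(f_peak_all) && is.na(f_peak_vis)) {
    stop("profile has no bins in a mappable frequency range", call. = FALSE)
  }

  data <- tibble::tibble(
    freq = f,
    wavelength = 2 * n_bar / f,
    reflectance = pct,
    visible = f >= visible_freq_band[1] & f <= visible_freq_band[2]
  )
  data <- dplyr::arrange(data, .data$wavelength)

  structure(
    list(
      data = data,
      lambda_max = if (is.na(f_peak_vis)) NA_real_ else 2 * n_bar / f_peak_vis,
      lambda_max_unrestricted = 2 * n_bar / f_peak_all,
      n_bar = n_bar,
      visible_band = visible_band,
      visible_freq_band = visible_freq_band,
      lambda_max_method = lambda_max_method
    ),
    class = "predicted_spectrum"
  )
}

#' @export
print.predicted_spectrum <- function(x, ...) {
  cat("<predicted_spectrum> n_bar ", signif(x$n_bar, 5), "\n", sep = "")
  cat("  lambda_max (visible ", x$visible_band[1], "-", x$visible_band[2],
      " nm): ", signif(x$lambda_max, 5), " nm\n", sep = "")
  cat("  lambda_max (unrestricted): ",
      signif(x$lambda_max_unrestricted, 5), " nm\n", sep = "")
  invisible(x)
}

#' @rdname predicted_reflectance
#' @param x A `predicted_spectrum`.
#' @param ... Unused.
#' @export
tidy.predicted_spectrum <- function(x, ...) x$data

#' @rdname predicted_reflectance
#' @export
glance.predicted_spectrum <- function(x, ...) {
  tibble::tibble(
    lambda_max = x$lambda_max,
    lambda_max_unrestricted = x$lambda_max_unrestricted,
    n_bar = x$n_bar,
    visible_low = x$visible_band[1],
    visible_high = x$visible_band[2]
  )
}
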