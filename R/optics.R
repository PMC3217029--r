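#' Lamina perforation factor
#'
#' The perforation factor *p* of a scale lamina is its open-area fraction:
#' open pixels over total pixels of the analyzed region. The convention is
#' that the absent/dark phase (mask value `FALSE`/0) is open; use `invert`
#' for images with the opposite contrast.
#'
#' @param phase A `phase_map`, a `synthetic_image` from
#'   [generate_perforated_lamina()] (thresholded at mid-gray), or a logical
#'   matrix (TRUE = solid).
#' @param invert Treat the TRUE/bright phase as open instead.
#' @return A tibble with columns `p`, `open_pixels`, `total_pixels`.
#' @export
perforation_factor <- function(phase, invert = FALSE) {
  solid <- if (inherits(phase, "phase_map")) {
    phase$mask
  } else if (inherits(phase, "raster_image")) {
    phase$pixels > 127.5
  } else if (is.matrix(phase)) {
    phase > 0
  } else {
    stop("expected a phase_map, raster image, or matrix", call. = FALSE)
  }
  if (length(solid) == 0) stop("empty region", call. = FALSE)
  open <- if (invert) solid else !solid
  tibble::tibble(
    p = mean(open),
    open_pixels = sum(open),
    total_pixels = length(open)
  )
}

#' Count propagating nonzero diffraction orders
#'
#' For a grating of period `period_d` illuminated at `incidence_deg` from
#' normal, counts the integers \eqn{m \ne 0} with
#' \eqn{|\sin\theta_i + m \lambda / d| \le 1} (both signs). A count of zero
#' means the grating is in the zero-order regime: only specular reflection
#' propagates, and the element cannot disperse color.
#'
#' @param period_d Grating period in nm (> 0).
#' @param lambda Wavelength(s) in nm (> 0); vectorized.
#' @param incidence_deg Angle of incidence in degrees from normal
#'   (|angle| < 90).
#' @return Integer vector: number of propagating nonzero orders per
#'   wavelength.
#' @examples
#' propagating_orders(140, 350:700)   # all zero: sub-wavelength period
#' propagating_orders(1800, 565)      # 6 (m = +-1, +-2, +-3)
#' @export
propagating_orders <- function(period_d, lambda, incidence_deg = 0) {
  stopifnot(period_d > 0, all(lambda > 0), abs(incidence_deg) < 90)
  s0 <- sin(incidence_deg * pi / 180)
  vapply(lambda, function(l) {
    m_max <- ceiling(2 * period_d / l)  # |m| l/d <= 2 is a safe bound
    m <- setdiff(-m_max:m_max, 0L)
    sum(abs(s0 + m * l / period_d) <= 1)
  }, integer(1))
}

#' Ideal multilayer reflectance peak (closed form)
#'
#' Fundamental normal-incidence constructive-interference peak of an
#' infinite periodic two-phase stack: \eqn{\lambda = 2 (n_1 d_1 + n_2 d_2)}.
#' This is the closed-form oracle the Fourier pipeline is validated against.
#'
#' @param d1,d2 Layer thicknesses in nm (> 0).
#' @param n1,n2 Refractive indices (>= 1).
#' @return Peak wavelength in nm.
#' @examples
#' ideal_multilayer_peak(110, 1.56, 111, 1.0)  # 565.2 nm
#' @export
ideal_multilayer_peak <- function(d1, n1, d2, n2) {
  stopifnot(all(d1 > 0), all(d2 > 0), all(n1 >= 1), all(n2 >= 1))
  2 * (n1 * d1 + n2 * d2)
}

#' Build a layer stack for transfer-matrix calculations
#'
#' @param n Refractive index per layer (>= 1), top (incidence side) first.
#' @param d Thickness per layer in nm (> 0).
#' @param n_ambient Index of the incidence medium (default 1, air).
#' @param n_substrate Index of the exit medium (default 1).
#' @return A `stack_spec` tibble of layers with ambient/substrate attributes.
#' @export
stack_spec <- function(n, d, n_ambient = 1, n_substrate = 1) {
  stopifnot(length(n) == length(d), all(d > 0), all(n >= 1),
            n_ambient >= 1, n_substrate >= 1)
  out <- tibble::tibble(n = n, d = d)
  structure(out, class = c("stack_spec", class(out)),
            n_ambient = n_ambient, n_substrate = n_substrate)
}

#' Quarter-wave stack tuned to a design wavelength
#'
#' Each layer has optical thickness \eqn{\lambda_0 / 4}
#' (\eqn{d_j = \lambda_0 / (4 n_j)}), the geometry that maximizes
#' reflectance at \eqn{\lambda_0}.
#'
#' @param lambda0 Design wavelength in nm.
#' @param n_high,n_low Refractive indices of the alternating layers.
#' @param bilayers Number of high/low bilayers.
#' @inheritParams stack_spec
#' @return A `stack_spec`.
#' @export
quarter_wave_stack <- function(lambda0, n_high = 1.56, n_low = 1.0,
                               bilayers = 5, n_ambient = 1, n_substrate = 1) {
  stopifnot(lambda0 > 0, bilayers >= 1)
  n <- rep(c(n_high, n_low), bilayers)
  d <- lambda0 / (4 * n)
  stack_spec(n, d, n_ambient, n_substrate)
}

#' Normal-incidence reflectance of a layer stack (transfer matrix)
#'
#' Characteristic-matrix (Abeles) method for a stack of non-absorbing
#' layers: each layer contributes phase \eqn{\delta_j = 2\pi n_j d_j /
#' \lambda} and matrix \eqn{[[\cos\delta_j, i \sin\delta_j / n_j],
#' [i n_j \sin\delta_j, \cos\delta_j]]}; the product over layers with the
#' ambient and substrate admittances gives the amplitude reflectance, whose
#' squared magnitude is the reflectance. Real finite stacks built from
#' chitin and air reflect well below 100%: this is the quantitative oracle
#' behind treating few-layer biological reflectors as non-ideal.
#'
#' @param stack A `stack_spec`. An empty stack between equal ambient and
#'   substrate media reflects nothing.
#' @param lambda_grid Wavelengths in nm (non-empty, > 0).
#' @return A tibble with columns `wavelength` and `reflectance` (in [0, 1]).
#' @export
transfer_matrix_reflectance <- function(stack, lambda_grid) {
  stopifnot(inherits(stack, "stack_spec"), length(lambda_grid) >= 1,
            all(lambda_grid > 0))
  n0 <- attr(stack, "n_ambient")
  ns <- attr(stack, "n_substrate")
  refl <- vapply(lambda_grid, function(l) {
    M <- diag(2)
    for (j in seq_len(nrow(stack))) {
      nj <- stack$n[j]
      dj <- stack$d[j]
      delta <- 2 * pi * nj * dj / l
      Mj <- matrix(c(cos(delta), 1i * sin(delta) / nj,
                     1i * nj * sin(delta), cos(delta)),
                   nrow = 2, byrow = TRUE)
      M <- M %*% Mj
    }
    B <- M[1, 1] + M[1, 2] * ns
    C <- M[2, 1] + M[2, 2] * ns
    r <- (n0 * B - C) / (n0 * B + C)
    Mod(r)^2
  }, numeric(1))
  tibble::tibble(wavelength = lambda_grid, reflectance = refl)
}
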