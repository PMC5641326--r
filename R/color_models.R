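# Colour-space transforms from 8-bit sRGB to HSI, CIE-Lab and CIE-Luv.
# All functions are vectorized over pixels and total on valid 8-bit input.

# IEC 61966-2-1 sRGB -> XYZ matrix, D65 white (2 degree observer).
.srgb_to_xyz_matrix <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)

# white point taken as the matrix row sums (the image of RGB = (1,1,1)) so
# that grey inputs land exactly on the achromatic axis
.d65_white <- setNames(rowSums(.srgb_to_xyz_matrix), c("X", "Y", "Z"))

.check_rgb8 <- function(r, g, b) {
  if (length(r) != length(g) || length(g) != length(b))
    stop("R, G, B channel vectors must have equal length", call. = FALSE)
  rng <- range(c(r, g, b))
  if (any(is.na(rng)) || rng[1] < 0 || rng[2] > 255)
    stop("RGB channels must be in [0, 255]", call. = FALSE)
  invisible(TRUE)
}

#' Convert 8-bit RGB to Hue, Saturation, Intensity
#'
#' Classic HSI decomposition used for hue-window pixel classification:
#' Intensity is the mean of the normalized channels (overall albedo),
#' Saturation is \code{1 - min/Intensity} (0 for grey pixels), and Hue is the
#' hexagonal hue angle in degrees with red at 0, green at 120 and blue at 240.
#' Achromatic pixels (max = min) get Hue 0 and Saturation 0 by convention.
#'
#' @param r,g,b numeric vectors of 8-bit channel values in `[0, 255]`.
#' @return A data.frame with columns `hue` (degrees, `[0, 360)`),
#'   `saturation` (`[0, 1]`) and `intensity` (`[0, 1]`), one row per pixel.
#' @examples
#' rgb_to_hsi(0, 255, 0)    # pure green: hue 120, saturation 1
#' rgb_to_hsi(128, 128, 128) # grey: saturation 0
#' @export
rgb_to_hsi <- function(r, g, b) {
  .check_rgb8(r, g, b)
  x <- r / 255; y <- g / 255; z <- b / 255
  i <- (x + y + z) / 3
  mn <- pmin(x, y, z); mx <- pmax(x, y, z)
  s <- ifelse(i > 0, 1 - mn / i, 0)
  d <- mx - mn
  hue <- numeric(length(x))
  chroma <- d > 0
  hr <- chroma & mx == x
  hg <- chroma & mx == y & !hr
  hb <- chroma & !hr & !hg
  hue[hr] <- (((y[hr] - z[hr]) / d[hr]) %% 6) * 60
  hue[hg] <- ((z[hg] - x[hg]) / d[hg] + 2) * 60
  hue[hb] <- ((x[hb] - y[hb]) / d[hb] + 4) * 60
  data.frame(hue = hue %% 360, saturation = s, intensity = i)
}

# sRGB gamma expansion (decoding) for channel values in [0, 1].
.srgb_decode <- function(c) ifelse(c <= 0.04045, c / 12.92, ((c + 0.055) / 1.055)^2.4)

.rgb_to_xyz <- function(r, g, b) {
  lin <- cbind(.srgb_decode(r / 255), .srgb_decode(g / 255), .srgb_decode(b / 255))
  lin %*% t(.srgb_to_xyz_matrix)
}

.lab_f <- function(t) {
  delta <- 6 / 29
  ifelse(t > delta^3, t^(1 / 3), t / (3 * delta^2) + 4 / 29)
}

#' Convert 8-bit RGB to CIE-Lab
#'
#' sRGB channels are gamma-expanded, mapped to XYZ under the D65 white point
#' and converted to CIE 1976 L*a*b*. White (255,255,255) maps to
#' L = 100, a* = b* = 0; greys lie on the achromatic axis.
#'
#' @inheritParams rgb_to_hsi
#' @return A data.frame with columns `L` (`[0, 100]`), `a` and `b`.
#' @export
rgb_to_cielab <- function(r, g, b) {
  .check_rgb8(r, g, b)
  xyz <- .rgb_to_xyz(r, g, b)
  fx <- .lab_f(xyz[, 1] / .d65_white["X"])
  fy <- .lab_f(xyz[, 2] / .d65_white["Y"])
  fz <- .lab_f(xyz[, 3] / .d65_white["Z"])
  data.frame(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

#' Convert 8-bit RGB to CIE-Luv
#'
#' Same decoding and white point as [rgb_to_cielab()] with the CIE 1976
#' L*u*v* chromaticity axes; white and greys map to u* = v* = 0.
#'
#' @inheritParams rgb_to_hsi
#' @return A data.frame with columns `L`, `u` and `v`.
#' @export
rgb_to_cieluv <- function(r, g, b) {
  .check_rgb8(r, g, b)
  xyz <- .rgb_to_xyz(r, g, b)
  X <- xyz[, 1]; Y <- xyz[, 2]; Z <- xyz[, 3]
  L <- 116 * .lab_f(Y / .d65_white["Y"]) - 16
  den <- X + 15 * Y + 3 * Z
  wden <- sum(.d65_white * c(1, 15, 3))
  up <- ifelse(den > 0, 4 * X / den, 0)
  vp <- ifelse(den > 0, 9 * Y / den, 0)
  un <- 4 * .d65_white["X"] / wden
  vn <- 9 * .d65_white["Y"] / wden
  # black (den = 0) has L = 0 so u*, v* vanish regardless of u', v'
  data.frame(L = L, u = 13 * L * (up - un), v = 13 * L * (vp - vn))
}

#' All colour components of a set of pixels
#'
#' Convenience wrapper returning every colour component used as an RGB
#' vegetation index: HSI hue/saturation/intensity, CIE-Lab L/a*/b* and
#' CIE-Luv u*/v* (Lightness is shared between Lab and Luv).
#'
#' @inheritParams rgb_to_hsi
#' @return A data.frame with columns `intensity`, `hue`, `saturation`,
#'   `lightness`, `a`, `b`, `u`, `v`.
#' @export
rgb_color_components <- function(r, g, b) {
  hsi <- rgb_to_hsi(r, g, b)
  lab <- rgb_to_cielab(r, g, b)
  luv <- rgb_to_cieluv(r, g, b)
  data.frame(intensity = hsi$intensity, hue = hsi$hue,
             saturation = hsi$saturation, lightness = lab$L,
             a = lab$a, b = lab$b, u = luv$u, v = luv$v)
}
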