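# Multispectral reflectance indices from 11-band stacks and per-plot thermal
# summaries.
#
# A reflectance stack is a list with elements:
#   bands   - named list (names = wavelength in nm) of matrices, or a named
#             numeric vector of per-plot mean reflectances
#   scale   - "unit" ([0,1]) or "8bit" ([0,255]); declared, never guessed
#   plot_id - optional identifier
#
# The per-plot index is the formula applied to the per-plot mean band
# reflectance (means first, then the formula), matching the per-plot export
# workflow; a pixelwise mode is available for sensitivity analysis.

#' Camera band centre wavelengths (nm)
#'
#' The 11 distinct centre wavelengths of the 12-sensor multispectral array
#' (780 nm appears twice on the camera). 720 and 860 nm are carried through
#' I/O but used by no index formula.
#' @export
ms_wavelengths <- function() c(450, 550, 570, 670, 700, 720, 780, 840, 860, 900, 950)

#' Names of the supported multispectral indices
#' @export
spectral_index_names <- function() {
  c("NDVI", "PRI", "SAVI", "MCARI", "WBI", "RDVI", "EVI", "ARI2", "CRI2",
    "TCARI", "OSAVI", "TCARI_OSAVI")
}

# wavelengths each index needs
.index_bands <- list(
  NDVI = c(840, 670), PRI = c(550, 570), SAVI = c(840, 670),
  MCARI = c(700, 670, 550), WBI = c(900, 950), RDVI = c(840, 670),
  EVI = c(840, 670, 450), ARI2 = c(840, 550, 700), CRI2 = c(550, 700),
  TCARI = c(700, 670, 550), OSAVI = c(780, 670),
  TCARI_OSAVI = c(700, 670, 550, 780))

.mean_bands <- function(stack) {
  b <- if (is.list(stack) && !is.null(stack$bands)) stack$bands else stack
  if (is.list(b)) b <- vapply(b, function(m) mean(as.numeric(m)), numeric(1))
  if (is.null(names(b)) || anyNA(suppressWarnings(as.numeric(names(b)))))
    stop("bands must be named by wavelength in nm", call. = FALSE)
  if (any(b < 0)) stop("reflectance values must be non-negative", call. = FALSE)
  b
}

.band <- function(bands, wl) {
  i <- match(as.character(wl), names(bands))
  if (is.na(i)) stop("required band ", wl, " nm missing from stack", call. = FALSE)
  unname(bands[i])
}

#' Compute one multispectral index from a reflectance stack
#'
#' Evaluates the named index formula on the per-plot mean band reflectances.
#' Soil-adjustment constants (L for SAVI, the +1 in EVI, +0.16 in OSAVI) are
#' applied on the declared reflectance scale without rescaling. A zero
#' denominator yields NaN with a warning, never a silent infinity.
#'
#' @param name one of [spectral_index_names()].
#' @param stack reflectance stack (see file header) or a named numeric vector
#'   of mean reflectances keyed by wavelength in nm.
#' @param L soil background adjustment factor for SAVI (default 0.5).
#' @return The index value (scalar).
#' @examples
#' b <- c(`450` = .05, `550` = .15, `570` = .14, `670` = .10, `700` = .20,
#'        `780` = .50, `840` = .50, `900` = .40, `950` = .38)
#' compute_spectral_index("NDVI", b)
#' @export
compute_spectral_index <- function(name, stack, L = 0.5) {
  name <- match.arg(name, spectral_index_names())
  b <- .mean_bands(stack)
  R <- function(wl) .band(b, wl)
  bad <- function(msg) { warning(msg, call. = FALSE); NaN }
  switch(name,
    NDVI = {
      den <- R(840) + R(670)
      if (den == 0) bad("NDVI: R840 + R670 = 0") else (R(840) - R(670)) / den
    },
    PRI = {
      den <- R(550) + R(570)
      if (den == 0) bad("PRI: R550 + R570 = 0") else (R(550) - R(570)) / den
    },
    SAVI = (R(840) - R(670)) / (R(840) + R(670) + L) * (1 + L),
    MCARI = if (R(670) == 0) bad("MCARI: R670 = 0") else
      ((R(700) - R(670)) - 0.2 * (R(700) - R(550))) * (R(700) / R(670)),
    WBI = if (R(950) == 0) bad("WBI: R950 = 0") else R(900) / R(950),
    RDVI = {
      den <- R(840) + R(670)
      if (den <= 0) bad("RDVI: R840 + R670 <= 0") else (R(840) - R(670)) / sqrt(den)
    },
    EVI = {
      den <- R(840) + 6 * R(670) - 7.5 * R(450) + 1
      if (den == 0) bad("EVI: denominator = 0") else 2.5 * (R(840) - R(670)) / den
    },
    ARI2 = if (R(550) == 0 || R(700) == 0) bad("ARI2: R550 or R700 = 0") else
      R(840) * (1 / R(550) - 1 / R(700)),
    CRI2 = if (R(550) == 0 || R(700) == 0) bad("CRI2: R550 or R700 = 0") else
      1 / R(550) - 1 / R(700),
    TCARI = if (R(670) == 0) bad("TCARI: R670 = 0") else
      3 * ((R(700) - R(670)) - 0.2 * (R(700) - R(550)) * (R(700) / R(670))),
    OSAVI = (1 + 0.16) * (R(780) - R(670)) / (R(780) + R(670) + 0.16),
    TCARI_OSAVI = {
      os <- compute_spectral_index("OSAVI", b)
      tc <- compute_spectral_index("TCARI", b)
      if (is.nan(tc) || os == 0) {
        if (!is.nan(tc)) warning("TCARI/OSAVI: OSAVI = 0", call. = FALSE)
        NaN
      } else tc / os
    })
}

#' All multispectral indices for one stack
#'
#' @inheritParams compute_spectral_index
#' @return One-row data.frame with a column per index.
#' @export
compute_spectral_indexset <- function(stack, L = 0.5) {
  vals <- lapply(spectral_index_names(), compute_spectral_index, stack = stack, L = L)
  as.data.frame(setNames(vals, spectral_index_names()))
}

#' Read a multi-band reflectance TIFF
#'
#' Bands are stored one per TIFF page in ascending wavelength order.
#'
#' @param path multi-page TIFF file.
#' @param wavelengths wavelengths (nm) of the pages in order; default the
#'   11 camera bands.
#' @param scale declared reflectance scale, "unit" or "8bit".
#' @return A reflectance stack list (`bands`, `scale`, `plot_id`).
#' @export
read_reflectance_stack <- function(path, wavelengths = ms_wavelengths(),
                                   scale = c("unit", "8bit")) {
  scale <- match.arg(scale)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(wavelengths))
    stop("stack has ", length(pages), " bands but ", length(wavelengths),
         " wavelengths declared: ", path, call. = FALSE)
  bands <- lapply(pages, function(p) if (scale == "8bit") p * 255 else p)
  names(bands) <- as.character(wavelengths)
  list(bands = bands, scale = scale,
       plot_id = tools::file_path_sans_ext(basename(path)))
}

#' Batch spectral indices over a directory of stacks
#'
#' @param stack_dir directory of multi-page TIFF stacks (`*.tif`).
#' @inheritParams read_reflectance_stack
#' @inheritParams compute_spectral_index
#' @return data.frame, one row per stack with `plot_id` first.
#' @export
batch_spectral_indices <- function(stack_dir, wavelengths = ms_wavelengths(),
                                   scale = "unit", L = 0.5) {
  files <- sort(list.files(stack_dir, pattern = "\\.tiff?$", full.names = TRUE))
  rows <- lapply(files, function(f) {
    st <- read_reflectance_stack(f, wavelengths, scale)
    cbind(data.frame(plot_id = st$plot_id, stringsAsFactors = FALSE),
          compute_spectral_indexset(st, L = L))
  })
  do.call(rbind, rows)
}

# ---- thermal ---------------------------------------------------------------

#' Convert raw thermal counts to degrees Celsius
#'
#' Thermal cameras export 16-bit digital numbers proportional to Kelvin;
#' temperature in Celsius is `dn * scale - 273.15`. The default scale of
#' 0.01 K per count (centi-Kelvin) is configurable.
#'
#' @param dn non-negative integer counts (vector or matrix).
#' @param scale Kelvin per count (> 0).
#' @return Temperatures in degrees Celsius, same shape as `dn`. Values outside
#'   `[-100, 150]` trigger a plausibility warning.
#' @export
raw_to_celsius <- function(dn, scale = 0.01) {
  if (any(dn < 0)) stop("raw counts must be non-negative", call. = FALSE)
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  celsius <- dn * scale - 273.15
  if (any(celsius < -100 | celsius > 150))
    warning("implausible temperatures outside [-100, 150] degC; check the scale",
            call. = FALSE)
  celsius
}

#' Per-plot thermal summary
#'
#' Arithmetic mean and population standard deviation over unmasked pixels of
#' a temperature raster in degrees Celsius.
#'
#' @param raster numeric matrix of temperatures; NA pixels are masked.
#' @return list with `mean` and `sd` (both degC).
#' @export
thermal_summary <- function(raster) {
  x <- as.numeric(raster)
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("fully masked thermal raster", call. = FALSE)
  m <- mean(x)
  list(mean = m, sd = sqrt(mean((x - m)^2)))
}

#' Read a 16-bit thermal TIFF and convert to Celsius
#'
#' Raw counts are stored as value*65535 in the TIFF; this reads them back and
#' applies [raw_to_celsius()].
#'
#' @param path single-page 16-bit TIFF of raw counts.
#' @inheritParams raw_to_celsius
#' @return numeric matrix of temperatures in degC.
#' @export
read_thermal_raster <- function(path, scale = 0.01) {
  img <- tiff::readTIFF(path)
  raw_to_celsius(round(img * 65535), scale = scale)
}

#' Batch thermal summaries over a directory of rasters
#'
#' @param raster_dir directory of thermal TIFFs.
#' @inheritParams raw_to_celsius
#' @return data.frame with columns `plot_id`, `mean`, `sd`.
#' @export
batch_thermal_summaries <- function(raster_dir, scale = 0.01) {
  files <- sort(list.files(raster_dir, pattern = "\\.tiff?$", full.names = TRUE))
  rows <- lapply(files, function(f) {
    s <- thermal_summary(read_thermal_raster(f, scale))
    data.frame(plot_id = tools::file_path_sans_ext(basename(f)),
               mean = s$mean, sd = s$sd, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
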