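# Per-plot RGB vegetation indices: mean colour components, Green Area (GA),
# Greener Green Area (GGA) and the Crop Senescence Index (CSI).
#
# Plot images are H x W x 3 arrays of 8-bit values (0-255). read_plot_image()
# produces them from PNG/JPEG-decoded [0,1] rasters written by the synthetic
# generator or any other source.

#' Read a plot RGB image as an 8-bit array
#'
#' @param path path to a PNG (or TIFF) RGB image.
#' @return An H x W x 3 array of integer values in 0-255.
#' @export
read_plot_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format for ", path, call. = FALSE))
  if (length(dim(img)) != 3 || dim(img)[3] < 3)
    stop("not a 3-channel RGB image: ", path, call. = FALSE)
  round(img[, , 1:3] * 255)
}

.image_channels <- function(image) {
  if (length(dim(image)) != 3 || dim(image)[3] < 3)
    stop("plot image must be an H x W x 3 array", call. = FALSE)
  if (prod(dim(image)[1:2]) == 0) stop("empty image", call. = FALSE)
  list(r = as.vector(image[, , 1]), g = as.vector(image[, , 2]),
       b = as.vector(image[, , 3]))
}

#' Classify green canopy pixels by hue window
#'
#' GA (Green Area) is the fraction of pixels whose hue falls in the wide
#' green window; GGA (Greener Green Area) uses a narrower nested window that
#' excludes yellowish hues of senescent tissue, so GGA <= GA always. Pixels
#' with HSI saturation below `min_saturation` are treated as achromatic and
#' never counted (hue is ill-defined for grey pixels).
#'
#' @param image H x W x 3 array of 8-bit RGB values.
#' @param ga_window,gga_window numeric length-2 hue intervals in degrees;
#'   `gga_window` must be nested inside `ga_window`. Defaults `[60, 180]` and
#'   `[80, 180]` follow the BreedPix convention.
#' @param min_saturation achromatic guard on HSI saturation (default 0.02).
#' @return A list with elements `ga` and `gga`, both proportions in `[0, 1]`.
#' @export
classify_green <- function(image, ga_window = c(60, 180),
                           gga_window = c(80, 180), min_saturation = 0.02) {
  ch <- .image_channels(image)
  .check_hue_windows(ga_window, gga_window)
  hsi <- rgb_to_hsi(ch$r, ch$g, ch$b)
  ok <- hsi$saturation >= min_saturation
  h <- hsi$hue
  n <- length(h)
  ga <- sum(ok & h >= ga_window[1] & h <= ga_window[2]) / n
  gga <- sum(ok & h >= gga_window[1] & h <= gga_window[2]) / n
  list(ga = ga, gga = gga)
}

.check_hue_windows <- function(ga_window, gga_window) {
  stopifnot(length(ga_window) == 2, length(gga_window) == 2)
  if (ga_window[1] > ga_window[2] || gga_window[1] > gga_window[2])
    stop("hue windows must be non-decreasing intervals in [0, 360)", call. = FALSE)
  if (gga_window[1] < ga_window[1] || gga_window[2] > ga_window[2])
    stop("gga_window must be nested inside ga_window", call. = FALSE)
  invisible(TRUE)
}

#' Crop Senescence Index
#'
#' CSI = 100 x (GA - GGA) / GA, the percentage of green-area pixels that are
#' yellowish (senescent). Defined as 0 when GA = 0 so that bare-soil plots do
#' not propagate NaN into trial statistics.
#'
#' @param ga,gga proportions with `0 <= gga <= ga <= 1`.
#' @return CSI in `[0, 100]`.
#' @export
compute_csi <- function(ga, gga) {
  if (any(gga > ga + 1e-12)) stop("GGA cannot exceed GA", call. = FALSE)
  if (any(ga < 0 | ga > 1 | gga < 0)) stop("GA/GGA must be proportions", call. = FALSE)
  ifelse(ga > 0, 100 * (ga - gga) / ga, 0)
}

#' Full RGB index set for one plot image
#'
#' Computes the per-image mean colour components (over all pixels), GA, GGA
#' and CSI. The same computation applies to field-camera photographs and to
#' plot mini-rasters cut from a UAV RGB orthomosaic.
#'
#' @inheritParams classify_green
#' @return A one-row data.frame with columns `intensity`, `hue`,
#'   `saturation`, `lightness`, `a`, `b`, `u`, `v`, `ga`, `gga`, `csi`.
#' @export
compute_rgb_indexset <- function(image, ga_window = c(60, 180),
                                 gga_window = c(80, 180),
                                 min_saturation = 0.02) {
  ch <- .image_channels(image)
  comp <- rgb_color_components(ch$r, ch$g, ch$b)
  cls <- classify_green(image, ga_window, gga_window, min_saturation)
  out <- as.data.frame(t(colMeans(comp)))
  out$ga <- cls$ga
  out$gga <- cls$gga
  out$csi <- compute_csi(cls$ga, cls$gga)
  out
}

#' Batch RGB indices over a directory of plot images
#'
#' @param image_dir directory containing the images.
#' @param manifest data.frame with columns `plot_id` and `image` (file name
#'   relative to `image_dir`). If NULL, every PNG in the directory is used and
#'   plot ids are the file names without extension.
#' @param ... passed to [compute_rgb_indexset()].
#' @return data.frame with one row per plot, `plot_id` first.
#' @export
batch_rgb_indices <- function(image_dir, manifest = NULL, ...) {
  if (is.null(manifest)) {
    files <- sort(list.files(image_dir, pattern = "\\.png$"))
    manifest <- data.frame(plot_id = tools::file_path_sans_ext(files),
                           image = files, stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_plot_image(file.path(image_dir, manifest$image[i]))
    cbind(data.frame(plot_id = manifest$plot_id[i], stringsAsFactors = FALSE),
          compute_rgb_indexset(img, ...))
  })
  do.call(rbind, rows)
}
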