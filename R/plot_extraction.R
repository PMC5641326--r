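# Cut an orthomosaic raster into per-plot mini-rasters given plot polygons.
#
# Conventions (stated because imagery sources rarely agree): pixel
# coordinates are 0-based, x = column and y = row with rows increasing
# downward; the pixel at (row i, col j) has its centre at (j + 0.5, i + 0.5);
# a pixel belongs to a polygon when its centre lies inside (centre-sampling
# rule), which makes shared edges between adjacent plots half-open.

#' Point-in-polygon test (even-odd rule)
#'
#' @param px,py point coordinates (vectors).
#' @param vertices n x 2 matrix of polygon vertices (closed implicitly).
#' @return logical vector.
#' @export
points_in_polygon <- function(px, py, vertices) {
  n <- nrow(vertices)
  xs <- vertices[, 1]; ys <- vertices[, 2]
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

.check_polygon <- function(vertices) {
  if (!is.matrix(vertices) || ncol(vertices) != 2 || nrow(vertices) < 3)
    stop("polygon needs an n x 2 vertex matrix with n >= 3", call. = FALSE)
  invisible(TRUE)
}

.polygon_area <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  xi <- c(x[-1], x[1]); yi <- c(y[-1], y[1])
  sum(x * yi - xi * y) / 2
}

#' Polygon area (shoelace formula)
#' @param vertices n x 2 vertex matrix.
#' @return absolute area in squared coordinate units.
#' @export
polygon_area <- function(vertices) {
  .check_polygon(vertices)
  abs(.polygon_area(vertices))
}

#' Erode a convex polygon inward by a fixed margin
#'
#' Each edge is shifted inward along its normal by `margin` and the offset
#' edges are re-intersected. Used to trim plot borders and alleys before
#' computing plot means.
#'
#' @param vertices n x 2 matrix of a convex polygon.
#' @param margin erosion distance (>= 0), in the polygon's coordinate units.
#' @return Eroded n x 2 vertex matrix; `margin = 0` is the identity.
#' @export
inward_buffer <- function(vertices, margin) {
  .check_polygon(vertices)
  if (margin < 0) stop("margin must be non-negative", call. = FALSE)
  if (margin == 0) return(vertices)
  a <- .polygon_area(vertices)
  if (a == 0) stop("degenerate polygon", call. = FALSE)
  # orient counter-clockwise (positive signed area) so interior is to the left
  v <- if (a < 0) vertices[rev(seq_len(nrow(vertices))), , drop = FALSE] else vertices
  n <- nrow(v)
  nxt <- c(seq_len(n)[-1], 1)
  ex <- v[nxt, 1] - v[, 1]; ey <- v[nxt, 2] - v[, 2]
  len <- sqrt(ex^2 + ey^2)
  cross <- ex * ey[c(n, seq_len(n - 1))] - ey * ex[c(n, seq_len(n - 1))]
  if (any(cross > 1e-9 * max(len)^2))
    stop("inward_buffer supports convex polygons only", call. = FALSE)
  # left (inward) unit normal of each edge
  nx <- -ey / len; ny <- ex / len
  px <- v[, 1] + margin * nx; py <- v[, 2] + margin * ny
  out <- matrix(NA_real_, n, 2)
  prv <- c(n, seq_len(n - 1))
  for (i in seq_len(n)) {
    j <- prv[i]
    d <- ex[j] * ey[i] - ey[j] * ex[i]
    if (abs(d) < 1e-12) stop("parallel adjacent edges; cannot buffer", call. = FALSE)
    t <- ((px[i] - px[j]) * ey[i] - (py[i] - py[j]) * ex[i]) / d
    out[i, ] <- c(px[j] + t * ex[j], py[j] + t * ey[j])
  }
  # over-erosion flips edge directions (vertices cross); reject it
  onx <- c(seq_len(n)[-1], 1)
  ex2 <- out[onx, 1] - out[, 1]; ey2 <- out[onx, 2] - out[, 2]
  if (any(ex2 * ex + ey2 * ey <= 0) || .polygon_area(out) <= 0)
    stop("margin erodes the polygon to nothing", call. = FALSE)
  if (a < 0) out <- out[rev(seq_len(n)), , drop = FALSE]
  out
}

#' Read plot polygons from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features carrying a `plot_id`
#' property. Only the outer ring of each polygon is used.
#'
#' @param path GeoJSON file.
#' @return list of polygons, each a list with `plot_id` and `vertices`.
#' @export
read_plot_polygons <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  polys <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    v <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    # GeoJSON rings repeat the first vertex at the end
    if (nrow(v) > 3 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
    list(plot_id = as.character(f$properties$plot_id), vertices = v)
  })
  ids <- vapply(polys, `[[`, character(1), "plot_id")
  if (anyDuplicated(ids)) stop("duplicated plot_id in ", path, call. = FALSE)
  polys
}

#' Extract per-plot mini-rasters from an orthomosaic
#'
#' Each polygon is (optionally) eroded inward by `buffer` pixels, cropped to
#' its bounding box and masked: pixels whose centre falls outside the polygon
#' become NA in every band. A polygon that leaves the mosaic bounds produces
#' an error record and the batch continues.
#'
#' @param mosaic numeric matrix (single band) or H x W x B array.
#' @param polygons list of polygons as from [read_plot_polygons()], or a
#'   single n x 2 vertex matrix.
#' @param buffer inward erosion margin in pixels (default 0, no trimming).
#' @return list with `plots` (named list of mini-rasters, band structure
#'   preserved) and `report` (data.frame: plot_id, status, n_pixels).
#' @export
extract_plots <- function(mosaic, polygons, buffer = 0) {
  if (is.matrix(polygons)) polygons <- list(list(plot_id = "plot", vertices = polygons))
  dm <- dim(mosaic)
  h <- dm[1]; w <- dm[2]; nb <- if (length(dm) == 3) dm[3] else 1
  plots <- list()
  report <- data.frame(plot_id = character(0), status = character(0),
                       n_pixels = integer(0), stringsAsFactors = FALSE)
  for (poly in polygons) {
    id <- poly$plot_id
    v <- tryCatch(if (buffer > 0) inward_buffer(poly$vertices, buffer) else poly$vertices,
                  error = function(e) e)
    if (inherits(v, "error")) {
      report <- rbind(report, data.frame(plot_id = id, status = conditionMessage(v),
                                         n_pixels = 0L))
      next
    }
    if (min(v[, 1]) < 0 || max(v[, 1]) > w || min(v[, 2]) < 0 || max(v[, 2]) > h) {
      report <- rbind(report, data.frame(plot_id = id, status = "outside mosaic bounds",
                                         n_pixels = 0L))
      next
    }
    cols <- seq.int(max(1, floor(min(v[, 1])) + 1), min(w, ceiling(max(v[, 1]))))
    rows <- seq.int(max(1, floor(min(v[, 2])) + 1), min(h, ceiling(max(v[, 2]))))
    cx <- rep(cols - 0.5, each = length(rows))
    cy <- rep(rows - 0.5, times = length(cols))
    inside <- matrix(points_in_polygon(cx, cy, v), nrow = length(rows))
    if (nb == 1) {
      mini <- (if (length(dm) == 3) mosaic[rows, cols, 1] else mosaic[rows, cols])
      mini[!inside] <- NA
    } else {
      mini <- mosaic[rows, cols, , drop = FALSE]
      for (k in seq_len(nb)) { band <- mini[, , k]; band[!inside] <- NA; mini[, , k] <- band }
    }
    plots[[id]] <- mini
    report <- rbind(report, data.frame(plot_id = id, status = "ok",
                                       n_pixels = sum(inside)))
  }
  list(plots = plots, report = report)
}
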