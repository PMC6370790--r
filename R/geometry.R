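#' Planar polygon area (shoelace formula)
#'
#' @param poly two-column numeric matrix of vertex coordinates (x, y); the
#'   ring need not be closed.
#' @return Non-negative area in squared coordinate units.
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Even-odd point-in-polygon test
#'
#' Vectorised ray-casting test. Points exactly on an edge may fall on either
#' side; callers that care about boundaries should use area-based overlap
#' instead.
#'
#' @param px,py numeric vectors of point coordinates.
#' @param poly two-column vertex matrix.
#' @return Logical vector, `TRUE` where the point is inside.
#' @export
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Sutherland-Hodgman clip of a polygon against an axis-aligned rectangle.
# Returns a vertex matrix (possibly with 0 rows when nothing remains).
clip_polygon_rect <- function(poly, xmin, xmax, ymin, ymax) {
  poly <- as.matrix(poly)
  clip_edge <- function(pts, keep, intersect) {
    n <- nrow(pts)
    if (n == 0) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      prev <- pts[if (i == 1) n else i - 1, ]
      cur_in <- keep(cur); prev_in <- keep(prev)
      if (cur_in) {
        if (!prev_in) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (prev_in) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(p, q, val, axis) {
    # intersection of segment p-q with the line {axis == val}
    t <- (val - p[axis]) / (q[axis] - p[axis])
    p + t * (q - p)
  }
  poly <- clip_edge(poly, function(p) p[1] >= xmin, function(p, q) ix(p, q, xmin, 1))
  poly <- clip_edge(poly, function(p) p[1] <= xmax, function(p, q) ix(p, q, xmax, 1))
  poly <- clip_edge(poly, function(p) p[2] >= ymin, function(p, q) ix(p, q, ymin, 2))
  poly <- clip_edge(poly, function(p) p[2] <= ymax, function(p, q) ix(p, q, ymax, 2))
  poly
}

#' Area of intersection between a polygon and an axis-aligned rectangle
#'
#' @param poly two-column vertex matrix (simple polygon, any orientation).
#' @param xmin,xmax,ymin,ymax rectangle bounds.
#' @return Intersection area (0 when disjoint or touching only along an edge).
#' @export
polygon_rect_overlap <- function(poly, xmin, xmax, ymin, ymax) {
  bb <- apply(as.matrix(poly), 2, range)
  if (bb[2, 1] <= xmin || bb[1, 1] >= xmax || bb[2, 2] <= ymin || bb[1, 2] >= ymax)
    return(0)
  polygon_area(clip_polygon_rect(poly, xmin, xmax, ymin, ymax))
}

# H x W logical mask of pixel centres inside a polygon, evaluating the
# point-in-polygon test only within the polygon's bounding box
polygon_pixel_mask <- function(poly, h, w) {
  poly <- as.matrix(poly)
  bb <- apply(poly, 2, range)
  jj <- max(1L, floor(bb[1, 1])):min(w, ceiling(bb[2, 1]))
  ii <- max(1L, floor(bb[1, 2])):min(h, ceiling(bb[2, 2]))
  mask <- matrix(FALSE, h, w)
  if (length(jj) == 0 || length(ii) == 0) return(mask)
  px <- rep(jj - 0.5, each = length(ii))
  py <- rep(ii - 0.5, times = length(jj))
  mask[cbind(rep(ii, length(jj)), rep(jj, each = length(ii)))] <-
    point_in_polygon(px, py, poly)
  mask
}

#' In-memory single-band raster on a projected equal-area CRS
#'
#' A minimal raster container: a numeric matrix with row 1 the northernmost
#' row, plus the extent, resolution and a CRS label. All package operations
#' (climate generation, annual averaging, zonal aggregation) work on this
#' class; [write_raster()]/[read_raster()] round-trip it through TIFF with a
#' JSON sidecar carrying the georeferencing.
#'
#' @param values numeric matrix (row 1 = top/north).
#' @param xmin,ymin lower-left corner of the extent, metres.
#' @param res pixel size, metres (square pixels).
#' @param crs CRS label (e.g. an EPSG-style code such as "102008", or any
#'   string naming the projected equal-area system the coordinates live in).
#' @param units free-text units of the pixel values.
#' @return Object of class `clim_raster`.
#' @export
clim_raster <- function(values, xmin, ymin, res, crs = "synthetic-albers", units = "") {
  values <- as.matrix(values)
  if (!is.numeric(res) || length(res) != 1 || res <= 0)
    stop("`res` must be a single positive number of metres per pixel")
  structure(
    list(values = values, xmin = xmin, ymin = ymin, res = res,
         crs = crs, units = units),
    class = "clim_raster"
  )
}

#' @export
print.clim_raster <- function(x, ...) {
  cat(sprintf("<clim_raster> %d x %d pixels @ %g m, crs %s\n",
              nrow(x$values), ncol(x$values), x$res, x$crs))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]%s\n",
              x$xmin, raster_xmax(x), x$ymin, raster_ymax(x),
              if (nzchar(x$units)) paste0("  values: ", x$units) else ""))
  invisible(x)
}

#' @rdname clim_raster
#' @param x a `clim_raster`.
#' @export
raster_xmax <- function(x) x$xmin + ncol(x$values) * x$res

#' @rdname clim_raster
#' @export
raster_ymax <- function(x) x$ymin + nrow(x$values) * x$res

# pixel-centre coordinates; y follows matrix rows (row 1 = north)
raster_xcoords <- function(x) x$xmin + (seq_len(ncol(x$values)) - 0.5) * x$res
raster_ycoords <- function(x) raster_ymax(x) - (seq_len(nrow(x$values)) - 0.5) * x$res

raster_same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$res - b$res) < tol
}
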