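#' Write / read a raster as text with a JSON georeferencing sidecar
#'
#' Values go to a tab-separated text file at full double precision; extent,
#' resolution, CRS and units go to `<path>.json`. The round trip is exact.
#'
#' @param raster a `clim_raster`.
#' @param path file path (conventionally `.tsv`).
#' @return `write_raster` returns `path` invisibly; `read_raster` returns a
#'   `clim_raster`.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "clim_raster"))
  utils::write.table(
    format(raster$values, digits = 17, scientific = TRUE, trim = TRUE),
    path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(xmin = raster$xmin, ymin = raster$ymin, res = raster$res,
         crs = raster$crs, units = raster$units,
         nrow = nrow(raster$values), ncol = ncol(raster$values)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(v) <- NULL
  stopifnot(nrow(v) == meta$nrow, ncol(v) == meta$ncol)
  clim_raster(v, meta$xmin, meta$ymin, meta$res, meta$crs, meta$units)
}

#' Write / read specimen images and ROI masks as PNG
#'
#' Images are 24-bit RGB; masks are single-band with 0 outside and 255
#' inside the ROI. PNG stores 8-bit channels, so fractional pixel values
#' (from additive noise) are rounded on write.
#'
#' @param image a `specimen_image` or an H x W x 3 array on the 0-255 scale.
#' @param path PNG file path.
#' @return Readers return the pixel array (0-255) / logical mask.
#' @export
write_image_png <- function(image, path) {
  px <- if (is.list(image)) image$pixels else image
  png::writePNG(px / 255, path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  a[, , 1:3, drop = FALSE] * 255
}

#' @rdname write_image_png
#' @param mask H x W logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a > 0.5
}

# one closed counter-clockwise ring per rectangle
rect_ring <- function(x1, x2, y1, y2) {
  list(list(c(x1, y1)), list(c(x2, y1)), list(c(x2, y2)), list(c(x1, y2)),
       list(c(x1, y1)))
}

#' Write / read species ranges as GeoJSON
#'
#' Each species becomes one MultiPolygon feature (property `species_id`)
#' whose polygons are the row-run rectangles of its pixel-union range.
#'
#' @param ranges a `range_set` from [gen_ranges()].
#' @param path output path (`.geojson`).
#' @return `read_ranges_geojson` returns a named list of multipolygons
#'   (lists of two-column vertex matrices), suitable for
#'   [rasterize_ranges()].
#' @export
write_ranges_geojson <- function(ranges, path) {
  features <- lapply(ranges, function(rg) {
    rc <- rg$rects
    polys <- lapply(seq_len(nrow(rc)), function(j) {
      ring <- rbind(c(rc$xmin[j], rc$ymin[j]), c(rc$xmax[j], rc$ymin[j]),
                    c(rc$xmax[j], rc$ymax[j]), c(rc$xmin[j], rc$ymax[j]),
                    c(rc$xmin[j], rc$ymin[j]))
      list(apply(ring, 1, function(p) p, simplify = FALSE))
    })
    list(type = "Feature",
         properties = list(species_id = rg$species_id, empty = rg$empty),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = unname(features)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ranges_geojson
#' @export
read_ranges_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(gj$features, function(f) {
    lapply(f$geometry$coordinates, function(poly) {
      ring <- poly[[1]]
      m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
      m[-nrow(m), , drop = FALSE]
    })
  })
  names(out) <- vapply(gj$features, function(f) f$properties$species_id, "")
  out
}

#' Write a data frame as CSV with a provenance comment header
#'
#' @param df data frame.
#' @param path output path.
#' @param meta named character vector written as `# key=value` lines.
#' @return `read_table_csv` returns a tibble (header lines skipped).
#' @export
write_table_csv <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(sprintf("# %s=%s", names(meta), unname(meta)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}

#' Write a presence matrix as sparse triplets
#'
#' One row per (cell, species) presence, with a provenance header.
#'
#' @param presence a `presence_grid`.
#' @param path output path.
#' @param meta named character vector for the header.
#' @export
write_presence_csv <- function(presence, path, meta = NULL) {
  idx <- which(presence$presence, arr.ind = TRUE)
  df <- data.frame(
    cell_id = presence$grid$cells$cell_id[idx[, 1]],
    species_id = presence$species_ids[idx[, 2]]
  )
  df <- df[order(df$cell_id, df$species_id), ]
  write_table_csv(df, path, meta)
}
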