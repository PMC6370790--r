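#' Equal-area analysis grid
#'
#' Lays a square grid of side `cell_size` over an extent given in a projected
#' equal-area CRS. The grid origin is snapped down to a multiple of
#' `cell_size`, so the tessellation is reproducible without a reference grid
#' file; only cells whose intersection with the extent has positive area are
#' retained. Cells are half-open `[x, x + cell_size) x [y, y + cell_size)`.
#'
#' @param extent either `c(xmin, xmax, ymin, ymax)` in metres, or a
#'   two-column polygon vertex matrix.
#' @param cell_size cell side in metres (50 km by default, the resolution of
#'   continental butterfly atlas data).
#' @param crs CRS label, e.g. `"102008"` (North America Albers) or
#'   `"102013"` (Europe Albers).
#' @return Object of class `ea_grid`: `cell_size`, `crs`, `origin`, and
#'   `cells`, a tibble with `cell_id`, `row`, `col`, `xmin`, `ymin`,
#'   `xcenter`, `ycenter`.
#' @export
make_grid <- function(extent, cell_size = 50000, crs = "102008") {
  if (cell_size <= 0) stop("`cell_size` must be positive")
  poly <- NULL
  if (is.matrix(extent)) {
    poly <- extent
    bb <- apply(poly, 2, range)
    extent <- c(bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2])
  }
  x0 <- cell_size * floor(extent[1] / cell_size)
  y0 <- cell_size * floor(extent[3] / cell_size)
  # integer-multiple lattice; the area tolerance kills floating-point
  # slivers without dropping genuine overlaps
  cols <- x0 + cell_size * 0:floor((extent[2] - x0) / cell_size + 1e-9)
  rows <- y0 + cell_size * 0:floor((extent[4] - y0) / cell_size + 1e-9)
  area_tol <- cell_size^2 * 1e-12
  cand <- expand.grid(col = seq_along(cols), row = seq_along(rows))
  cxmin <- cols[cand$col]; cymin <- rows[cand$row]
  keep <- if (is.null(poly)) {
    (pmin(extent[2], cxmin + cell_size) - pmax(extent[1], cxmin)) *
      (pmin(extent[4], cymin + cell_size) - pmax(extent[3], cymin)) > area_tol &
      pmin(extent[2], cxmin + cell_size) - pmax(extent[1], cxmin) > 0 &
      pmin(extent[4], cymin + cell_size) - pmax(extent[3], cymin) > 0
  } else {
    vapply(seq_len(nrow(cand)), function(i) {
      polygon_rect_overlap(poly, cxmin[i], cxmin[i] + cell_size,
                           cymin[i], cymin[i] + cell_size) > area_tol
    }, logical(1))
  }
  cells <- tibble::tibble(
    cell_id = seq_len(sum(keep)),
    row = cand$row[keep], col = cand$col[keep],
    xmin = cxmin[keep], ymin = cymin[keep],
    xcenter = cxmin[keep] + cell_size / 2,
    ycenter = cymin[keep] + cell_size / 2
  )
  structure(list(cell_size = cell_size, crs = crs, origin = c(x0, y0),
                 cells = cells),
            class = "ea_grid")
}

#' @export
print.ea_grid <- function(x, ...) {
  cat(sprintf("<ea_grid> %d cells of %g km, crs %s, origin (%g, %g)\n",
              nrow(x$cells), x$cell_size / 1000, x$crs,
              x$origin[1], x$origin[2]))
  invisible(x)
}

# light repair + validation of a polygon vertex matrix; `id` names the
# offending species in error messages
sanitize_polygon <- function(poly, id) {
  poly <- as.matrix(poly)
  poly <- poly[stats::complete.cases(poly) & is.finite(poly[, 1]) &
                 is.finite(poly[, 2]), , drop = FALSE]
  if (nrow(poly) > 1) {
    dup <- c(FALSE, rowSums(abs(diff(poly))) == 0)
    poly <- poly[!dup, , drop = FALSE]
  }
  if (nrow(poly) < 3)
    stop(sprintf("invalid range geometry for species %s (fewer than 3 usable vertices)", id))
  poly
}

#' Rasterize species range polygons onto a grid
#'
#' A species is present in a cell iff its range overlaps the cell with
#' positive area -- touching a cell only along an edge does not count. This
#' any-overlap rule (rather than centroid-in-polygon) matches the
#' over-covering character of expert contour maps; atlas-style data at the
#' grid's own resolution are unaffected by the choice.
#'
#' @param ranges a `range_set` from [gen_ranges()], or a named list whose
#'   elements are either `species_range` objects, polygon vertex matrices,
#'   or lists of polygon matrices (multipolygons).
#' @param grid an [make_grid()] grid.
#' @param complex_map optional data frame (`species_id`, `complex_id`):
#'   member columns are unioned into a single presence column per complex.
#' @return Object of class `presence_grid`: `grid`, `species_ids`,
#'   `presence` (cells x species logical matrix), `richness` (per-cell
#'   species count); species with no occupied cell are listed in
#'   `empty_species`.
#' @export
rasterize_ranges <- function(ranges, grid, complex_map = NULL) {
  stopifnot(inherits(grid, "ea_grid"))
  cs <- grid$cell_size
  cells <- grid$cells
  ids <- names(ranges)
  if (is.null(ids)) ids <- vapply(ranges, function(r) r$species_id, "")

  pres <- matrix(FALSE, nrow(cells), length(ranges),
                 dimnames = list(NULL, ids))
  for (k in seq_along(ranges)) {
    rg <- ranges[[k]]
    if (inherits(rg, "species_range")) {
      rc <- rg$rects
      for (j in seq_len(nrow(rc))) {
        hit <- pmin(rc$xmax[j], cells$xmin + cs) - pmax(rc$xmin[j], cells$xmin) > 0 &
          pmin(rc$ymax[j], cells$ymin + cs) - pmax(rc$ymin[j], cells$ymin) > 0
        pres[hit, k] <- TRUE
      }
    } else {
      polys <- if (is.matrix(rg)) list(rg) else if (is.list(rg) && !is.null(rg$polygon))
        list(rg$polygon) else rg
      for (poly in polys) {
        poly <- sanitize_polygon(poly, ids[k])
        bb <- apply(poly, 2, range)
        cand <- which(cells$xmin + cs > bb[1, 1] & cells$xmin < bb[2, 1] &
                        cells$ymin + cs > bb[1, 2] & cells$ymin < bb[2, 2])
        for (i in cand) {
          if (!pres[i, k] &&
              polygon_rect_overlap(poly, cells$xmin[i], cells$xmin[i] + cs,
                                   cells$ymin[i], cells$ymin[i] + cs) > 0)
            pres[i, k] <- TRUE
        }
      }
    }
  }

  if (!is.null(complex_map)) {
    for (cx in unique(complex_map$complex_id)) {
      mem <- complex_map$species_id[complex_map$complex_id == cx]
      mem <- intersect(mem, colnames(pres))
      if (length(mem) == 0) next
      merged <- apply(pres[, mem, drop = FALSE], 1, any)
      pres <- pres[, setdiff(colnames(pres), mem), drop = FALSE]
      pres <- cbind(pres, merged)
      colnames(pres)[ncol(pres)] <- cx
    }
  }

  structure(list(grid = grid, species_ids = colnames(pres), presence = pres,
                 richness = rowSums(pres),
                 empty_species = colnames(pres)[colSums(pres) == 0]),
            class = "presence_grid")
}

#' @export
print.presence_grid <- function(x, ...) {
  cat(sprintf("<presence_grid> %d cells x %d species; richness %d-%d; %d empty species\n",
              nrow(x$presence), ncol(x$presence), min(x$richness),
              max(x$richness), length(x$empty_species)))
  invisible(x)
}

#' Assemblage mean colour lightness per grid cell
#'
#' For each grid cell, the unweighted mean lightness (requested side) of all
#' species present in the cell, restricted to `family_scope`. Cells holding
#' fewer than `min_richness` in-scope species are excluded to stabilise the
#' estimate (the number excluded is reported as an attribute).
#'
#' @param presence a [rasterize_ranges()] result.
#' @param traits trait tibble with `species_id`, `family` and the lightness
#'   columns; every in-scope species present somewhere must have a trait.
#' @param side `"dorsal"` or `"ventral"`.
#' @param family_scope a single family name, or `"all"`.
#' @param min_richness minimum in-scope species per retained cell.
#' @return Tibble `cell_id`, `side`, `family_scope`, `mean_lightness`,
#'   `n_species`, with attribute `n_excluded`.
#' @export
assemblage_mean <- function(presence, traits, side = c("dorsal", "ventral"),
                            family_scope = "all", min_richness = 5) {
  side <- match.arg(side)
  stopifnot(inherits(presence, "presence_grid"))
  ids <- presence$species_ids
  if (family_scope != "all") {
    fam <- traits$family[match(ids, traits$species_id)]
    ids <- ids[!is.na(fam) & fam == family_scope]
  }
  miss <- setdiff(ids[colSums(presence$presence[, ids, drop = FALSE]) > 0],
                  traits$species_id)
  if (length(miss))
    stop("species present but traitless: ", paste(miss, collapse = ", "))
  sub <- presence$presence[, intersect(ids, traits$species_id), drop = FALSE]
  lv <- traits[[paste0("lightness_", side)]][
    match(colnames(sub), traits$species_id)]
  n_sp <- as.integer(rowSums(sub))
  msum <- as.numeric(sub %*% lv)
  keep <- n_sp >= min_richness
  out <- tibble::tibble(
    cell_id = presence$grid$cells$cell_id[keep],
    side = side, family_scope = family_scope,
    mean_lightness = msum[keep] / n_sp[keep],
    n_species = n_sp[keep]
  )
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Quantile bin classification
#'
#' Assigns each value to one of `k` bins delimited by the `1/k, ..., (k-1)/k`
#' sample quantiles, as used for choropleth mapping. The lowest bin is closed
#' on the left; values equal to a bin edge fall in the lower bin.
#'
#' @param values numeric vector (no NAs).
#' @param k number of bins, at least 2.
#' @return Integer bin index per value (1 = lowest). When all values are
#'   equal a single bin is returned with a warning.
#' @export
quantile_bins <- function(values, k) {
  if (length(values) == 0) stop("`values` is empty")
  if (k < 2) stop("`k` must be at least 2")
  if (anyNA(values)) stop("`values` contains NA")
  if (max(values) == min(values)) {
    warning("all values equal: single bin")
    return(rep(1L, length(values)))
  }
  qs <- unique(stats::quantile(values, probs = seq_len(k - 1) / k,
                               names = FALSE, type = 7))
  as.integer(cut(values, breaks = c(-Inf, qs, Inf), right = TRUE))
}
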