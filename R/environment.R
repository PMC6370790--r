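#' Annual mean of a stack of raster layers
#'
#' Per-pixel unweighted mean across all layers of a monthly (or
#' hourly-within-month, pre-pooled) climate stack. Months are weighted
#' equally. No-data pixels propagate: a pixel missing in any layer is
#' missing in the mean.
#'
#' @param layers list of `clim_raster` layers with identical geometry.
#' @return A `clim_raster` of the per-pixel mean.
#' @export
annual_mean <- function(layers) {
  if (length(layers) < 1) stop("need at least one layer")
  ref <- layers[[1]]
  for (l in layers[-1])
    if (!raster_same_geometry(ref, l)) stop("raster layers differ in geometry")
  acc <- Reduce(`+`, lapply(layers, `[[`, "values"))
  out <- ref
  out$values <- acc / length(layers)
  out
}

#' Aggregate a raster to grid-cell means
#'
#' Area-weighted mean of the raster pixels intersecting each grid cell
#' (weights proportional to the pixel-cell overlap area, so the result is
#' robust to resolution mismatches). No-data pixels are dropped from the
#' weighted mean; cells covered by no valid pixel are returned as `NA`,
#' never silently as zero.
#'
#' @param raster a `clim_raster`; its CRS label must match the grid's
#'   (no reprojection is performed).
#' @param grid an [make_grid()] grid.
#' @return Numeric vector of cell values, aligned with `grid$cells`.
#' @export
aggregate_to_grid <- function(raster, grid) {
  stopifnot(inherits(raster, "clim_raster"), inherits(grid, "ea_grid"))
  if (!identical(as.character(raster$crs), as.character(grid$crs)))
    stop(sprintf("raster CRS (%s) does not match grid CRS (%s); reproject first",
                 raster$crs, grid$crs))
  res <- raster$res
  v <- raster$values
  nr <- nrow(v); ncol_r <- ncol(v)
  rx0 <- raster$xmin; rymax <- raster_ymax(raster)
  cs <- grid$cell_size
  cells <- grid$cells

  # pixel j spans x in [rx0+(j-1)res, rx0+j*res]; row i spans
  # y in [rymax - i*res, rymax - (i-1)*res]
  out <- rep(NA_real_, nrow(cells))
  any_overlap <- FALSE
  for (ci in seq_len(nrow(cells))) {
    x1 <- cells$xmin[ci]; x2 <- x1 + cs
    y1 <- cells$ymin[ci]; y2 <- y1 + cs
    j1 <- max(1L, floor((x1 - rx0) / res) + 1L)
    j2 <- min(ncol_r, ceiling((x2 - rx0) / res))
    i1 <- max(1L, floor((rymax - y2) / res) + 1L)
    i2 <- min(nr, ceiling((rymax - y1) / res))
    if (j1 > j2 || i1 > i2) next
    jj <- j1:j2; ii <- i1:i2
    wx <- pmin(x2, rx0 + jj * res) - pmax(x1, rx0 + (jj - 1) * res)
    wy <- pmin(y2, rymax - (ii - 1) * res) - pmax(y1, rymax - ii * res)
    w <- outer(wy, wx)
    w[w < 0] <- 0
    vals <- v[ii, jj, drop = FALSE]
    ok <- is.finite(vals) & w > 0
    if (!any(ok)) next
    any_overlap <- TRUE
    out[ci] <- sum(vals[ok] * w[ok]) / sum(w[ok])
  }
  if (!any_overlap) stop("raster and grid do not overlap spatially")
  out
}

#' Per-cell annual climate summary
#'
#' Convenience wrapper: computes [annual_mean()] for each variable's monthly
#' stack and aggregates it to the grid, yielding the per-cell explanatory
#' variables of the analysis.
#'
#' @param monthly named list with elements `INS`, `TMP`, `HUM`, each a list
#'   of monthly `clim_raster` layers (as produced by [gen_climate()]).
#' @param grid an [make_grid()] grid.
#' @return Tibble `cell_id`, `INS` (W m^-2), `TMP` (degrees C), `HUM` (%),
#'   `missing` (no raster coverage).
#' @export
cell_environment <- function(monthly, grid) {
  stopifnot(all(c("INS", "TMP", "HUM") %in% names(monthly)))
  vals <- lapply(monthly[c("INS", "TMP", "HUM")], function(stack)
    aggregate_to_grid(annual_mean(stack), grid))
  tibble::tibble(
    cell_id = grid$cells$cell_id,
    INS = vals$INS, TMP = vals$TMP, HUM = vals$HUM,
    missing = !is.finite(vals$INS) | !is.finite(vals$TMP) | !is.finite(vals$HUM)
  )
}
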