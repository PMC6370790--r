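#' Configuration for a synthetic study region
#'
#' Bundles every parameter of the synthetic world: the projected extent and
#' raster resolution of the climate fields, the species pool and its
#' lightness-temperature coupling, and the specimen-rendering noise model.
#' Identical configurations (including `seed`) generate bit-identical worlds.
#'
#' @param seed integer seed; every stochastic component derives its own
#'   sub-seed deterministically from it.
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in metres of a projected
#'   equal-area CRS.
#' @param raster_resolution climate pixel size, metres.
#' @param n_species number of species in the pool.
#' @param families named numeric vector of family proportions (must sum to 1).
#' @param lightness_range `c(low, high)` within \[0, 255\]; true dorsal
#'   lightness is drawn uniformly from this interval.
#' @param beta coupling of the thermal optimum to true dorsal lightness,
#'   degrees C per lightness unit (positive: lighter species have warmer
#'   optima, the thermal-melanism direction).
#' @param niche_width thermal niche breadth, degrees C; a species occupies
#'   every pixel whose annual temperature is within `niche_width / 2` of its
#'   optimum.
#' @param noise_sd_climate standard deviation (degrees C) of the smooth
#'   spatially correlated noise added to the temperature field; insolation
#'   and humidity noise scale with it.
#' @param pixel_noise_sd standard deviation of per-pixel grayscale noise in
#'   rendered specimens (0-255 units).
#' @param dorsal_ventral_offset additive lightness offset of the ventral
#'   side (positive = ventral lighter, the countershading direction).
#' @param tmp_south,tmp_north annual temperature (degrees C) at the southern
#'   and northern edge of the extent; the north-south gradient is linear.
#' @param opt_noise_sd standard deviation (degrees C) of the noise on the
#'   thermal optimum around its lightness-predicted value.
#' @param response shape of the lightness-temperature coupling: `"linear"`
#'   (optimum affine in lightness), or `"hump"` / `"U"` (lightness a concave /
#'   convex quadratic in the optimum), used to probe shape classification.
#' @param morph_delta half-spread of morph lightness around the species mean
#'   for polymorphic species (the two morphs sit at +/- `morph_delta`).
#' @param image_size `c(height, width)` of rendered specimen images, pixels.
#' @param seasonal_amplitude amplitude of the zero-mean monthly sinusoid
#'   added to the annual temperature field (degrees C); insolation and
#'   humidity use proportional amplitudes.
#' @param crs CRS label attached to all generated spatial objects.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         extent = c(0, 2e6, 0, 2e6),
                         raster_resolution = 25000,
                         n_species = 150,
                         families = c(Lycaenidae = 0.30, Nymphalidae = 0.40,
                                      Papilionidae = 0.10, Pieridae = 0.20),
                         lightness_range = c(30, 230),
                         beta = 0.12,
                         niche_width = 10,
                         noise_sd_climate = 1,
                         pixel_noise_sd = 3,
                         dorsal_ventral_offset = 30,
                         tmp_south = 25,
                         tmp_north = -5,
                         opt_noise_sd = 2,
                         response = c("linear", "hump", "U"),
                         morph_delta = 5,
                         image_size = c(256, 384),
                         seasonal_amplitude = 8,
                         crs = "synthetic-albers") {
  response <- match.arg(response)
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3])
  if (raster_resolution <= 0) stop("`raster_resolution` must be positive")
  if (n_species < 1) stop("`n_species` must be >= 1")
  if (niche_width <= 0) stop("`niche_width` must be positive")
  if (lightness_range[1] < 0 || lightness_range[2] > 255 ||
      lightness_range[1] >= lightness_range[2])
    stop("`lightness_range` must be an increasing interval within [0, 255]")
  if (abs(sum(families) - 1) > 1e-8) stop("family proportions must sum to 1")
  structure(as.list(environment()), class = "synth_config")
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 7919) %% 2147483629 + 1)
}

# separable Gaussian smoothing of a matrix (edge-renormalised)
smooth_field <- function(m, sigma = 3) {
  wmat <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    w <- exp(-d^2 / (2 * sigma^2))
    w / rowSums(w)
  }
  wmat(nrow(m)) %*% m %*% t(wmat(ncol(m)))
}

# smooth spatially correlated field, standardised to unit sd
correlated_noise <- function(nr, nc, sigma = 3) {
  z <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
  s <- stats::sd(z)
  if (s > 0) z / s else z
}

#' Generate synthetic climate rasters
#'
#' Builds annual fields of air temperature (TMP, degrees C), solar insolation
#' (INS, W m^-2) and relative humidity (HUM, %) on the configured extent, plus
#' twelve "monthly" layers per variable whose per-pixel mean equals the annual
#' field exactly (annual field + a zero-mean seasonal sinusoid), so that
#' annual averaging downstream is exercised non-trivially.
#'
#' TMP is a linear north-south gradient plus smooth correlated noise; INS is
#' a positive affine function of TMP plus independent noise; HUM is a
#' negative affine function of TMP plus independent noise.
#'
#' @param config a [synth_config()].
#' @return A list with elements `annual` (named list of `clim_raster`:
#'   `INS`, `TMP`, `HUM`) and `monthly` (named list of 12-element raster
#'   lists).
#' @export
gen_climate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  res <- config$raster_resolution
  nc <- max(1L, round((config$extent[2] - config$extent[1]) / res))
  nr <- max(1L, round((config$extent[4] - config$extent[3]) / res))

  set.seed(derive_seed(config$seed, 1))
  ycen <- config$extent[4] - (seq_len(nr) - 0.5) * res   # row 1 = north
  frac_north <- (ycen - config$extent[3]) / (config$extent[4] - config$extent[3])
  tmp_grad <- config$tmp_south + (config$tmp_north - config$tmp_south) * frac_north
  tmp <- matrix(tmp_grad, nr, nc)
  nsd <- config$noise_sd_climate
  if (nsd > 0) tmp <- tmp + nsd * correlated_noise(nr, nc)

  ins <- 180 + 6 * tmp
  hum <- 70 - 1.5 * tmp
  if (nsd > 0) {
    ins <- ins + 4 * nsd * correlated_noise(nr, nc)
    hum <- hum + 2 * nsd * correlated_noise(nr, nc)
  }
  hum <- pmin(pmax(hum, 0), 100)

  mk <- function(v, units) clim_raster(v, config$extent[1], config$extent[3],
                                       res, config$crs, units)
  annual <- list(INS = mk(ins, "W m-2"), TMP = mk(tmp, "degC"),
                 HUM = mk(hum, "%"))
  amp <- c(INS = 6 * config$seasonal_amplitude, TMP = config$seasonal_amplitude,
           HUM = 0.5 * config$seasonal_amplitude)
  monthly <- lapply(names(annual), function(v) {
    lapply(1:12, function(m) {
      r <- annual[[v]]
      r$values <- r$values + amp[[v]] * sin(2 * pi * m / 12)
      r
    })
  })
  names(monthly) <- names(annual)
  list(annual = annual, monthly = monthly)
}

#' Generate a species pool with known lightness-climate coupling
#'
#' Draws true dorsal lightness uniformly from the configured range, sets the
#' ventral side by the countershading offset (clipped to \[0, 255\]), assigns
#' families by the configured proportions, and couples each species' thermal
#' optimum to its lightness. Under `response = "linear"` the optimum is
#' `mu_T + beta * (dorsal - midrange) + N(0, opt_noise_sd)` with `mu_T` the
#' midpoint of the configured temperature span. Under `"hump"`/`"U"` the
#' optimum is drawn uniformly over the temperature span and lightness is a
#' concave/convex quadratic in the optimum plus noise, giving a known
#' quadratic assemblage-level response.
#'
#' @param config a [synth_config()].
#' @return A tibble with one row per species: `species_id`, `family`, `sex`
#'   (`"monomorphic"` or `"female"`), `n_morphs`,
#'   `true_lightness_dorsal`, `true_lightness_ventral`, `thermal_optimum`.
#' @export
gen_species_pool <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, 2))
  n <- config$n_species
  lo <- config$lightness_range[1]; hi <- config$lightness_range[2]
  mu_t <- (config$tmp_south + config$tmp_north) / 2
  halfspan <- abs(config$tmp_south - config$tmp_north) / 2

  fam <- sample(names(config$families), n, replace = TRUE,
                prob = config$families)
  noise <- if (config$opt_noise_sd > 0) stats::rnorm(n, 0, config$opt_noise_sd) else 0

  if (config$response == "linear") {
    dorsal <- stats::runif(n, lo, hi)
    opt <- mu_t + config$beta * (dorsal - (lo + hi) / 2) + noise
  } else {
    opt <- stats::runif(n, mu_t - halfspan, mu_t + halfspan)
    u <- ((opt - mu_t) / halfspan)^2            # in [0, 1]
    shape01 <- if (config$response == "hump") 1 - u else u
    dorsal <- pmin(pmax(lo + (hi - lo) * shape01 +
                          noise * (hi - lo) / (2 * halfspan), lo), hi)
  }
  ventral <- pmin(pmax(dorsal + config$dorsal_ventral_offset, 0), 255)

  tibble::tibble(
    species_id = sprintf("sp%03d", seq_len(n)),
    family = fam,
    sex = sample(c("monomorphic", "female"), n, replace = TRUE,
                 prob = c(0.7, 0.3)),
    n_morphs = sample(1:2, n, replace = TRUE, prob = c(0.9, 0.1)),
    true_lightness_dorsal = dorsal,
    true_lightness_ventral = ventral,
    thermal_optimum = opt
  )
}

#' Generate thermal-niche range polygons for a species pool
#'
#' A species' range is the union of all temperature-raster pixels whose
#' annual temperature lies within `niche_width / 2` of the species' thermal
#' optimum, represented as row-run rectangles in map coordinates (an exact
#' polygonization of the pixel union). Species whose optimum falls outside
#' the observed temperature span get an empty range and are flagged.
#'
#' @param pool tibble from [gen_species_pool()].
#' @param tmp_raster annual temperature `clim_raster`.
#' @param config a [synth_config()].
#' @return A list of class `range_set`; each element has `species_id`,
#'   `rects` (tibble `xmin`, `xmax`, `ymin`, `ymax`), `n_pixels` and `empty`.
#' @export
gen_ranges <- function(pool, tmp_raster, config) {
  stopifnot(inherits(tmp_raster, "clim_raster"))
  res <- tmp_raster$res
  vals <- tmp_raster$values
  nr <- nrow(vals); nc <- ncol(vals)
  ymax <- raster_ymax(tmp_raster)
  half <- config$niche_width / 2

  ranges <- lapply(seq_len(nrow(pool)), function(k) {
    opt <- pool$thermal_optimum[k]
    inn <- abs(vals - opt) <= half
    n_pix <- sum(inn)
    rects <- if (n_pix == 0) {
      tibble::tibble(xmin = numeric(0), xmax = numeric(0),
                     ymin = numeric(0), ymax = numeric(0))
    } else {
      out <- vector("list", nr)
      for (i in seq_len(nr)) {
        row <- inn[i, ]
        if (!any(row)) next
        r <- rle(row)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        keep <- r$values
        out[[i]] <- tibble::tibble(
          xmin = tmp_raster$xmin + (starts[keep] - 1) * res,
          xmax = tmp_raster$xmin + ends[keep] * res,
          ymin = ymax - i * res,
          ymax = ymax - (i - 1) * res
        )
      }
      do.call(rbind, out[!vapply(out, is.null, logical(1))])
    }
    structure(list(species_id = pool$species_id[k], rects = rects,
                   n_pixels = n_pix, empty = n_pix == 0),
              class = "species_range")
  })
  names(ranges) <- pool$species_id
  structure(ranges, class = "range_set", crs = tmp_raster$crs)
}

# butterfly landmark geometry for a given image size (rows, cols);
# coordinates are pixel units, x rightwards, y downwards (row direction)
specimen_geometry <- function(image_size) {
  h <- image_size[1]; w <- image_size[2]
  cx <- w / 2; cy <- h / 2
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  body <- cbind(cx + (w / 30) * cos(th), cy + (h / 3.4) * sin(th))
  # right forewing / hindwing quadrilaterals, mirrored for the left side
  fw <- cbind(c(cx + 8, w - 15, w - 10, cx + 13),
              cy + c(-35, -95, -60, 5) * (h / 240))
  hw <- cbind(c(cx + 8, w - 30, w - 50, cx + 6),
              cy + c(15, 75, 105, 50) * (h / 240))
  mirror <- function(p) cbind(w - p[, 1], p[, 2])
  wing <- function(poly) {
    base <- c((poly[1, 1] + poly[4, 1]) / 2, (poly[1, 2] + poly[4, 2]) / 2)
    tip <- c((poly[2, 1] + poly[3, 1]) / 2, (poly[2, 2] + poly[3, 2]) / 2)
    list(polygon = poly, base = base, tip = tip)
  }
  list(body_polygon = body,
       wings = list(fw_right = wing(fw), fw_left = wing(mirror(fw)),
                    hw_right = wing(hw), hw_left = wing(mirror(hw))))
}

# distal wing grayscale: always 60 units away from the species value
distal_value <- function(lightness) {
  ifelse(lightness <= 195, lightness + 60, lightness - 60)
}

#' Render a synthetic specimen image with its ground-truth ROI mask
#'
#' Draws a stylised butterfly (body ellipse plus four wing quadrilaterals) on
#' a white background. Pixels in the region of interest -- the body and the
#' proximal third of each wing, measured as distance along the wing's
#' base-to-tip axis -- receive the species' true grayscale lightness for the
#' requested side (identical R, G and B); the distal two thirds receive a
#' deliberately different grayscale (offset by 60 units) so that errors in
#' ROI construction are detectable. Optional clipped Gaussian pixel noise is
#' added to all drawn pixels. The exact ROI mask used is returned with the
#' image.
#'
#' @param species one-row data frame (a row of [gen_species_pool()] output).
#' @param side `"dorsal"` or `"ventral"`.
#' @param config a [synth_config()].
#' @param morph morph index (1-based); for polymorphic species morphs sit
#'   symmetrically at the species value +/- `morph_delta`, so the morph mean
#'   recovers the species value.
#' @return A list of class `specimen_image`: `pixels` (H x W x 3 numeric
#'   array, 0-255), `roi_mask` (H x W logical), `species_id`, `family`,
#'   `side`, `sex`, `morph_id`, `true_lightness`, `landmarks`.
#' @export
render_specimen <- function(species, side = c("dorsal", "ventral"),
                            config, morph = 1) {
  side <- match.arg(side)
  stopifnot(inherits(config, "synth_config"))
  h <- config$image_size[1]; w <- config$image_size[2]
  geo <- specimen_geometry(config$image_size)

  base_l <- if (side == "dorsal") species$true_lightness_dorsal else
    species$true_lightness_ventral
  n_morphs <- if ("n_morphs" %in% names(species)) species$n_morphs else 1L
  lightness <- base_l
  if (n_morphs == 2) lightness <- base_l + c(-1, 1)[morph] * config$morph_delta
  lightness <- min(max(lightness, 0), 255)

  px <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  py <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  canvas <- matrix(255, h, w)
  roi <- matrix(FALSE, h, w)
  drawn <- matrix(FALSE, h, w)

  for (wg in geo$wings) {
    inside <- polygon_pixel_mask(wg$polygon, h, w)
    drawn <- drawn | inside
    axis <- wg$tip - wg$base
    len2 <- sum(axis^2)
    if (len2 == 0) stop("degenerate wing axis")
    tfrac <- ((px - wg$base[1]) * axis[1] + (py - wg$base[2]) * axis[2]) / len2
    prox <- inside & (tfrac <= 1 / 3)
    canvas[inside] <- distal_value(lightness)
    canvas[prox] <- lightness
    roi <- roi | prox
  }
  body <- polygon_pixel_mask(geo$body_polygon, h, w)
  canvas[body] <- lightness
  roi <- roi | body
  drawn <- drawn | body

  if (config$pixel_noise_sd > 0) {
    idnum <- suppressWarnings(as.integer(gsub("\\D", "", species$species_id)))
    if (is.na(idnum)) idnum <- sum(utf8ToInt(as.character(species$species_id)))
    set.seed(derive_seed(config$seed,
                         1000L + idnum * 8L + (side == "ventral") * 2L + morph))
    canvas[drawn] <- pmin(pmax(canvas[drawn] +
                                 stats::rnorm(sum(drawn), 0, config$pixel_noise_sd),
                               0), 255)
  }

  structure(list(
    pixels = array(canvas, dim = c(h, w, 3)),
    roi_mask = roi,
    species_id = species$species_id,
    family = if ("family" %in% names(species)) species$family else NA_character_,
    side = side,
    sex = if ("sex" %in% names(species)) species$sex else "monomorphic",
    morph_id = morph,
    true_lightness = lightness,
    landmarks = geo
  ), class = "specimen_image")
}
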