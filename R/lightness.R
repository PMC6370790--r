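#' Colour lightness of a specimen image over its region of interest
#'
#' Colour lightness is the average of the red, green and blue channel values
#' over the considered area (the ROI mask), on the 0 (black) to 255 (white)
#' scale. The grand mean over all channel values equals the mean of the
#' per-channel means because the three channels share the mask.
#'
#' @param image a `specimen_image`, or any list with `pixels` (H x W x 3
#'   numeric array, 0-255) and `roi_mask` (H x W logical).
#' @param roi_mask optional mask overriding `image$roi_mask`.
#' @return Scalar lightness in \[0, 255\].
#' @export
compute_lightness <- function(image, roi_mask = NULL) {
  px <- image$pixels
  mask <- if (is.null(roi_mask)) image$roi_mask else roi_mask
  if (is.null(px) || is.null(mask)) stop("image must carry `pixels` and `roi_mask`")
  if (!identical(dim(px)[1:2], dim(mask))) stop("mask and image dimensions differ")
  if (!any(mask)) stop("empty ROI mask: specimen unusable")
  if (min(px) < 0 || max(px) > 255) stop("pixel values outside [0, 255]")
  mean(c(px[, , 1][mask], px[, , 2][mask], px[, , 3][mask]))
}

#' Build a body-plus-proximal-wing ROI mask from landmarked polygons
#'
#' The region of interest is the body polygon united with, for each wing,
#' the wing pixels whose orthogonal projection onto the wing's base-to-tip
#' axis lies in the proximal third of that axis (the third closest to the
#' body). Pixel membership is decided at pixel centres.
#'
#' @param body_polygon two-column vertex matrix in pixel coordinates.
#' @param wings list of wings, each a list with `polygon` (vertex matrix),
#'   `base` and `tip` (length-2 numeric, the wing-body junction and the wing
#'   tip).
#' @param image_shape `c(height, width)` in pixels.
#' @return H x W logical matrix.
#' @export
build_roi_mask <- function(body_polygon, wings, image_shape) {
  h <- image_shape[1]; w <- image_shape[2]
  px <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  py <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  mask <- polygon_pixel_mask(body_polygon, h, w)
  for (wg in wings) {
    axis <- wg$tip - wg$base
    len2 <- sum(axis^2)
    if (len2 == 0) stop("degenerate wing: base and tip coincide")
    tfrac <- ((px - wg$base[1]) * axis[1] + (py - wg$base[2]) * axis[2]) / len2
    mask <- mask | (polygon_pixel_mask(wg$polygon, h, w) & (tfrac <= 1 / 3))
  }
  mask
}

#' Species-level trait from a set of specimen images
#'
#' Applies the sex policy (by default only images tagged `female` or
#' `monomorphic` are used, excluding effects of sexual dichromatism), averages
#' lightness within each morph and then unweighted across morphs separately
#' for the dorsal and the ventral side, and requires both sides to be
#' represented: species missing either side are returned as an exclusion
#' record rather than a trait.
#'
#' @param images list of `specimen_image` objects sharing one `species_id`.
#' @param sex_policy character vector of admissible sex tags.
#' @return A one-row tibble (`species_id`, `family`, `lightness_dorsal`,
#'   `lightness_ventral`, `n_images_dorsal`, `n_images_ventral`,
#'   `complex_id = NA`) or, when a side is missing, a list of class
#'   `species_exclusion` with the reason.
#' @export
species_lightness <- function(images, sex_policy = c("female", "monomorphic")) {
  sid <- unique(vapply(images, `[[`, "", "species_id"))
  if (length(sid) != 1) stop("images must share one species_id")
  fams <- unique(stats::na.omit(vapply(images, `[[`, "", "family")))
  if (length(fams) > 1)
    stop(sprintf("conflicting family labels for %s: %s", sid,
                 paste(fams, collapse = ", ")))
  keep <- vapply(images, function(im) im$sex %in% sex_policy, logical(1))
  images <- images[keep]

  side_mean <- function(side) {
    imgs <- Filter(function(im) im$side == side, images)
    if (length(imgs) == 0) return(list(value = NA_real_, n = 0L))
    l <- vapply(imgs, compute_lightness, numeric(1))
    morph <- vapply(imgs, function(im) as.character(im$morph_id), "")
    list(value = mean(tapply(l, morph, mean)), n = length(imgs))
  }
  d <- side_mean("dorsal"); v <- side_mean("ventral")
  if (d$n == 0 || v$n == 0) {
    reason <- if (d$n == 0 && v$n == 0) "no images pass sex policy"
      else if (d$n == 0) "missing dorsal" else "missing ventral"
    return(structure(list(species_id = sid, reason = reason),
                     class = "species_exclusion"))
  }
  tibble::tibble(
    species_id = sid,
    family = if (length(fams)) fams else NA_character_,
    lightness_dorsal = d$value, lightness_ventral = v$value,
    n_images_dorsal = d$n, n_images_ventral = v$n,
    complex_id = NA_character_
  )
}

#' Collapse species complexes to single analysis units
#'
#' Species with unstable taxonomic status are grouped into complexes; each
#' complex becomes one trait row whose dorsal and ventral lightness are the
#' unweighted means of its members. Species not in the map pass through
#' unchanged. (Downstream, a complex's range is the union of member ranges;
#' see [rasterize_ranges()] which accepts the same map.)
#'
#' @param traits tibble of species traits (as from [species_lightness()]).
#' @param complex_map data frame with columns `species_id`, `complex_id`;
#'   each member belongs to exactly one complex.
#' @return Trait tibble with member rows replaced by complex rows (the
#'   complex id becomes the `species_id`).
#' @export
complex_average <- function(traits, complex_map) {
  if (anyDuplicated(complex_map$species_id))
    stop("a species is assigned to more than one complex")
  cm <- data.frame(species_id = complex_map$species_id,
                   .complex = complex_map$complex_id)
  members <- traits$species_id %in% cm$species_id
  rest <- traits[!members, , drop = FALSE]
  mem <- merge(traits[members, , drop = FALSE], cm, by = "species_id")
  if (nrow(mem) == 0) return(traits)
  rows <- lapply(split(mem, mem$.complex), function(g) {
    if (length(unique(g$family)) > 1)
      stop(sprintf("complex %s mixes families: %s", g$.complex[1],
                   paste(unique(g$family), collapse = ", ")))
    tibble::tibble(
      species_id = g$.complex[1],
      family = g$family[1],
      lightness_dorsal = mean(g$lightness_dorsal),
      lightness_ventral = mean(g$lightness_ventral),
      n_images_dorsal = sum(g$n_images_dorsal),
      n_images_ventral = sum(g$n_images_ventral),
      complex_id = g$.complex[1]
    )
  })
  out <- rbind(rest, do.call(rbind, rows))
  tibble::as_tibble(out[order(out$species_id), , drop = FALSE])
}

#' Cross-validate lightness scores from two independent sources
#'
#' For species scored in both sources (e.g. two continental image datasets),
#' regresses source-b lightness on source-a lightness by OLS. Close agreement
#' (slope near 1, high r-squared) validates combining the sources.
#'
#' @param traits_a,traits_b trait tibbles with `species_id` and the lightness
#'   columns.
#' @param side which side to compare (`"dorsal"` or `"ventral"`).
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
cross_source_validation <- function(traits_a, traits_b,
                                    side = c("dorsal", "ventral")) {
  side <- match.arg(side)
  col <- paste0("lightness_", side)
  shared <- intersect(traits_a$species_id, traits_b$species_id)
  if (length(shared) < 3) stop("fewer than 3 shared species")
  a <- traits_a[[col]][match(shared, traits_a$species_id)]
  b <- traits_b[[col]][match(shared, traits_b$species_id)]
  fit <- stats::lm(b ~ a)
  sm <- suppressWarnings(summary(fit))  # exact agreement warns harmlessly
  p <- if (is.null(sm$fstatistic)) NA_real_ else
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared, p_value = p, n = length(shared))
}
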