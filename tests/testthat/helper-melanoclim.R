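# small fast synthetic world for unit tests
tiny_config <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(seed = seed, extent = c(0, 1e6, 0, 1e6),
                   raster_resolution = 50000, n_species = 60,
                   image_size = c(128, 192))
  do.call(synth_config, utils::modifyList(defaults, args))
}

# brute-force lightness oracle: per-pixel double loop over all channels
brute_lightness <- function(pixels, mask) {
  acc <- 0; n <- 0
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j]) {
        acc <- acc + pixels[i, j, 1] + pixels[i, j, 2] + pixels[i, j, 3]
        n <- n + 3
      }
    }
  }
  acc / n
}

# build a specimen_image from a plain grayscale matrix
as_specimen <- function(gray, mask, species_id = "spX", side = "dorsal",
                        sex = "monomorphic", morph_id = 1, family = "Pieridae") {
  structure(list(pixels = array(rep(gray, 3), dim = c(dim(gray), 3)),
                 roi_mask = mask, species_id = species_id, side = side,
                 sex = sex, morph_id = morph_id, family = family),
            class = "specimen_image")
}

# dense-sampling presence oracle: a species occupies a cell iff any of an
# n x n lattice of interior sample points falls inside one of its rectangles
presence_by_sampling <- function(ranges, grid, n = 25) {
  cs <- grid$cell_size
  off <- (seq_len(n) - 0.5) / n * cs
  pres <- matrix(FALSE, nrow(grid$cells), length(ranges))
  for (ci in seq_len(nrow(grid$cells))) {
    xs <- grid$cells$xmin[ci] + off
    ys <- grid$cells$ymin[ci] + off
    px <- rep(xs, times = n); py <- rep(ys, each = n)
    for (k in seq_along(ranges)) {
      rc <- ranges[[k]]$rects
      hit <- FALSE
      for (j in seq_len(nrow(rc))) {
        if (any(px > rc$xmin[j] & px < rc$xmax[j] &
                  py > rc$ymin[j] & py < rc$ymax[j])) { hit <- TRUE; break }
      }
      pres[ci, k] <- hit
    }
  }
  pres
}
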