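test_that("grid construction counts cells correctly", {
  g1 <- make_grid(c(0, 50000, 0, 50000))
  expect_equal(nrow(g1$cells), 1)
  g4 <- make_grid(c(0, 1e5, 0, 1e5))
  expect_equal(nrow(g4$cells), 4)
  # unaligned extent snaps the origin down and still covers everything
  g <- make_grid(c(20000, 120000, -30000, 60000))
  expect_equal(g$origin, c(0, -50000))
  expect_equal(nrow(g$cells), 3 * 3)
  expect_error(make_grid(c(0, 1e5, 0, 1e5), cell_size = 0), "positive")
})

test_that("polygon extents keep exactly the lattice squares they overlap", {
  # an irregular convex pentagon; oracle = dense point sampling per cell
  poly <- rbind(c(10000, 5000), c(230000, 30000), c(260000, 180000),
                c(120000, 260000), c(-20000, 140000))
  g <- make_grid(poly, cell_size = 50000)
  n <- 40
  off <- (seq_len(n) - 0.5) / n * 50000
  x0 <- 50000 * floor(min(poly[, 1]) / 50000)
  y0 <- 50000 * floor(min(poly[, 2]) / 50000)
  brute <- 0
  for (cx in seq(x0, max(poly[, 1]), by = 50000)) {
    for (cy in seq(y0, max(poly[, 2]), by = 50000)) {
      px <- rep(cx + off, times = n); py <- rep(cy + off, each = n)
      if (any(point_in_polygon(px, py, poly))) brute <- brute + 1
    }
  }
  expect_equal(nrow(g$cells), brute)
})

test_that("presence requires positive-area overlap", {
  g <- make_grid(c(0, 1.5e5, 0, 1e5))
  cover_one <- rbind(c(0, 0), c(50000, 0), c(50000, 50000), c(0, 50000))
  touch_only <- rbind(c(50000, 0), c(100000, 0), c(100000, -50000),
                      c(50000, -50000))  # shares an edge with the grid row
  pg <- rasterize_ranges(list(spA = cover_one, spB = touch_only), g)
  expect_equal(sum(pg$presence[, "spA"]), 1)
  cell_a <- which(pg$presence[, "spA"])
  expect_equal(g$cells$xmin[cell_a], 0)
  expect_equal(g$cells$ymin[cell_a], 0)
  expect_equal(sum(pg$presence[, "spB"]), 0)
  expect_true("spB" %in% pg$empty_species)
})

test_that("invalid geometries are repaired when possible, else rejected by name", {
  g <- make_grid(c(0, 1e5, 0, 1e5))
  dup_vertices <- rbind(c(0, 0), c(0, 0), c(60000, 0), c(60000, 0),
                        c(60000, 60000), c(0, 60000))
  pg <- rasterize_ranges(list(ok = dup_vertices), g)
  expect_equal(sum(pg$presence[, "ok"]), 4)
  degenerate <- rbind(c(0, 0), c(0, 0), c(NA, 5))
  expect_error(rasterize_ranges(list(bad = degenerate), g), "bad")
})

test_that("synthetic range rasterization matches the dense-sampling oracle", {
  cfg <- tiny_config(seed = 3, n_species = 25)
  clim <- gen_climate(cfg)
  pool <- gen_species_pool(cfg)
  ranges <- gen_ranges(pool, clim$annual$TMP, cfg)
  g <- make_grid(cfg$extent, 50000, cfg$crs)
  pg <- rasterize_ranges(ranges, g)
  oracle <- presence_by_sampling(ranges, g)
  expect_identical(unname(pg$presence), oracle)
  # conservation: total richness equals total occupancy
  expect_equal(sum(pg$richness), sum(colSums(pg$presence)))
})

test_that("complex ranges merge into unioned presence columns", {
  g <- make_grid(c(0, 1.5e5, 0, 5e4))
  left <- rbind(c(0, 0), c(50000, 0), c(50000, 50000), c(0, 50000))
  right <- rbind(c(100000, 0), c(150000, 0), c(150000, 50000), c(100000, 50000))
  pg <- rasterize_ranges(list(m1 = left, m2 = right), g,
                         complex_map = data.frame(species_id = c("m1", "m2"),
                                                  complex_id = "cx"))
  expect_equal(pg$species_ids, "cx")
  expect_equal(sum(pg$presence[, "cx"]), 2)
})

test_that("assemblage means and the richness filter behave as specified", {
  g <- make_grid(c(0, 5e4, 0, 5e4))
  ids <- sprintf("s%d", 1:5)
  pres <- structure(list(
    grid = g, species_ids = ids,
    presence = matrix(TRUE, 1, 5, dimnames = list(NULL, ids)),
    richness = 5, empty_species = character(0)
  ), class = "presence_grid")
  traits <- tibble::tibble(species_id = ids, family = "Pieridae",
                           lightness_dorsal = c(100, 110, 120, 130, 140),
                           lightness_ventral = c(100, 110, 120, 130, 140) + 10)
  a <- assemblage_mean(pres, traits, "dorsal", "all", min_richness = 5)
  expect_equal(a$mean_lightness, 120)
  expect_equal(a$n_species, 5L)

  # a 4-species cell is excluded at the default threshold
  pres$presence[1, 5] <- FALSE
  a4 <- assemblage_mean(pres, traits, "dorsal", "all", min_richness = 5)
  expect_equal(nrow(a4), 0)
  expect_equal(attr(a4, "n_excluded"), 1)

  # traitless present species are an error naming the offender
  pres$presence[1, 5] <- TRUE
  expect_error(assemblage_mean(pres, traits[-5, ], "dorsal", "all", 1), "s5")
})

test_that("assemblage means match a brute-force loop on a synthetic world", {
  cfg <- tiny_config(seed = 4)
  clim <- gen_climate(cfg)
  pool <- gen_species_pool(cfg)
  ranges <- gen_ranges(pool, clim$annual$TMP, cfg)
  g <- make_grid(cfg$extent, 50000, cfg$crs)
  pg <- rasterize_ranges(ranges, g)
  traits <- tibble::tibble(species_id = pool$species_id, family = pool$family,
                           lightness_dorsal = pool$true_lightness_dorsal,
                           lightness_ventral = pool$true_lightness_ventral)
  a <- assemblage_mean(pg, traits, "dorsal", "all", min_richness = 5)
  for (r in sample(nrow(a), 10)) {
    ci <- which(g$cells$cell_id == a$cell_id[r])
    members <- pg$species_ids[pg$presence[ci, ]]
    expect_equal(a$mean_lightness[r],
                 mean(traits$lightness_dorsal[traits$species_id %in% members]))
  }
  # convexity
  expect_true(all(a$mean_lightness >= min(traits$lightness_dorsal) &
                    a$mean_lightness <= max(traits$lightness_dorsal)))
  # filter monotonicity
  kept <- vapply(1:8, function(k)
    nrow(assemblage_mean(pg, traits, "dorsal", "all", min_richness = k)),
    numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("per-family scopes nest inside the all-species mean", {
  cfg <- tiny_config(seed = 5)
  clim <- gen_climate(cfg)
  pool <- gen_species_pool(cfg)
  pg <- rasterize_ranges(gen_ranges(pool, clim$annual$TMP, cfg),
                         make_grid(cfg$extent, 50000, cfg$crs))
  traits <- tibble::tibble(species_id = pool$species_id, family = pool$family,
                           lightness_dorsal = pool$true_lightness_dorsal,
                           lightness_ventral = pool$true_lightness_ventral)
  all_m <- assemblage_mean(pg, traits, "dorsal", "all", min_richness = 1)
  fams <- unique(pool$family)
  per_fam <- lapply(fams, function(f)
    assemblage_mean(pg, traits, "dorsal", f, min_richness = 1))
  for (ci in sample(all_m$cell_id, 10)) {
    vals <- numeric(0); wts <- numeric(0)
    for (k in seq_along(fams)) {
      row <- per_fam[[k]][per_fam[[k]]$cell_id == ci, ]
      if (nrow(row)) { vals <- c(vals, row$mean_lightness); wts <- c(wts, row$n_species) }
    }
    expect_equal(all_m$mean_lightness[all_m$cell_id == ci],
                 sum(vals * wts) / sum(wts))
  }
})

test_that("quantile bins follow the sort-and-split rule with ties going down", {
  expect_equal(quantile_bins(1:10, 2), rep(1:2, each = 5))
  expect_equal(quantile_bins(1:10, 10), 1:10)

  set.seed(9)
  v <- rnorm(113)
  b <- quantile_bins(v, 7)
  qs <- quantile(v, probs = (1:6) / 7, names = FALSE)
  oracle <- vapply(v, function(x) 1L + sum(x > qs), integer(1))
  expect_identical(b, oracle)

  expect_warning(one <- quantile_bins(rep(3, 5), 4), "single bin")
  expect_equal(one, rep(1L, 5))
  expect_error(quantile_bins(numeric(0), 2), "empty")
  expect_error(quantile_bins(1:5, 1), "at least 2")
})
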