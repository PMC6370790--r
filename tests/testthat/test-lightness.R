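test_that("lightness is the RGB grand mean over the ROI", {
  mk <- function(vals, mask) {
    as_specimen(matrix(vals, nrow(mask), ncol(mask)), mask)
  }
  mask <- matrix(TRUE, 4, 4)
  expect_identical(compute_lightness(mk(255, mask)), 255)
  expect_identical(compute_lightness(mk(0, mask)), 0)

  # one ROI pixel with distinct channels: (30 + 60 + 90) / 3
  px <- array(0, dim = c(2, 2, 3))
  px[1, 1, ] <- c(30, 60, 90)
  m1 <- matrix(FALSE, 2, 2); m1[1, 1] <- TRUE
  expect_equal(compute_lightness(list(pixels = px, roi_mask = m1)), 60)

  # half black, half white
  g <- matrix(c(0, 0, 255, 255), 2, 2)
  expect_equal(compute_lightness(mk(g, mask = matrix(TRUE, 2, 2))), 127.5)
})

test_that("lightness equals the brute-force per-pixel accumulation", {
  set.seed(11)
  px <- array(sample(0:255, 50 * 50 * 3, replace = TRUE), dim = c(50, 50, 3))
  mask <- matrix(runif(50 * 50) < 0.4, 50, 50)
  mask[1, 1] <- TRUE
  img <- list(pixels = px, roi_mask = mask)
  expect_lt(abs(compute_lightness(img) - brute_lightness(px, mask)), 1e-9)
})

test_that("lightness is invariant to pixel order and errors on empty masks", {
  set.seed(12)
  px <- array(sample(0:255, 10 * 10 * 3, replace = TRUE), dim = c(10, 10, 3))
  mask <- matrix(runif(100) < 0.5, 10, 10); mask[1, 1] <- TRUE
  perm <- sample(100)
  px2 <- array(0, dim = c(10, 10, 3))
  for (ch in 1:3) px2[, , ch] <- matrix(px[, , ch][perm], 10, 10)
  mask2 <- matrix(mask[perm], 10, 10)
  expect_equal(compute_lightness(list(pixels = px, roi_mask = mask)),
               compute_lightness(list(pixels = px2, roi_mask = mask2)))
  expect_error(compute_lightness(list(pixels = px,
                                      roi_mask = matrix(FALSE, 10, 10))),
               "empty ROI")
})

test_that("an axis-aligned rectangular wing keeps its proximal third", {
  # wing = 90 x 30 rectangle, axis horizontal: expect 1/3 of its pixels
  wing <- list(polygon = rbind(c(10, 10), c(100, 10), c(100, 40), c(10, 40)),
               base = c(10, 25), tip = c(100, 25))
  body <- rbind(c(1, 1), c(2, 1), c(2, 2), c(1, 2))  # negligible
  mask <- build_roi_mask(body, list(wing), c(60, 120))
  wing_pixels <- 90 * 30
  frac <- (sum(mask) - 1) / wing_pixels  # subtract the 1-px body
  expect_lt(abs(frac - 1 / 3), 0.02)
})

test_that("degenerate wing axes are rejected", {
  wing <- list(polygon = rbind(c(1, 1), c(5, 1), c(5, 5)),
               base = c(2, 2), tip = c(2, 2))
  expect_error(build_roi_mask(rbind(c(1, 1), c(2, 1), c(2, 2)), list(wing),
                              c(10, 10)),
               "degenerate")
})

test_that("landmark-derived mask reproduces the generator's ROI pixel-for-pixel", {
  cfg <- tiny_config(pixel_noise_sd = 0)
  pool <- gen_species_pool(cfg)
  img <- render_specimen(pool[2, ], "ventral", cfg)
  mask <- build_roi_mask(img$landmarks$body_polygon, img$landmarks$wings,
                         dim(img$roi_mask))
  expect_identical(mask, img$roi_mask)
})

test_that("species trait assembly averages morphs and filters sides", {
  g <- function(val) matrix(val, 8, 8)
  m <- matrix(TRUE, 8, 8)
  d1 <- as_specimen(g(120), m, side = "dorsal")
  v1 <- as_specimen(g(150), m, side = "ventral")
  tr <- species_lightness(list(d1, v1))
  expect_equal(tr$lightness_dorsal, 120)
  expect_equal(tr$lightness_ventral, 150)

  # two dorsal morphs 100 and 140 average to 120
  d_a <- as_specimen(g(100), m, side = "dorsal", morph_id = 1)
  d_b <- as_specimen(g(140), m, side = "dorsal", morph_id = 2)
  tr2 <- species_lightness(list(d_a, d_b, v1))
  expect_equal(tr2$lightness_dorsal, 120)
  expect_equal(tr2$n_images_dorsal, 2L)

  # dorsal only: excluded with the missing-side reason
  ex <- species_lightness(list(d1))
  expect_s3_class(ex, "species_exclusion")
  expect_equal(ex$reason, "missing ventral")

  # male images are dropped by the default sex policy
  d_m <- as_specimen(g(10), m, side = "dorsal", sex = "male")
  tr3 <- species_lightness(list(d1, d_m, v1))
  expect_equal(tr3$lightness_dorsal, 120)

  # conflicting family labels are an error
  d_f <- as_specimen(g(120), m, side = "dorsal", family = "Lycaenidae")
  expect_error(species_lightness(list(d_f, v1)), "family")
})

test_that("complex averaging collapses members and keeps row arithmetic", {
  traits <- tibble::tibble(
    species_id = sprintf("s%02d", 1:40),
    family = "Nymphalidae",
    lightness_dorsal = seq(80, 158, by = 2),
    lightness_ventral = seq(110, 188, by = 2),
    n_images_dorsal = 1L, n_images_ventral = 1L,
    complex_id = NA_character_
  )
  # members s01 and s02 with dorsal 80 and 82 average to 81
  cm1 <- data.frame(species_id = c("s01", "s02"), complex_id = "cx1")
  out1 <- complex_average(traits, cm1)
  expect_equal(out1$lightness_dorsal[out1$species_id == "cx1"], 81)
  expect_equal(nrow(out1), 39)

  # singleton complex is the member itself
  cm2 <- data.frame(species_id = "s05", complex_id = "solo")
  out2 <- complex_average(traits, cm2)
  expect_equal(out2$lightness_dorsal[out2$species_id == "solo"],
               traits$lightness_dorsal[traits$species_id == "s05"])

  # 34 members grouped into 13 complexes: 21 fewer rows
  cm3 <- data.frame(
    species_id = sprintf("s%02d", 1:34),
    complex_id = paste0("cx", c(rep(1:8, each = 3), rep(9:13, each = 2)))
  )
  out3 <- complex_average(traits, cm3)
  expect_equal(nrow(traits) - nrow(out3), 21)

  # complexes must not mix families
  traits2 <- traits; traits2$family[2] <- "Pieridae"
  expect_error(complex_average(traits2, cm1), "mixes families")
})

test_that("averaging never leaves the convex hull of its inputs", {
  set.seed(5)
  traits <- tibble::tibble(
    species_id = sprintf("s%02d", 1:20), family = "Pieridae",
    lightness_dorsal = runif(20, 0, 255),
    lightness_ventral = runif(20, 0, 255),
    n_images_dorsal = 1L, n_images_ventral = 1L, complex_id = NA_character_
  )
  cm <- data.frame(species_id = traits$species_id,
                   complex_id = rep(c("a", "b", "c", "d"), each = 5))
  out <- complex_average(traits, cm)
  expect_true(all(out$lightness_dorsal >= min(traits$lightness_dorsal) &
                    out$lightness_dorsal <= max(traits$lightness_dorsal)))
  expect_true(all(out$lightness_dorsal >= 0 & out$lightness_dorsal <= 255))
})

test_that("cross-source validation matches the closed-form OLS solution", {
  base <- tibble::tibble(
    species_id = sprintf("s%02d", 1:16), family = "Pieridae",
    lightness_dorsal = seq(40, 220, length.out = 16),
    lightness_ventral = seq(70, 250, length.out = 16)
  )
  # identical sources: slope 1, r2 1
  v0 <- cross_source_validation(base, base)
  expect_equal(v0$slope, 1)
  expect_equal(v0$r_squared, 1)
  expect_equal(v0$n, 16)

  # constant shift: slope still 1
  shifted <- base
  shifted$lightness_dorsal <- shifted$lightness_dorsal + 12
  expect_equal(cross_source_validation(base, shifted)$slope, 1)

  # noisy second source: closed-form OLS on the same numbers
  set.seed(21)
  noisy <- base
  noisy$lightness_dorsal <- base$lightness_dorsal + rnorm(16, 0, 5)
  v <- cross_source_validation(base, noisy)
  a <- base$lightness_dorsal; b <- noisy$lightness_dorsal
  slope_cf <- sum((a - mean(a)) * (b - mean(b))) / sum((a - mean(a))^2)
  expect_equal(v$slope, slope_cf)
  expect_equal(v$r_squared, cor(a, b)^2)

  expect_error(cross_source_validation(base[1:2, ], base), "3 shared")
})
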