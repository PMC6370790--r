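# rolling polynomial hash of the deparsed config; provenance tag for outputs
# (the output directory is not part of the analysis identity)
config_hash <- function(x) {
  x$out_dir <- NULL
  s <- paste(deparse(x, control = "all"), collapse = "")
  h <- 7
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%x", h)
}

#' Configuration for an end-to-end synthetic two-continent run
#'
#' Bundles two [synth_config()] worlds (continent "A", a large one, and
#' continent "B", a smaller one, mirroring the North America / Europe
#' asymmetry) with the analysis settings. All sub-seeds derive from `seed`.
#'
#' @param seed master seed.
#' @param continents optional named list of `synth_config` objects; when
#'   `NULL` the default two-continent design is built from `seed`.
#' @param cell_size analysis grid cell side, metres.
#' @param min_richness minimum species per retained cell.
#' @param alpha,delta_threshold shape-model settings (see
#'   [fit_shape_models()]).
#' @param k_bins quantile bins for choropleth maps.
#' @param use_images extract traits from rendered specimen images (`TRUE`,
#'   the full protocol) or read them from the generator's ground truth
#'   (`FALSE`, faster; useful for replicated simulation studies).
#' @param gls also fit spatial GLS models for the all-species scopes.
#' @param gls_variables variables to fit by GLS (default `"TMP"`).
#' @param gls_max_n subsample cap for the GLS (see [fit_gls_spatial()]).
#' @param out_dir optional directory; when set, [run_pipeline()] writes the
#'   CSV outputs there with a provenance header.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, continents = NULL, cell_size = 50000,
                            min_richness = 5, alpha = 0.001,
                            delta_threshold = 0.1, k_bins = 10,
                            use_images = TRUE, gls = FALSE,
                            gls_variables = "TMP", gls_max_n = 1000,
                            out_dir = NULL) {
  if (min_richness <= 0 || alpha <= 0 || delta_threshold < 0 || k_bins < 2)
    stop("thresholds must be positive")
  if (is.null(continents)) {
    continents <- list(
      A = synth_config(seed = derive_seed(seed, 101)),
      B = synth_config(seed = derive_seed(seed, 202),
                       extent = c(0, 1.5e6, 0, 1.5e6), n_species = 120,
                       crs = "synthetic-albers-b")
    )
  }
  stopifnot(length(names(continents)) == length(continents))
  structure(list(seed = seed, continents = continents, cell_size = cell_size,
                 min_richness = min_richness, alpha = alpha,
                 delta_threshold = delta_threshold, k_bins = k_bins,
                 use_images = use_images, gls = gls,
                 gls_variables = gls_variables, gls_max_n = gls_max_n,
                 out_dir = out_dir),
            class = "pipeline_config")
}

# trait table for one continent, either via image rendering + extraction
# (the full protocol) or straight from the generator's ground truth
continent_traits <- function(pool, cfg, use_images) {
  if (!use_images) {
    return(tibble::tibble(
      species_id = pool$species_id, family = pool$family,
      lightness_dorsal = pool$true_lightness_dorsal,
      lightness_ventral = pool$true_lightness_ventral,
      n_images_dorsal = 1L, n_images_ventral = 1L,
      complex_id = NA_character_
    ))
  }
  rows <- lapply(seq_len(nrow(pool)), function(k) {
    sp <- pool[k, ]
    images <- list()
    for (side in c("dorsal", "ventral"))
      for (m in seq_len(sp$n_morphs))
        images[[length(images) + 1]] <- render_specimen(sp, side, cfg, morph = m)
    species_lightness(images)
  })
  ok <- !vapply(rows, inherits, logical(1), "species_exclusion")
  list(traits = do.call(rbind, rows[ok]),
       exclusions = rows[!ok])
}

#' Run the full assemblage colour-lightness pipeline on synthetic worlds
#'
#' Executes, per continent: climate generation, species pool and range
#' generation, specimen rendering and trait extraction, gridding, range
#' rasterization, assemblage means per side and family scope, per-cell
#' annual climate aggregation; then the cross-continent regression battery
#' (and optionally spatial GLS for the all-species scopes). Re-running with
#' the same configuration reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return List of class `melanoclim_run`: `traits`, `assemblages`,
#'   `environment`, `models`, `gls`, `presence` (per continent),
#'   `grids` (per continent), `log`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  traits_all <- list(); assem_all <- list(); env_all <- list()
  presence_all <- list(); grids <- list(); logs <- list()

  for (cname in names(config$continents)) {
    cfg <- config$continents[[cname]]
    clim <- gen_climate(cfg)
    pool <- gen_species_pool(cfg)
    ranges <- gen_ranges(pool, clim$annual$TMP, cfg)

    tr <- continent_traits(pool, cfg, config$use_images)
    traits <- if (is.data.frame(tr)) tr else tr$traits
    n_excl <- if (is.data.frame(tr)) 0L else length(tr$exclusions)

    grid <- make_grid(cfg$extent, config$cell_size, cfg$crs)
    presence <- rasterize_ranges(ranges, grid)
    env <- cell_environment(clim$monthly, grid)

    fams <- sort(intersect(names(cfg$families), unique(traits$family)))
    assem <- list()
    for (side in c("dorsal", "ventral"))
      for (scope in c("all", fams))
        assem[[paste(side, scope)]] <-
          assemblage_mean(presence, traits, side, scope,
                          min_richness = config$min_richness)
    assem <- do.call(rbind, assem)

    traits_all[[cname]] <- cbind(continent = cname, traits)
    assem_all[[cname]] <- cbind(continent = cname, assem)
    env_all[[cname]] <- cbind(continent = cname, env)
    presence_all[[cname]] <- presence
    grids[[cname]] <- grid
    logs[[cname]] <- list(
      n_species = nrow(pool), n_traits = nrow(traits),
      n_species_excluded = n_excl,
      n_empty_ranges = length(presence$empty_species),
      n_cells = nrow(grid$cells),
      n_cells_retained_all_dorsal =
        sum(assem$side == "dorsal" & assem$family_scope == "all")
    )
  }

  traits_all <- tibble::as_tibble(do.call(rbind, traits_all))
  assem_all <- tibble::as_tibble(do.call(rbind, assem_all))
  env_all <- tibble::as_tibble(do.call(rbind, env_all))

  models <- table1_battery(assem_all, env_all,
                           alpha = config$alpha,
                           delta_threshold = config$delta_threshold)

  gls_out <- NULL
  if (isTRUE(config$gls)) {
    recs <- list()
    for (cname in names(config$continents)) {
      grid <- grids[[cname]]
      for (side in c("dorsal", "ventral")) {
        a <- assem_all[assem_all$continent == cname &
                         assem_all$family_scope == "all" &
                         assem_all$side == side, ]
        e <- env_all[env_all$continent == cname, ]
        m <- merge(a, e, by = "cell_id")
        cc <- grid$cells[match(m$cell_id, grid$cells$cell_id), ]
        for (v in config$gls_variables) {
          shape_row <- models[models$continent == cname &
                                models$family_scope == "all" &
                                models$side == side & models$variable == v, ]
          quad <- isTRUE(shape_row$shape %in% c("U", "hump"))
          g <- fit_gls_spatial(m$mean_lightness, m[[v]],
                               cbind(cc$xcenter, cc$ycenter) / 1000,
                               quadratic = quad, max_n = config$gls_max_n,
                               seed = config$seed)
          recs[[length(recs) + 1]] <- tibble::tibble(
            continent = cname, side = side, variable = v,
            slope = g$coefficients$estimate[2],
            slope_se = g$coefficients$se[2], slope_p = g$coefficients$p[2],
            rho_km = g$rho, log_lik = g$log_lik,
            n_cells_used = g$n_cells_used, subsampled = g$subsampled
          )
        }
      }
    }
    gls_out <- do.call(rbind, recs)
  }

  run <- structure(list(
    traits = traits_all, assemblages = assem_all, environment = env_all,
    models = models, gls = gls_out, presence = presence_all, grids = grids,
    log = logs, config = config
  ), class = "melanoclim_run")

  if (!is.null(config$out_dir)) write_run_outputs(run, config$out_dir)
  run
}

#' @export
print.melanoclim_run <- function(x, ...) {
  cat(sprintf("<melanoclim_run> %d continents, %d trait rows, %d model records\n",
              length(x$grids), nrow(x$traits), nrow(x$models)))
  invisible(x)
}

#' Write the pipeline output bundle as provenance-stamped CSV files
#'
#' Every CSV starts with comment lines recording the seed and a hash of the
#' configuration, so outputs are traceable to the run that produced them.
#'
#' @param run a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- c(seed = run$config$seed, config_hash = config_hash(run$config))
  files <- c(traits = "traits.csv", assemblages = "assemblages.csv",
             environment = "environment.csv", models = "models.csv")
  written <- character(0)
  for (nm in names(files)) {
    p <- file.path(dir, files[[nm]])
    write_table_csv(run[[nm]], p, meta)
    written <- c(written, p)
  }
  if (!is.null(run$gls)) {
    p <- file.path(dir, "gls.csv")
    write_table_csv(run$gls, p, meta)
    written <- c(written, p)
  }
  for (cname in names(run$presence)) {
    p <- file.path(dir, sprintf("presence_%s.csv", cname))
    write_presence_csv(run$presence[[cname]], p, meta)
    written <- c(written, p)
  }
  invisible(written)
}

#' Quantile choropleth maps of assemblage lightness
#'
#' One map per (side, family scope): cells are coloured by quantile bin of
#' mean lightness, red for the lightest assemblages through blue for the
#' darkest. Bin edges are recorded in the plot caption.
#'
#' @param assemblages assemblage tibble for one continent (from
#'   [assemblage_mean()] or a [run_pipeline()] bundle filtered to one
#'   continent).
#' @param grid the matching [make_grid()] grid.
#' @param k_bins number of quantile bins.
#' @return Named list of ggplot objects (`"dorsal all"`, ...); scopes with
#'   no cells are skipped with a warning.
#' @export
render_maps <- function(assemblages, grid, k_bins = 10) {
  stopifnot(inherits(grid, "ea_grid"))
  out <- list()
  groups <- unique(assemblages[c("side", "family_scope")])
  for (i in seq_len(nrow(groups))) {
    side <- groups$side[i]; scope <- groups$family_scope[i]
    a <- assemblages[assemblages$side == side &
                       assemblages$family_scope == scope, ]
    key <- paste(side, scope)
    if (nrow(a) == 0) {
      warning("no cells for scope ", key, "; skipped")
      next
    }
    bins <- quantile_bins(a$mean_lightness, k_bins)
    nb <- max(bins)
    pal <- grDevices::colorRampPalette(
      c("#2166AC", "#F7F7F7", "#B2182B"))(max(nb, 2))[seq_len(nb)]
    edges <- stats::quantile(a$mean_lightness,
                             probs = seq_len(k_bins - 1) / k_bins, names = FALSE)
    cc <- grid$cells[match(a$cell_id, grid$cells$cell_id), ]
    df <- data.frame(x = cc$xcenter / 1000, y = cc$ycenter / 1000,
                     bin = factor(bins, levels = seq_len(nb)))
    out[[key]] <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, fill = bin)) +
      ggplot2::geom_tile(width = grid$cell_size / 1000,
                         height = grid$cell_size / 1000) +
      ggplot2::scale_fill_manual(values = pal, name = "lightness\n(quantile bin)") +
      ggplot2::coord_equal() +
      ggplot2::labs(
        title = sprintf("Assemblage colour lightness (%s, %s)", side, scope),
        x = "x (km)", y = "y (km)",
        caption = paste("bin edges:",
                        paste(sprintf("%.1f", edges), collapse = ", "))
      ) +
      ggplot2::theme_minimal()
  }
  out
}
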