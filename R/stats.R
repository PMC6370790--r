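#' Linear vs quadratic OLS with shape classification
#'
#' Fits `y ~ x` and `y ~ x + x^2` by OLS and classifies the relationship:
#' not significant (`"n.s."`) when neither model's overall F-test reaches
#' `alpha`; otherwise quadratic -- `"U"` (positive x^2 coefficient) or
#' `"hump"` (negative) -- when the r-squared gain of the quadratic model is
#' strictly larger than `delta_threshold`; otherwise `"linear"` with the
#' sign of the linear slope. The predictor is z-scored internally for the
#' numerical stability of the quadratic fit; r-squared, signs and p-values
#' are invariant to this.
#'
#' @param y response (assemblage mean lightness per cell).
#' @param x explanatory variable per cell.
#' @param alpha significance level of the overall F-tests (0.001 by
#'   default).
#' @param delta_threshold strict threshold on
#'   `delta_r2 = quadratic r2 - linear r2` (0.1 by default).
#' @return One-row tibble: `n_cells`, `linear_sign`, `linear_r2`,
#'   `linear_p`, `quad_sign`, `quad_r2`, `quad_p`, `delta_r2`, `shape`.
#' @export
fit_shape_models <- function(y, x, alpha = 0.001, delta_threshold = 0.1) {
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 10) stop("need at least 10 cells")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  xz <- (x - mean(x)) / stats::sd(x)

  # summary.lm warns on exact fits ("essentially perfect fit"); those are
  # legitimate inputs here (noiseless synthetic worlds), so keep it quiet
  fit_p <- function(fit) {
    fs <- suppressWarnings(summary(fit))$fstatistic
    if (is.null(fs)) return(NA_real_)
    unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  }
  lin <- stats::lm(y ~ xz)
  qua <- stats::lm(y ~ xz + I(xz^2))
  lin_r2 <- suppressWarnings(summary(lin))$r.squared
  qua_r2 <- suppressWarnings(summary(qua))$r.squared
  lin_p <- fit_p(lin); qua_p <- fit_p(qua)
  lin_sign <- if (stats::coef(lin)[2] >= 0) "+" else "-"
  qua_sign <- if (stats::coef(qua)[3] >= 0) "+" else "-"
  delta <- qua_r2 - lin_r2

  shape <- if (!is.na(lin_p) && lin_p >= alpha && !is.na(qua_p) && qua_p >= alpha) {
    "n.s."
  } else if (delta > delta_threshold) {
    if (qua_sign == "+") "U" else "hump"
  } else "linear"

  tibble::tibble(
    n_cells = length(y),
    linear_sign = lin_sign, linear_r2 = lin_r2, linear_p = lin_p,
    quad_sign = qua_sign, quad_r2 = qua_r2, quad_p = qua_p,
    delta_r2 = delta, shape = shape
  )
}

# deterministic tiny jitter for duplicated coordinates (multiplicative hash)
dedupe_coords <- function(coords, eps = 1e-3) {
  key <- paste(coords[, 1], coords[, 2])
  dup <- which(duplicated(key))
  if (length(dup)) {
    u <- ((dup * 2654435761) %% 104729) / 104729 - 0.5
    coords[dup, 1] <- coords[dup, 1] + eps * (1 + u)
    coords[dup, 2] <- coords[dup, 2] + eps * (1 - u)
  }
  coords
}

#' Generalized least squares with a Gaussian spatial correlation structure
#'
#' Fits the assemblage-level regression with errors correlated as
#' `corr(i, j) = exp(-(d_ij / rho)^2)` where `d_ij` is the Manhattan
#' distance between cell coordinates and the range `rho` is estimated by
#' maximum likelihood, accounting for the spatial non-independence of
#' neighbouring cells. Because dense-covariance ML is O(n^3), datasets larger
#' than `max_n` cells are fitted on a seeded random subsample (recorded in
#' the result). Duplicated coordinates are jittered deterministically by
#' about a metre to keep the correlation matrix non-singular.
#'
#' @param y,x response and explanatory variable per cell.
#' @param coords two-column matrix/data frame of projected coordinates in
#'   kilometres.
#' @param quadratic also include `x^2` in the mean model (use when the OLS
#'   shape classification was quadratic).
#' @param metric distance metric for the correlation structure
#'   (`"manhattan"` by default).
#' @param nugget include a nugget effect (off by default).
#' @param max_n subsample cap on the number of cells.
#' @param seed seed for the subsample draw.
#' @return List of class `gls_record`: `coefficients` (tibble of term,
#'   estimate, se, t, p), `rho` (correlation range, same units as
#'   `coords`), `log_lik`, `n_cells_used`, `subsampled`, and the underlying
#'   `fit`.
#' @export
fit_gls_spatial <- function(y, x, coords, quadratic = FALSE,
                            metric = "manhattan", nugget = FALSE,
                            max_n = 3000, seed = 1) {
  coords <- as.matrix(coords)
  ok <- is.finite(y) & is.finite(x) & is.finite(coords[, 1]) & is.finite(coords[, 2])
  y <- y[ok]; x <- x[ok]; coords <- coords[ok, , drop = FALSE]
  n <- length(y)
  subsampled <- FALSE
  if (n > max_n) {
    set.seed(derive_seed(seed, 9))
    idx <- sort(sample.int(n, max_n))
    y <- y[idx]; x <- x[idx]; coords <- coords[idx, , drop = FALSE]
    subsampled <- TRUE
  }
  coords <- dedupe_coords(coords)
  dat <- data.frame(y = y, x = x, cx = coords[, 1], cy = coords[, 2])
  form <- if (quadratic) y ~ x + I(x^2) else y ~ x

  span <- diff(range(dat$cx)) + diff(range(dat$cy))  # Manhattan diameter
  # the profiled range parameter can overflow during optimisation when the
  # data carry little spatial correlation; try a ladder of starting values
  inits <- pmax(span * c(1 / 8, 1 / 20, 1 / 50, 1 / 2), 1e-3)
  fit <- NULL; errors <- character(0)
  for (init in inits) {
    cor_struct <- nlme::corGaus(value = if (nugget) c(init, 0.1) else init,
                                form = ~ cx + cy, metric = metric,
                                nugget = nugget)
    fit <- tryCatch(
      nlme::gls(form, data = dat, correlation = cor_struct, method = "ML"),
      error = function(e) {
        errors <<- c(errors, sprintf("init %.3g: %s", init,
                                     conditionMessage(e)))
        NULL
      })
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop(sprintf(
      "spatial GLS did not converge (n = %d, metric = %s): %s",
      nrow(dat), metric, paste(errors, collapse = "; ")), call. = FALSE)
  ct <- summary(fit)$tTable
  cp <- coef(fit$modelStruct$corStruct, unconstrained = FALSE)
  structure(list(
    coefficients = tibble::tibble(
      term = rownames(ct), estimate = ct[, "Value"], se = ct[, "Std.Error"],
      t = ct[, "t-value"], p = ct[, "p-value"]
    ),
    rho = unname(cp["range"]),
    nugget = if (nugget) unname(cp["nugget"]) else 0,
    log_lik = as.numeric(stats::logLik(fit)),
    n_cells_used = nrow(dat), subsampled = subsampled, fit = fit
  ), class = "gls_record")
}

#' @export
print.gls_record <- function(x, ...) {
  cat(sprintf("<gls_record> n = %d%s, rho = %.3g, logLik = %.2f\n",
              x$n_cells_used, if (x$subsampled) " (subsampled)" else "",
              x$rho, x$log_lik))
  print(x$coefficients)
  invisible(x)
}

#' Tukey HSD contrasts of species lightness between groups
#'
#' One-way layout on species-level lightness with groups defined by family
#' and/or body side; all pairwise comparisons are adjusted with the
#' studentized-range (Tukey HSD) procedure. Groups with fewer than two
#' species are dropped with a warning.
#'
#' @param traits trait tibble with `lightness_dorsal`, `lightness_ventral`,
#'   and any grouping columns named in `group_vars` (besides `"side"`,
#'   which is created by stacking the two lightness columns).
#' @param group_vars character vector among `"family"`, `"side"`,
#'   `"continent"`.
#' @return Tibble of contrasts: `group1`, `group2`, `mean1`, `mean2`,
#'   `difference`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_side_family <- function(traits, group_vars = c("family", "side")) {
  long <- rbind(
    data.frame(traits[setdiff(names(traits),
                              c("lightness_dorsal", "lightness_ventral"))],
               side = "dorsal", lightness = traits$lightness_dorsal),
    data.frame(traits[setdiff(names(traits),
                              c("lightness_dorsal", "lightness_ventral"))],
               side = "ventral", lightness = traits$lightness_ventral)
  )
  missing_vars <- setdiff(group_vars, names(long))
  if (length(missing_vars))
    stop("grouping columns not found: ", paste(missing_vars, collapse = ", "))
  grp <- interaction(long[group_vars], sep = ":", drop = TRUE)
  sizes <- table(grp)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("dropping groups with < 2 species: ", paste(small, collapse = ", "))
    keep <- !(grp %in% small)
    long <- long[keep, ]; grp <- droplevels(grp[keep])
  }
  if (nlevels(grp) < 2) stop("need at least 2 groups with >= 2 species")
  fit <- stats::aov(long$lightness ~ grp)
  tk <- stats::TukeyHSD(fit)$grp
  gm <- tapply(long$lightness, grp, mean)
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  g1 <- vapply(pairs, `[`, "", 1); g2 <- vapply(pairs, `[`, "", 2)
  tibble::tibble(
    group1 = g1, group2 = g2,
    mean1 = unname(gm[g1]), mean2 = unname(gm[g2]),
    difference = unname(tk[, "diff"]),
    lwr = unname(tk[, "lwr"]), upr = unname(tk[, "upr"]),
    p_adj = unname(tk[, "p adj"])
  )
}

#' Full regression battery over continents, families, sides and variables
#'
#' Runs [fit_shape_models()] for every combination of continent, family
#' scope (`"all"` plus each family), body side and environmental variable,
#' producing one record per model in the layout of a continental trait-
#' climate comparison table. Combinations that cannot be fitted (absent
#' scope, too few cells, zero variance) are recorded with status
#' `"absent"` rather than dropped.
#'
#' @param assemblages tibble with `continent`, `family_scope`, `side`,
#'   `cell_id`, `mean_lightness` (as from [assemblage_mean()], stacked).
#' @param environments tibble with `continent`, `cell_id`, `INS`, `TMP`,
#'   `HUM`.
#' @param continents,families,sides,variables design levels; by default
#'   derived from the inputs.
#' @param alpha,delta_threshold passed to [fit_shape_models()].
#' @param min_cells minimum cells for a fit (10 by default).
#' @return Tibble with one row per design combination.
#' @export
table1_battery <- function(assemblages, environments,
                           continents = sort(unique(assemblages$continent)),
                           families = NULL,
                           sides = c("dorsal", "ventral"),
                           variables = c("INS", "TMP", "HUM"),
                           alpha = 0.001, delta_threshold = 0.1,
                           min_cells = 10) {
  if (is.null(families))
    families <- sort(setdiff(unique(assemblages$family_scope), "all"))
  scopes <- c("all", families)
  empty_rec <- tibble::tibble(
    n_cells = 0L, linear_sign = NA_character_, linear_r2 = NA_real_,
    linear_p = NA_real_, quad_sign = NA_character_, quad_r2 = NA_real_,
    quad_p = NA_real_, delta_r2 = NA_real_, shape = NA_character_
  )
  design <- expand.grid(variable = variables, family_scope = scopes,
                        side = sides, continent = continents,
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(design)), function(i) {
    d <- design[i, ]
    a <- assemblages[assemblages$continent == d$continent &
                       assemblages$family_scope == d$family_scope &
                       assemblages$side == d$side, ]
    e <- environments[environments$continent == d$continent, ]
    m <- merge(a, e, by = "cell_id")
    rec <- if (nrow(m) < min_cells) empty_rec else tryCatch(
      fit_shape_models(m$mean_lightness, m[[d$variable]],
                       alpha = alpha, delta_threshold = delta_threshold),
      error = function(e) empty_rec
    )
    status <- if (rec$n_cells == 0) "absent" else "ok"
    cbind(tibble::as_tibble(d), status = status, rec)
  })
  tibble::as_tibble(do.call(rbind, rows))
}
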