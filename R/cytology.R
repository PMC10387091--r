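#' GRC size from one pachytene spread cell
#'
#' Within a cell, the measured lengths of the 29 largest A chromosomes are
#' rank-paired with the 29 largest chromosome sizes of a reference karyotype
#' and an ordinary least squares regression of `log(bp)` on `log(um)` is fit.
#' The measured GRC length is first divided by `univalent_divisor` (1.5): the
#' unpaired univalent GRC forms a single, less condensed synaptonemal-complex
#' axis, inflating its apparent length relative to the bivalents. The GRC size
#' is then `exp(intercept + slope * log(grc_um / divisor))`. The estimate is
#' invariant to the micrometre unit scale and to the logarithm base.
#'
#' @param lengths_um Numeric vector of 29 measured A-chromosome lengths (um).
#' @param grc_um Measured GRC length (um).
#' @param ref_bp Numeric vector of 29 reference chromosome sizes (bp),
#'   matching by rank (both sides are sorted descending internally).
#' @param univalent_divisor Divisor applied to the GRC measurement.
#' @return List: `grc_bp`, `r_squared`, `slope`, `intercept`.
#' @export
cell_regression <- function(lengths_um, grc_um, ref_bp,
                            univalent_divisor = grc_defaults$univalent_divisor) {
  if (length(lengths_um) != length(ref_bp))
    abort("measured lengths and reference karyotype must have equal size")
  if (any(c(lengths_um, grc_um, ref_bp) <= 0))
    abort("all lengths must be positive")
  x <- log(sort(lengths_um, decreasing = TRUE))
  y <- log(sort(ref_bp, decreasing = TRUE))
  fit <- lm(y ~ x)
  grc_bp <- exp(unname(coef(fit)[1] + coef(fit)[2] * log(grc_um / univalent_divisor)))
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  list(grc_bp = grc_bp, r_squared = r2,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
}

#' Per-cell GRC size estimates for a table of spread cells
#'
#' Applies [cell_regression()] to every cell of a measurements table.
#'
#' @param cells Tibble from [read_spread_measurements()] (columns `cell_id`,
#'   `individual`, `grc_um`, list-column `lengths_um`, optional `species`).
#' @param ref_bp Reference karyotype: 29 chromosome sizes in bp.
#' @param univalent_divisor Divisor applied to GRC measurements.
#' @return Tibble: `cell_id`, `individual`, `species`, `grc_bp`, `r_squared`.
#' @export
spread_size_estimates <- function(cells, ref_bp,
                                  univalent_divisor = grc_defaults$univalent_divisor) {
  res <- purrr::map2(cells$lengths_um, cells$grc_um, function(l, g)
    cell_regression(l, g, ref_bp, univalent_divisor))
  tibble(cell_id = cells$cell_id, individual = cells$individual,
         species = if ("species" %in% names(cells)) cells$species else NA_character_,
         grc_bp = purrr::map_dbl(res, "grc_bp"),
         r_squared = purrr::map_dbl(res, "r_squared"))
}

#' Per-individual GRC size summary
#'
#' Mean per-cell estimate for each individual, and the min..max range of
#' individual means (the way a species-level size range is reported).
#'
#' @param estimates Tibble from [spread_size_estimates()].
#' @return List: `individuals` (tibble with per-individual mean, n cells) and
#'   `range_bp` (length-2 numeric, min and max of individual means).
#' @export
size_summary <- function(estimates) {
  ind <- estimates %>%
    group_by(.data$individual) %>%
    summarise(mean_bp = mean(.data$grc_bp), n_cells = n(), .groups = "drop")
  list(individuals = ind, range_bp = range(ind$mean_bp))
}

#' One-way ANOVA with Tukey HSD over per-cell GRC size estimates
#'
#' Tests whether GRC size differs among individuals, using the per-cell
#' estimates as observations (with 3 individuals of 10 cells each the total
#' degrees of freedom are 29), followed by Tukey honest significant
#' differences on the group means.
#'
#' @param estimates Tibble with `individual` and `grc_bp` columns.
#' @return A `grc_size_anova` object; `tidy()` gives the pairwise Tukey table,
#'   `glance()` the F statistic, p-value and degrees of freedom.
#' @export
anova_tukey <- function(estimates) {
  counts <- table(estimates$individual)
  if (length(counts) < 2) abort("need at least two individuals")
  if (any(counts < 2)) abort("every individual needs at least two cells")
  d <- data.frame(grc_bp = estimates$grc_bp,
                  individual = factor(estimates$individual))
  fit <- aov(grc_bp ~ individual, data = d)
  s <- summary(fit)[[1]]
  structure(list(
    aov = fit,
    f = s[["F value"]][1], p = s[["Pr(>F)"]][1],
    df_between = s[["Df"]][1], df_within = s[["Df"]][2],
    df_total = sum(s[["Df"]]),
    tukey = TukeyHSD(fit)$individual
  ), class = "grc_size_anova")
}

#' Tidy the GRC size ANOVA
#' @param x A `grc_size_anova`.
#' @param ... Unused.
#' @return Tibble of pairwise Tukey HSD comparisons with adjusted p-values
#'   and a `significant` decision at 0.05.
#' @export
tidy.grc_size_anova <- function(x, ...) {
  t <- x$tukey
  tibble(comparison = rownames(t), diff = t[, "diff"],
         lwr = t[, "lwr"], upr = t[, "upr"], p.adj = t[, "p adj"],
         significant = t[, "p adj"] < 0.05)
}

#' One-row summary of the GRC size ANOVA
#' @param x A `grc_size_anova`.
#' @param ... Unused.
#' @return Tibble with `statistic` (F), `p.value`, and degrees of freedom.
#' @export
glance.grc_size_anova <- function(x, ...) {
  tibble(statistic = x$f, p.value = x$p,
         df_between = x$df_between, df_within = x$df_within,
         df_total = x$df_total)
}

#' @export
print.grc_size_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA over individuals: F = %.3f, p = %.4g, df = %d\n",
              x$f, x$p, x$df_total))
  invisible(x)
}

#' Simulate meiotic-spread measurements
#'
#' Generates per-cell chromosome measurements from a reference karyotype
#' under a power-law length model `um = c * bp^beta` with per-cell scale
#' variation and lognormal measurement noise; the GRC measurement is inflated
#' by the univalent factor the estimator divides out.
#'
#' @param ref_bp Reference karyotype (29 sizes in bp, descending).
#' @param grc_bp_true True GRC sizes, one per individual (named vector).
#' @param cells_per_individual Cells measured per individual.
#' @param beta Power-law exponent relating physical length to bp.
#' @param noise_sd Standard deviation of lognormal measurement noise.
#' @param univalent_factor Inflation applied to the simulated GRC measurement.
#' @param seed Integer seed.
#' @return Tibble in the shape of [read_spread_measurements()] output.
#' @export
simulate_spreads <- function(ref_bp, grc_bp_true, cells_per_individual = 10L,
                             beta = 0.8, noise_sd = 0.05,
                             univalent_factor = grc_defaults$univalent_divisor,
                             seed = 1L) {
  set.seed(seed)
  if (is.null(names(grc_bp_true)))
    names(grc_bp_true) <- paste0("ind", seq_along(grc_bp_true))
  rows <- list()
  for (ind in names(grc_bp_true)) {
    for (cc in seq_len(cells_per_individual)) {
      scale <- exp(stats::rnorm(1, 0, 0.1))  # cell-to-cell spreading variation
      um <- scale * ref_bp^beta * exp(stats::rnorm(length(ref_bp), 0, noise_sd))
      grc_um <- univalent_factor * scale * grc_bp_true[[ind]]^beta *
        exp(stats::rnorm(1, 0, noise_sd))
      rows[[length(rows) + 1]] <- tibble(
        cell_id = sprintf("%s_c%02d", ind, cc), individual = ind,
        species = NA_character_, grc_um = grc_um,
        lengths_um = list(sort(um, decreasing = TRUE)))
    }
  }
  bind_rows(rows)
}
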