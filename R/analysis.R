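#' Regress estimated against total water fraction
#'
#' Simple linear regression of the water fractions recovered by the
#' pipeline on the fractions implied by fabrication. Unconstrained: ordinary
#' least squares for slope and intercept. Constrained: the line is forced
#' through the origin (a phantom of pure gelatin must read zero water), so
#' the intercept is 0 and the slope is `sum(xy)/sum(x^2)`. In both cases
#' R^2 is reported against the grand-mean null model, `1 - SSres/SStot`;
#' for the constrained line this convention can fall below zero (or differ
#' from origin-model conventions) and is used deliberately so the two modes
#' are comparable.
#'
#' @param total numeric vector of fabrication (total) water fractions.
#' @param estimated numeric vector of recovered water fractions.
#' @param constrained logical; force the fit through the origin.
#' @return An object of class `water_regression`: `slope`, `intercept`,
#'   `r_squared`, `rmse`, `constrained`, `n_points`.
#' @export
regress_water_fraction <- function(total, estimated, constrained = FALSE) {
  x <- as.numeric(total)
  y <- as.numeric(estimated)
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  n_min <- if (constrained) 1L else 2L
  if (length(x) < n_min)
    stop(sprintf("need at least %d point(s)", n_min), call. = FALSE)
  if (!constrained && length(unique(x)) < 2)
    stop("degenerate regressor: all total fractions equal", call. = FALSE)
  if (constrained && all(x == 0))
    stop("degenerate regressor: all total fractions zero", call. = FALSE)
  if (constrained) {
    slope <- sum(x * y) / sum(x * x)
    intercept <- 0
  } else {
    fit <- stats::lm.fit(cbind(1, x), y)
    intercept <- fit$coefficients[1]
    slope <- fit$coefficients[2]
  }
  pred <- intercept + slope * x
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else as.numeric(ss_res == 0)
  structure(list(slope = unname(slope), intercept = unname(intercept),
                 r_squared = r2, rmse = sqrt(mean((y - pred)^2)),
                 constrained = constrained, n_points = length(x)),
            class = "water_regression")
}

#' @export
print.water_regression <- function(x, ...) {
  cat(sprintf("<water regression%s: y = %.4g*x %+.4g, R2 = %.4g, RMSE = %.3g, n = %d>\n",
              if (x$constrained) " (through origin)" else "",
              x$slope, x$intercept, x$r_squared, x$rmse, x$n_points))
  invisible(x)
}

#' Stability period of a fitted chromophore concentration
#'
#' A phantom is considered stable while the mean fitted concentration of
#' the chromophore of interest remains within a fractional threshold
#' (default 10%) of its initial estimate. Deviations are
#' `|c(t) - c(t0)| / |c(t0)|` on per-timepoint means (replicate
#' measurements are averaged before thresholding); the last stable
#' timepoint is the latest `t` such that every timepoint up to and
#' including `t` deviates at most `threshold`. The first timepoint is
#' stable by definition.
#'
#' @param timepoints ordered numeric times (days).
#' @param values concentrations: a numeric vector (one per timepoint) or a
#'   matrix with one row per timepoint and one column per replicate.
#' @param threshold fractional deviation threshold (default 0.10).
#' @param component optional chromophore name recorded on the result.
#' @return An object of class `stability_result`: `component`,
#'   `initial_value`, `threshold`, `deviations`, `last_stable_timepoint`,
#'   `stable_through` (duration from t0).
#' @export
stability_period <- function(timepoints, values, threshold = 0.10,
                             component = "") {
  t <- as.numeric(timepoints)
  if (length(t) < 1L) stop("need at least one timepoint", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("timepoints must be strictly increasing", call. = FALSE)
  v <- if (is.matrix(values)) rowMeans(values) else as.numeric(values)
  if (length(v) != length(t))
    stop("one value (or replicate row) per timepoint required",
         call. = FALSE)
  if (v[1] == 0)
    stop("zero initial value: relative stability undefined", call. = FALSE)
  dev <- abs(v - v[1]) / abs(v[1])
  ok <- dev <= threshold + 1e-12
  last_idx <- if (all(ok)) length(t) else which(!ok)[1] - 1L
  structure(list(component = component, initial_value = v[1],
                 threshold = threshold, timepoints = t, deviations = dev,
                 last_stable_timepoint = t[last_idx],
                 stable_through = t[last_idx] - t[1]),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf(
    "<stability%s: initial %.4g, within %.0f%% through t = %g (%g from start)>\n",
    if (nzchar(x$component)) paste0(" of ", x$component) else "",
    x$initial_value, 100 * x$threshold, x$last_stable_timepoint,
    x$stable_through))
  invisible(x)
}

#' Analyze a synthetic study end to end
#'
#' Runs the full recovery chain on a generated study: per-cell inversion of
#' the observed reflectance, water/gelatin unmixing of the recovered
#' absorption, per-recipe averaging over batches and repeats, and the
#' estimated-vs-total water regression. This is the synthetic analogue of
#' the study's water-ladder analysis.
#'
#' @param study a study from [generate_study()].
#' @param lut an [inversion_lut()] (built on the study frequencies if
#'   omitted).
#' @param components components to unmix; default `NULL` fits water plus
#'   the gelatin component matching each recipe's gelatin type.
#' @param mode fit mode (default `"unconstrained"`, the convention for
#'   water/gelatin-only fits; see [fit_concentrations()]).
#' @param timepoint which timepoint to analyze (default the first).
#' @return List: `per_cell` data frame of recovered concentrations,
#'   `per_recipe` data frame of recipe means, `regression`
#'   (unconstrained) and `regression_constrained`.
#' @export
analyze_water_study <- function(study, lut = NULL, components = NULL,
                                mode = "unconstrained",
                                timepoint = NULL) {
  stopifnot(inherits(study, "synthetic_study"))
  if (is.null(lut))
    lut <- build_lookup(fx = study$config$fx, n = study$config$n)
  if (is.null(timepoint)) timepoint <- min(study$config$timepoints)
  basis <- study$basis
  cells <- Filter(function(c) c$timepoint == timepoint, study$cells)
  per_cell <- do.call(rbind, lapply(cells, function(cell) {
    comps <- components
    if (is.null(comps)) {
      gel <- if (study$config$recipes[[cell$recipe_id]]$gelatin_type ==
                 "store_bought") "gelatin_store" else "gelatin_research"
      comps <- c("water", gel)
    }
    props <- invert_reflectance(cell$obs, lut)
    fit <- fit_concentrations(
      spectrum(props$wavelengths_nm, pmax(props$mu_a, 0),
               "absorption mm^-1"),
      basis, comps, mode)
    conc <- fit$concentrations
    names(conc)[startsWith(names(conc), "gelatin")] <- "gelatin"
    data.frame(recipe = cell$recipe_id, batch = cell$batch,
               repeat_id = cell$repeat_id,
               total_water = cell$total_water_fraction,
               t(conc))
  }))
  agg <- stats::aggregate(per_cell[intersect(c("water", "gelatin"),
                                             names(per_cell))],
                          by = list(recipe = per_cell$recipe,
                                    total_water = per_cell$total_water),
                          FUN = mean)
  multi <- length(unique(agg$total_water)) >= 2
  list(per_cell = per_cell,
       per_recipe = agg,
       regression = if (multi)
         regress_water_fraction(agg$total_water, agg$water,
                                constrained = FALSE),
       regression_constrained = if (multi)
         regress_water_fraction(agg$total_water, agg$water,
                                constrained = TRUE))
}
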