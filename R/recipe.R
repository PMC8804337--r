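#' Phantom recipe
#'
#' Composition of a gelatin/Intralipid tissue-simulating phantom in weight
#' percent, optionally carrying a hemoglobin additive. The three weight
#' percentages must sum to 100. The additive amount is absolute (mg of
#' ferrous-stabilized hemoglobin powder, or ml of whole blood), so an
#' absolute batch mass is carried alongside the percentages to allow
#' concentration arithmetic.
#'
#' @param water_wt_pct,gelatin_wt_pct,intralipid20_wt_pct weight percent of
#'   water, gelatin and Intralipid 20%; non-negative, summing to 100.
#' @param gelatin_type `"store_bought"` or `"research_grade"`.
#' @param hemoglobin_additive `NULL`, or a list
#'   `list(kind = "ferrous_powder"|"whole_blood", amount = <mg or ml>)`.
#' @param batch_label free-text batch identifier.
#' @param batch_mass_g total phantom mass in grams (water + gelatin +
#'   Intralipid, excluding the additive); default 100.
#' @return An object of class `phantom_recipe`.
#' @export
phantom_recipe <- function(water_wt_pct, gelatin_wt_pct, intralipid20_wt_pct,
                           gelatin_type = c("store_bought", "research_grade"),
                           hemoglobin_additive = NULL,
                           batch_label = "", batch_mass_g = 100) {
  gelatin_type <- match.arg(gelatin_type)
  pct <- c(water_wt_pct, gelatin_wt_pct, intralipid20_wt_pct)
  if (any(pct < 0))
    stop("weight percentages must be non-negative", call. = FALSE)
  if (abs(sum(pct) - 100) > 1e-6)
    stop(sprintf("weight percentages sum to %.8g, not 100", sum(pct)),
         call. = FALSE)
  if (!is.null(hemoglobin_additive)) {
    if (!is.list(hemoglobin_additive) ||
        !all(c("kind", "amount") %in% names(hemoglobin_additive)) ||
        !hemoglobin_additive$kind %in% c("ferrous_powder", "whole_blood") ||
        hemoglobin_additive$amount < 0)
      stop("hemoglobin_additive must be list(kind = 'ferrous_powder'|'whole_blood', amount >= 0)",
           call. = FALSE)
  }
  structure(list(water_wt_pct = water_wt_pct,
                 gelatin_wt_pct = gelatin_wt_pct,
                 intralipid20_wt_pct = intralipid20_wt_pct,
                 gelatin_type = gelatin_type,
                 hemoglobin_additive = hemoglobin_additive,
                 batch_label = batch_label,
                 batch_mass_g = batch_mass_g),
            class = "phantom_recipe")
}

#' @export
print.phantom_recipe <- function(x, ...) {
  cat(sprintf("<phantom recipe: water %g%% / gelatin %g%% (%s) / IL20 %g%%%s>\n",
              x$water_wt_pct, x$gelatin_wt_pct, x$gelatin_type,
              x$intralipid20_wt_pct,
              if (is.null(x$hemoglobin_additive)) "" else
                sprintf(" + %g %s %s", x$hemoglobin_additive$amount,
                        if (x$hemoglobin_additive$kind == "whole_blood")
                          "ml" else "mg",
                        x$hemoglobin_additive$kind)))
  invisible(x)
}

#' The four-level water ladder
#'
#' The study's standard design: four compositions at fixed 10 wt% of
#' Intralipid 20%, spanning total water fractions 0.97, 0.88, 0.68, 0.48.
#'
#' @param gelatin_type gelatin type applied to all four recipes.
#' @return List of four [phantom_recipe()]s.
#' @export
water_ladder_recipes <- function(gelatin_type = "store_bought") {
  comps <- list(c(89, 1, 10), c(80, 10, 10), c(60, 30, 10), c(40, 50, 10))
  lapply(seq_along(comps), function(i)
    phantom_recipe(comps[[i]][1], comps[[i]][2], comps[[i]][3],
                   gelatin_type = gelatin_type,
                   batch_label = sprintf("phantom%d", i)))
}

#' Total water fraction of a recipe
#'
#' Intralipid 20% is itself 80% water by mass, so the total water fraction
#' is `(water_wt_pct + 0.8 * intralipid20_wt_pct) / 100`.
#'
#' @param recipe a [phantom_recipe()].
#' @return Total water mass fraction in \[0, 1\].
#' @export
total_water_fraction <- function(recipe) {
  stopifnot(inherits(recipe, "phantom_recipe"))
  (recipe$water_wt_pct + 0.8 * recipe$intralipid20_wt_pct) / 100
}

#' Default density / molecular-weight assumptions
#'
#' All components at 1.00 g/ml (the recipes are stated in weight percent and
#' no densities are given, so unit density keeps mass-volume conversions
#' transparent); hemoglobin tetramer MW 64,500 g/mol; whole-blood hemoglobin
#' content 150 g/L.
#'
#' @return Named list of assumption constants.
#' @export
default_assumptions <- function() {
  list(density_g_per_ml = c(water = 1.0, gelatin = 1.0, intralipid20 = 1.0),
       hb_mw_g_per_mol = 64500,
       blood_hb_g_per_l = 150)
}

#' Nominal chromophore concentrations implied by a recipe
#'
#' Deterministic recipe arithmetic: total-water volume fraction, gelatin
#' mass fraction, and — when a hemoglobin additive is present — the
#' hemoglobin tetramer concentration in uM, computed as additive hemoglobin
#' mass / MW / phantom volume under the stated density assumptions. The
#' additive's own mass is excluded from the phantom volume.
#'
#' @param recipe a [phantom_recipe()].
#' @param assumptions density/MW table as from [default_assumptions()].
#' @return Named list: `water` (volume fraction), `gelatin` (mass
#'   fraction), `hemoglobin_uM` (total heme tetramer, 0 when no additive).
#' @export
nominal_concentrations <- function(recipe, assumptions = default_assumptions()) {
  stopifnot(inherits(recipe, "phantom_recipe"))
  need <- c("density_g_per_ml", "hb_mw_g_per_mol", "blood_hb_g_per_l")
  if (!all(need %in% names(assumptions)))
    stop(sprintf("assumptions table missing entries: %s",
                 paste(setdiff(need, names(assumptions)), collapse = ", ")),
         call. = FALSE)
  dens <- assumptions$density_g_per_ml
  if (!all(c("water", "gelatin", "intralipid20") %in% names(dens)))
    stop("density table must name water, gelatin and intralipid20",
         call. = FALSE)
  m <- recipe$batch_mass_g *
    c(recipe$water_wt_pct, recipe$gelatin_wt_pct,
      recipe$intralipid20_wt_pct) / 100
  vol_ml <- sum(m / dens[c("water", "gelatin", "intralipid20")])
  # water volume: free water plus the 80% water content of Intralipid 20%
  water_vol_ml <- (m[1] + 0.8 * m[3]) / dens[["water"]]
  hb_uM <- 0
  if (!is.null(recipe$hemoglobin_additive)) {
    add <- recipe$hemoglobin_additive
    hb_g <- if (add$kind == "ferrous_powder") add$amount / 1000
            else add$amount / 1000 * assumptions$blood_hb_g_per_l
    hb_uM <- hb_g / assumptions$hb_mw_g_per_mol / (vol_ml / 1000) * 1e6
  }
  list(water = unname(water_vol_ml / vol_ml),
       gelatin = recipe$gelatin_wt_pct / 100,
       hemoglobin_uM = unname(hb_uM))
}

#' Forward linear mixing of absorption
#'
#' The forward direction of the unmixing model:
#' `mu_a(lambda) = sum_i c_i * eps_i(lambda)` over the named basis
#' components. Concentration units must match each component's tag (uM for
#' Hb species, fractions for water/gelatin).
#'
#' @param basis a [chromophore_basis()].
#' @param concentrations named numeric vector/list, names in the basis.
#' @return Absorption [spectrum()] (mm^-1) on the basis grid.
#' @export
expected_absorption <- function(basis, concentrations) {
  stopifnot(inherits(basis, "chromophore_basis"))
  conc <- unlist(concentrations)
  missing <- setdiff(names(conc), names(basis$components))
  if (length(missing))
    stop(sprintf("concentration name(s) not in basis: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (nm in names(conc))
    if (!grepl("specific-absorption", basis$components[[nm]]$unit_tag))
      stop(sprintf("component '%s' is not a specific-absorption spectrum", nm),
           call. = FALSE)
  E <- basis_matrix(basis, names(conc))
  v <- as.vector(E %*% conc)
  spectrum(basis$grid, v, "absorption mm^-1")
}

#' Power-law reduced-scattering model
#'
#' Rayleigh + Mie mixture:
#' `mu_s'(lambda) = amplitude * (r (lambda/lambda0)^-4 +
#' (1-r) (lambda/lambda0)^-b)`, scaled in proportion to the Intralipid
#' content when evaluated for a recipe. The default amplitude puts a
#' 10 wt% Intralipid-20% phantom (2% Intralipid) at ~1.6 mm^-1 at 650 nm,
#' the mid-spectrum regime of these phantoms.
#'
#' @param amplitude_mm1 reduced scattering (mm^-1) at the reference
#'   wavelength for the reference 10 wt% Intralipid-20% loading.
#' @param reference_wavelength_nm reference wavelength (nm).
#' @param rayleigh_fraction Rayleigh mixing fraction r in \[0, 1\].
#' @param mie_power Mie scatter power b > 0.
#' @return An object of class `scattering_model`.
#' @export
scattering_model <- function(amplitude_mm1 = 1.6,
                             reference_wavelength_nm = 650,
                             rayleigh_fraction = 0.1, mie_power = 2.4) {
  if (amplitude_mm1 <= 0) stop("amplitude must be positive", call. = FALSE)
  if (rayleigh_fraction < 0 || rayleigh_fraction > 1)
    stop("rayleigh_fraction must lie in [0, 1]", call. = FALSE)
  if (mie_power <= 0) stop("mie_power must be positive", call. = FALSE)
  structure(list(amplitude_mm1 = amplitude_mm1,
                 reference_wavelength_nm = reference_wavelength_nm,
                 rayleigh_fraction = rayleigh_fraction,
                 mie_power = mie_power),
            class = "scattering_model")
}

#' Predicted reduced-scattering spectrum of a recipe
#'
#' @param recipe a [phantom_recipe()]; scattering scales with
#'   `intralipid20_wt_pct / 10` (the study holds Intralipid fixed at 10 wt%
#'   precisely so scattering is decoupled from the water ladder).
#' @param model a [scattering_model()].
#' @param grid wavelength grid (nm).
#' @return Reduced-scattering [spectrum()] (mm^-1), strictly positive and
#'   monotone decreasing in wavelength.
#' @export
expected_scattering <- function(recipe, model = scattering_model(),
                                grid = default_grid()) {
  stopifnot(inherits(recipe, "phantom_recipe"),
            inherits(model, "scattering_model"))
  rel <- grid / model$reference_wavelength_nm
  shape <- model$rayleigh_fraction * rel^-4 +
    (1 - model$rayleigh_fraction) * rel^(-model$mie_power)
  v <- (recipe$intralipid20_wt_pct / 10) * model$amplitude_mm1 * shape
  spectrum(grid, v, "reduced-scattering mm^-1")
}

#' Read / write phantom recipes as JSON
#'
#' Schema keys: `water_wt_pct`, `gelatin_wt_pct`, `intralipid20_wt_pct`,
#' `gelatin_type`, `hemoglobin_additive{kind, amount, unit}`, `batch_label`,
#' `batch_mass_g`.
#'
#' @param path JSON file path holding one recipe or a list of recipes.
#' @return `read_recipe_json`: a list of [phantom_recipe()]s.
#' @export
read_recipe_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(x$water_wt_pct)) x <- list(x)  # single recipe file
  lapply(x, function(r) {
    add <- r$hemoglobin_additive
    if (!is.null(add)) add <- list(kind = add$kind, amount = add$amount)
    phantom_recipe(r$water_wt_pct, r$gelatin_wt_pct, r$intralipid20_wt_pct,
                   gelatin_type = r$gelatin_type %||% "store_bought",
                   hemoglobin_additive = add,
                   batch_label = r$batch_label %||% "",
                   batch_mass_g = r$batch_mass_g %||% 100)
  })
}

#' @param recipes list of [phantom_recipe()]s.
#' @rdname read_recipe_json
#' @export
write_recipe_json <- function(recipes, path) {
  if (inherits(recipes, "phantom_recipe")) recipes <- list(recipes)
  out <- lapply(recipes, function(r) {
    add <- r$hemoglobin_additive
    if (!is.null(add))
      add <- list(kind = add$kind, amount = add$amount,
                  unit = if (add$kind == "whole_blood") "ml" else "mg")
    list(water_wt_pct = r$water_wt_pct, gelatin_wt_pct = r$gelatin_wt_pct,
         intralipid20_wt_pct = r$intralipid20_wt_pct,
         gelatin_type = r$gelatin_type, hemoglobin_additive = add,
         batch_label = r$batch_label, batch_mass_g = r$batch_mass_g)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
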