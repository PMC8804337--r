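#' First-order oxyhemoglobin-to-methemoglobin conversion
#'
#' Auto-oxidation of the heme group converts HbO2 to MetHb; modeled as a
#' first-order process with rate `k` (per day):
#' `HbO2(t) = c0 exp(-k t)`, `MetHb(t) = m0 + c0 (1 - exp(-k t))`.
#' Total heme is conserved at every time.
#'
#' @param c_hbo2_0 initial HbO2 concentration (uM), >= 0.
#' @param c_methb_0 initial MetHb concentration (uM), >= 0.
#' @param k conversion rate (per day), >= 0.
#' @param times numeric times (days), >= 0.
#' @return Data frame with columns `time`, `HbO2`, `MetHb`.
#' @export
methb_drift <- function(c_hbo2_0, c_methb_0, k, times) {
  if (k < 0 || c_hbo2_0 < 0 || c_methb_0 < 0)
    stop("rate and initial concentrations must be non-negative",
         call. = FALSE)
  if (any(times < 0)) stop("negative time", call. = FALSE)
  decay <- exp(-k * times)
  data.frame(time = times, HbO2 = c_hbo2_0 * decay,
             MetHb = c_methb_0 + c_hbo2_0 * (1 - decay))
}

#' Early water loss with a stable plateau
#'
#' Fitted water fractions of these phantoms drop by a few percent over the
#' first days and then hold steady; modeled as a linear decline from `f0`
#' to `f0 (1 - early_loss)` at `plateau_day`, constant afterwards. The
#' defaults (8% loss, plateau at day 2) echo the observed behavior.
#'
#' @param f0 initial water fraction.
#' @param early_loss fractional loss in \[0, 1).
#' @param plateau_day day at which the plateau is reached (> 0).
#' @param times numeric times (days), >= 0.
#' @return Numeric vector of water fractions per time.
#' @export
water_drift <- function(f0, early_loss = 0.08, plateau_day = 2, times = 0) {
  if (early_loss < 0 || early_loss >= 1)
    stop("early_loss must lie in [0, 1)", call. = FALSE)
  if (plateau_day <= 0) stop("plateau_day must be positive", call. = FALSE)
  if (any(times < 0)) stop("negative time", call. = FALSE)
  f0 * (1 - early_loss * pmin(times / plateau_day, 1))
}

#' Configuration of a synthetic phantom study
#'
#' Defines the conditions of a simulated fabrication-and-characterization
#' study: the recipe ladder (default the four-level water ladder at fixed
#' 10 wt% Intralipid 20%), the hemoglobin scenario, drift parameters,
#' noise and variability levels, replication structure and time grid.
#'
#' Defaults encode the study conditions: three batches with three spatial
#' repeats each; 1% multiplicative reflectance noise; 5% batch-to-batch and
#' 3% within-phantom lognormal variability on concentrations; timepoints
#' 2 h, 4 h, 1 d, 2 d, 3 d, 4 d. Ferrous-powder hemoglobin starts with 35%
#' of total heme already oxidized to MetHb and converts fast (k = 1/day);
#' whole blood starts MetHb-free and converts slowly (k = 0.08/day). Total
#' heme defaults (3.2 uM ferrous, 4.2 uM whole blood) are set to the
#' magnitude regime of the measured concentration tables, which sit well
#' below the recipe-implied molarity (see the methods vignette).
#'
#' @param recipes list of [phantom_recipe()]s (default
#'   [water_ladder_recipes()]).
#' @param hemoglobin_scenario `"none"`, `"ferrous_powder"` or
#'   `"whole_blood"`.
#' @param hb_total_uM total heme concentration (uM); default by scenario.
#' @param methb_init_fraction initial MetHb fraction of total heme;
#'   default by scenario.
#' @param k_per_day HbO2 -> MetHb conversion rate; default by scenario.
#' @param water_early_loss,water_plateau_day water-drift parameters.
#' @param noise_sd multiplicative reflectance noise sd (fraction).
#' @param batch_sd,spatial_sd lognormal sds of the batch and within-phantom
#'   concentration factors (fractions).
#' @param timepoints measurement times (days).
#' @param n_batches,n_spatial_repeats replication structure.
#' @param grid wavelength grid (nm).
#' @param fx spatial frequencies (mm^-1).
#' @param n refractive index.
#' @param scattering a [scattering_model()].
#' @param seed integer seed; the study is a pure function of
#'   (config, seed).
#' @return An object of class `synthetic_study_config`.
#' @export
synthetic_study_config <- function(
    recipes = water_ladder_recipes(),
    hemoglobin_scenario = c("none", "ferrous_powder", "whole_blood"),
    hb_total_uM = NULL, methb_init_fraction = NULL, k_per_day = NULL,
    water_early_loss = 0.08, water_plateau_day = 2,
    noise_sd = 0.01, batch_sd = 0.05, spatial_sd = 0.03,
    timepoints = c(2, 4, 24, 48, 72, 96) / 24,
    n_batches = 3, n_spatial_repeats = 3,
    grid = default_grid(), fx = default_frequencies(), n = 1.4,
    scattering = scattering_model(), seed = 1) {
  hemoglobin_scenario <- match.arg(hemoglobin_scenario)
  defaults <- switch(hemoglobin_scenario,
    none           = list(tot = 0,   m0 = 0,    k = 0),
    ferrous_powder = list(tot = 3.2, m0 = 0.35, k = 1.0),
    whole_blood    = list(tot = 4.2, m0 = 0,    k = 0.08))
  hb_total_uM <- hb_total_uM %||% defaults$tot
  methb_init_fraction <- methb_init_fraction %||% defaults$m0
  k_per_day <- k_per_day %||% defaults$k
  stopifnot(noise_sd >= 0, batch_sd >= 0, spatial_sd >= 0, k_per_day >= 0,
            hb_total_uM >= 0, methb_init_fraction >= 0,
            methb_init_fraction <= 1, n_batches >= 1,
            n_spatial_repeats >= 1)
  for (r in recipes) stopifnot(inherits(r, "phantom_recipe"))
  structure(list(recipes = recipes,
                 hemoglobin_scenario = hemoglobin_scenario,
                 hb_total_uM = hb_total_uM,
                 methb_init_fraction = methb_init_fraction,
                 k_per_day = k_per_day,
                 water_early_loss = water_early_loss,
                 water_plateau_day = water_plateau_day,
                 noise_sd = noise_sd, batch_sd = batch_sd,
                 spatial_sd = spatial_sd,
                 timepoints = sort(timepoints),
                 n_batches = n_batches,
                 n_spatial_repeats = n_spatial_repeats,
                 grid = grid, fx = fx, n = n, scattering = scattering,
                 seed = as.integer(seed)),
            class = "synthetic_study_config")
}

#' Generate a complete synthetic phantom study
#'
#' For every (recipe, batch, timepoint, spatial repeat) cell: true
#' concentrations are the recipe nominals scaled by lognormal batch and
#' spatial factors and drifted by [methb_drift()] / [water_drift()]; the
#' true absorption spectrum is assembled by [expected_absorption()] over
#' the reference basis (with the recipe's gelatin spectrum), reduced
#' scattering by [expected_scattering()]; calibrated reflectance is
#' computed at the configured frequencies by [diffusion_reflectance()] and
#' degraded with truncated multiplicative Gaussian noise. The whole study
#' is a deterministic function of (config, seed): each batch draws from
#' its own derived RNG substream.
#'
#' @param config a [synthetic_study_config()].
#' @return An object of class `synthetic_study`: `config`, `basis` (the
#'   reference basis including both gelatin types), and `cells`, a list of
#'   records `recipe_id`, `batch`, `timepoint`, `repeat_id`,
#'   `total_water_fraction`, `truth` (concentrations, mu_a, mu_s_prime)
#'   and `obs` (an [sfd_measurement()]).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_study_config"))
  old_rng <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_rng), add = TRUE)
  grid <- config$grid
  basis <- make_reference_basis(grid, gelatin_spectra = list(
    gelatin_store = gelatin_spectrum("store_bought", grid),
    gelatin_research = gelatin_spectrum("research_grade", grid)))
  cells <- list()
  for (ri in seq_along(config$recipes)) {
    recipe <- config$recipes[[ri]]
    gel_comp <- if (recipe$gelatin_type == "store_bought")
      "gelatin_store" else "gelatin_research"
    f_w0 <- total_water_fraction(recipe)
    f_g <- recipe$gelatin_wt_pct / 100
    hb_tot <- if (config$hemoglobin_scenario == "none") 0 else
      config$hb_total_uM
    for (b in seq_len(config$n_batches)) {
      # distinct deterministic substream per (recipe, batch)
      sub_seed <- (config$seed * 7919 + ri * 104729 + b * 1299709) %%
        2147483647
      set.seed(as.integer(sub_seed))
      batch_f <- stats::rlnorm(3, -config$batch_sd^2 / 2, config$batch_sd)
      names(batch_f) <- c("water", "gelatin", "hb")
      if (config$batch_sd == 0) batch_f[] <- 1
      for (ti in seq_along(config$timepoints)) {
        t <- config$timepoints[ti]
        f_w_t <- water_drift(f_w0, config$water_early_loss,
                             config$water_plateau_day, t)
        hb <- methb_drift(hb_tot * (1 - config$methb_init_fraction),
                          hb_tot * config$methb_init_fraction,
                          config$k_per_day, t)
        for (rep_i in seq_len(config$n_spatial_repeats)) {
          sp_f <- stats::rlnorm(3, -config$spatial_sd^2 / 2,
                                config$spatial_sd)
          if (config$spatial_sd == 0) sp_f[] <- 1
          conc <- c(water = f_w_t * batch_f[["water"]] * sp_f[1],
                    gelatin = f_g * batch_f[["gelatin"]] * sp_f[2])
          names(conc)[2] <- gel_comp
          if (hb_tot > 0) {
            conc <- c(conc, HbO2 = hb$HbO2 * batch_f[["hb"]] * sp_f[3],
                      MetHb = hb$MetHb * batch_f[["hb"]] * sp_f[3])
          }
          mu_a <- expected_absorption(basis, conc)
          mu_s <- expected_scattering(recipe, config$scattering, grid)
          rd <- vapply(config$fx, function(f)
            diffusion_reflectance(mu_a$values + 1e-12, mu_s$values, f,
                                  config$n),
            numeric(length(grid)))
          if (config$noise_sd > 0)
            rd <- rd * pmax(1 + config$noise_sd *
                              stats::rnorm(length(rd)), 0)
          rd <- pmin(pmax(rd, 0), 1)
          cells[[length(cells) + 1L]] <- list(
            recipe_id = ri, batch = b, timepoint = t, repeat_id = rep_i,
            total_water_fraction = f_w0,
            truth = list(concentrations = conc, mu_a = mu_a,
                         mu_s_prime = mu_s),
            obs = sfd_measurement(grid, config$fx, rd,
                                  reference = "synthetic"))
        }
      }
    }
  }
  structure(list(config = config, basis = basis, cells = cells),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic study: %d recipes x %d batches x %d timepoints x %d repeats = %d cells (seed %d)>\n",
    length(x$config$recipes), x$config$n_batches,
    length(x$config$timepoints), x$config$n_spatial_repeats,
    length(x$cells), x$config$seed))
  invisible(x)
}

# save/restore R's global RNG state so generation is a pure function of the
# config seed and leaves the caller's stream untouched
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Write a study bundle to disk
#'
#' Directory layout: `recipes.json`, one long-format reflectance CSV per
#' cell (`cell_<recipe>_<batch>_<time>_<repeat>.csv`) and a
#' `manifest.json` recording the config, seed and schema version.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @export
write_study_bundle <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_recipe_json(study$config$recipes, file.path(dir, "recipes.json"))
  files <- vapply(study$cells, function(cell) {
    f <- sprintf("cell_r%d_b%d_t%s_s%d.csv", cell$recipe_id, cell$batch,
                 gsub("[.]", "p", format(cell$timepoint)), cell$repeat_id)
    write_reflectance_csv(cell$obs, file.path(dir, f))
    f
  }, character(1))
  cfg <- study$config
  manifest <- list(
    schema_version = "1",
    seed = cfg$seed,
    hemoglobin_scenario = cfg$hemoglobin_scenario,
    noise_sd = cfg$noise_sd, batch_sd = cfg$batch_sd,
    spatial_sd = cfg$spatial_sd,
    timepoints = cfg$timepoints,
    n_batches = cfg$n_batches, n_spatial_repeats = cfg$n_spatial_repeats,
    fx = cfg$fx, n = cfg$n,
    wavelength_range = range(cfg$grid),
    cells = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
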