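#' Chromophore basis set
#'
#' An ordered set of named specific-absorption spectra sharing one
#' wavelength grid, used both to predict phantom absorption (forward) and
#' to unmix measured absorption into concentrations (inverse). Hemoglobin
#' species are tabulated per micromolar of tetramer (MW 64,500 g/mol),
#' water per unit volume fraction, gelatin per unit mass fraction.
#'
#' @param components named list of [spectrum()] objects with
#'   specific-absorption unit tags, all on exactly the same grid.
#' @return An object of class `chromophore_basis`.
#' @export
chromophore_basis <- function(components) {
  if (is.null(names(components)) || any(names(components) == "") ||
      anyDuplicated(names(components)))
    stop("components must be uniquely named", call. = FALSE)
  grids <- lapply(components, `[[`, "wavelengths_nm")
  g0 <- grids[[1]]
  for (i in seq_along(grids))
    if (!identical(length(grids[[i]]), length(g0)) ||
        any(grids[[i]] != g0))
      stop(sprintf("component '%s' is not on the shared grid",
                   names(components)[i]), call. = FALSE)
  structure(list(components = components, grid = g0),
            class = "chromophore_basis")
}

#' @export
print.chromophore_basis <- function(x, ...) {
  cat(sprintf("<chromophore basis: %s; %d wavelengths, %.0f-%.0f nm>\n",
              paste(names(x$components), collapse = ", "),
              length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Resample every basis component onto a target grid
#'
#' @param basis a [chromophore_basis()].
#' @param target_grid strictly increasing wavelengths (nm) within the native
#'   span of every component.
#' @return A [chromophore_basis()] on `target_grid`; unit tags preserved.
#' @export
resample_basis <- function(basis, target_grid) {
  stopifnot(inherits(basis, "chromophore_basis"))
  comps <- lapply(names(basis$components), function(nm) {
    tryCatch(resample_spectrum(basis$components[[nm]], target_grid),
             error = function(e) stop(sprintf(
               "component '%s': %s", nm, conditionMessage(e)), call. = FALSE))
  })
  names(comps) <- names(basis$components)
  chromophore_basis(comps)
}

#' Matrix view of a basis over selected components
#'
#' @param basis a [chromophore_basis()].
#' @param components character vector of component names (default: all).
#' @return numeric matrix, wavelengths x components.
#' @export
basis_matrix <- function(basis, components = names(basis$components)) {
  missing <- setdiff(components, names(basis$components))
  if (length(missing))
    stop(sprintf("unknown basis component(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  E <- vapply(components, function(nm) basis$components[[nm]]$values,
              numeric(length(basis$grid)))
  dimnames(E) <- list(NULL, components)
  E
}

#' Bundled reference chromophore basis
#'
#' Loads the packaged specific-absorption tables for oxyhemoglobin (HbO2),
#' deoxyhemoglobin (Hb), methemoglobin (MetHb) — all per uM of tetramer —
#' and water (per unit volume fraction), resampled onto `grid`, and appends
#' any supplied gelatin spectra (per unit mass fraction). The bundled tables
#' are smooth synthetic reconstructions anchored at the canonical landmarks
#' of each chromophore (e.g. the water band at 970 nm and the MetHb feature
#' at 630 nm); see the file headers under `inst/extdata/spectra`.
#'
#' @param grid target wavelength grid (nm), within \[450, 1000\].
#' @param gelatin_spectra optional named list of gelatin [spectrum()]s to
#'   append (they are resampled onto `grid`).
#' @return A [chromophore_basis()] with components HbO2, Hb, MetHb, water,
#'   plus any gelatin components.
#' @export
make_reference_basis <- function(grid = default_grid(), gelatin_spectra = NULL) {
  if (min(grid) < 450 - 1e-9 || max(grid) > 1000 + 1e-9)
    stop("grid outside the tabulated 450-1000 nm span", call. = FALSE)
  dir <- system.file("extdata", "spectra", package = "sfdphantom",
                     mustWork = TRUE)
  files <- c(HbO2 = "hbo2_synthetic.csv", Hb = "hb_synthetic.csv",
             MetHb = "methb_synthetic.csv", water = "water_synthetic.csv")
  comps <- lapply(files, function(f)
    resample_spectrum(read_spectrum_csv(file.path(dir, f)), grid))
  if (!is.null(gelatin_spectra)) {
    if (is.null(names(gelatin_spectra)))
      stop("gelatin_spectra must be named", call. = FALSE)
    comps <- c(comps, lapply(gelatin_spectra, resample_spectrum,
                             target_grid = grid))
  }
  chromophore_basis(comps)
}

#' Default wavelength grid
#'
#' 450 to 1000 nm in 2-nm steps: the spectrometer range of the study system
#' at a resolution that keeps simulations desk-scale.
#'
#' @return numeric vector of wavelengths (nm).
#' @export
default_grid <- function() seq(450, 1000, by = 2)

#' One point of a gelatin/water dilution series
#'
#' @param mu_a measured absorption [spectrum()] (mm^-1).
#' @param water_fraction total water fraction in \[0, 1\].
#' @param gelatin_fraction gelatin mass fraction in \[0, 1\].
#' @return A `dilution_point` record.
#' @export
dilution_point <- function(mu_a, water_fraction, gelatin_fraction) {
  stopifnot(inherits(mu_a, "spectrum_sfd"))
  if (water_fraction < 0 || water_fraction > 1 ||
      gelatin_fraction < 0 || gelatin_fraction > 1)
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (water_fraction + gelatin_fraction > 1 + 1e-9)
    stop("water_fraction + gelatin_fraction exceeds 1", call. = FALSE)
  structure(list(mu_a = mu_a, water_fraction = water_fraction,
                 gelatin_fraction = gelatin_fraction),
            class = "dilution_point")
}

#' Estimate the gelatin absorption spectrum from a dilution series
#'
#' Gelatin absorption is taken as the part of each measured spectrum that
#' the water spectrum cannot account for: per dilution point the known
#' water contribution `water_fraction * water_basis` is removed, the
#' residual is clipped at zero (absorption cannot be negative), divided by
#' the gelatin mass fraction, and the per-unit-gelatin spectra are averaged
#' across points. With `method = "joint"` a single per-wavelength
#' least-squares gelatin value is fit across all points instead (clipped at
#' zero); the two agree exactly on noiseless data. `water = "fitted"`
#' replaces the known water fraction by an ordinary least-squares water
#' coefficient per point, for series whose nominal water content is not
#' trusted.
#'
#' @param series list of [dilution_point()]s; at least two points with
#'   distinct non-zero gelatin fractions.
#' @param water_basis water specific-absorption [spectrum()] on the same
#'   grid as the series.
#' @param method `"residual"` (per-point residual mean, default) or
#'   `"joint"` (per-wavelength least squares across points).
#' @param water `"known"` (use each point's recorded water fraction,
#'   default) or `"fitted"` (least-squares water coefficient per point).
#' @return Gelatin specific-absorption [spectrum()] per unit mass fraction;
#'   non-negative everywhere.
#' @export
estimate_gelatin_spectrum <- function(series, water_basis,
                                      method = c("residual", "joint"),
                                      water = c("known", "fitted")) {
  method <- match.arg(method)
  water <- match.arg(water)
  stopifnot(inherits(water_basis, "spectrum_sfd"))
  if (!length(series) || !all(vapply(series, inherits, TRUE, "dilution_point")))
    stop("series must be a list of dilution_point objects", call. = FALSE)
  fg <- vapply(series, `[[`, numeric(1), "gelatin_fraction")
  if (all(fg == 0))
    stop("all gelatin fractions are zero: gelatin spectrum unidentifiable",
         call. = FALSE)
  if (sum(fg > 0) < 2 || length(unique(fg[fg > 0])) < 2)
    stop("need at least two points with distinct non-zero gelatin fractions",
         call. = FALSE)
  W <- water_basis$values
  g0 <- water_basis$wavelengths_nm
  for (p in series)
    if (length(p$mu_a$wavelengths_nm) != length(g0) ||
        any(p$mu_a$wavelengths_nm != g0))
      stop("dilution series and water basis are on different grids",
           call. = FALSE)
  keep <- series[fg > 0]
  fgk <- fg[fg > 0]
  resid_per_unit <- mapply(function(p, f) {
    w_coef <- if (water == "known") p$water_fraction
              else sum(p$mu_a$values * W) / sum(W * W)
    pmax(p$mu_a$values - w_coef * W, 0) / f
  }, keep, fgk)
  est <- if (method == "residual") {
    rowMeans(resid_per_unit)
  } else {
    # per-wavelength LSQ of (mu_a - f_w W) on f_g, clipped at zero
    resid <- mapply(function(p, f) {
      w_coef <- if (water == "known") p$water_fraction
                else sum(p$mu_a$values * W) / sum(W * W)
      p$mu_a$values - w_coef * W
    }, keep, fgk)
    pmax(as.vector(resid %*% fgk) / sum(fgk^2), 0)
  }
  spectrum(g0, est, "specific-absorption mm^-1 per unit mass-fraction")
}

#' Synthetic gelatin absorption spectra
#'
#' Smooth per-unit-mass-fraction gelatin absorption models used by the
#' synthetic study generator: both gelatin types absorb most strongly at the
#' blue end and decay toward the near infrared; the research-grade model is
#' markedly stronger below 580 nm (the visibly yellow gelatin), the
#' store-bought model weaker and flatter.
#'
#' @param type `"store_bought"` or `"research_grade"`.
#' @param grid wavelength grid (nm).
#' @return Gelatin specific-absorption [spectrum()] per unit mass fraction.
#' @export
gelatin_spectrum <- function(type = c("store_bought", "research_grade"),
                             grid = default_grid()) {
  type <- match.arg(type)
  v <- switch(type,
    store_bought   = 0.020 * exp(-(grid - 450) / 130) + 0.0012,
    research_grade = 0.055 * exp(-(grid - 450) / 90) + 0.0015)
  spectrum(grid, v, "specific-absorption mm^-1 per unit mass-fraction")
}
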