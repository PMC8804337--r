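#' Unmix an absorption spectrum into chromophore concentrations
#'
#' Linear least-squares decomposition of a measured absorption spectrum
#' over a chromophore basis: solves `min || mu_a - E c ||^2` with the
#' basis matrix `E` (wavelengths x components), either unconstrained
#' (normal equations) or subject to `c >= 0` (non-negative least squares).
#' Uncertainties follow the residual-variance-scaled covariance
#' `sigma_i = sqrt([(E'E)^-1]_ii * chi2 / dof)` with `chi2` the residual
#' sum of squares and `dof = n_wavelengths - n_components`; components
#' pinned at zero by the non-negativity bound still receive their
#' unconstrained-covariance uncertainty (so "0 +/- sd" rows are
#' reproducible). Concentration units follow the basis tags: uM for
#' hemoglobin species, fractions for water and gelatin.
#'
#' @param mu_a absorption [spectrum()] (mm^-1).
#' @param basis a [chromophore_basis()] on the same grid.
#' @param components character vector of basis components to fit.
#' @param mode `"nonnegative"` (default) or `"unconstrained"`.
#' @return An object of class `concentration_fit`: `concentrations`,
#'   `uncertainties` (1 sigma, same units), `chi2`, `dof`, `mode`,
#'   `fitted` (spectrum), `residual` (vector).
#' @export
fit_concentrations <- function(mu_a, basis,
                               components = names(basis$components),
                               mode = c("nonnegative", "unconstrained")) {
  mode <- match.arg(mode)
  stopifnot(inherits(mu_a, "spectrum_sfd"),
            inherits(basis, "chromophore_basis"))
  if (length(mu_a$wavelengths_nm) != length(basis$grid) ||
      any(mu_a$wavelengths_nm != basis$grid))
    stop("spectrum and basis are on different grids", call. = FALSE)
  E <- basis_matrix(basis, components)
  p <- ncol(E)
  nwl <- nrow(E)
  if (nwl <= p)
    stop("need more wavelengths than fitted components", call. = FALSE)
  EtE <- crossprod(E)
  cn <- kappa(EtE, exact = TRUE)
  if (cn > 1e10) {
    cors <- stats::cor(E)
    diag(cors) <- 0
    worst <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "basis is numerically collinear over this grid (cond %.3g); most collinear pair: %s / %s",
      cn, components[worst[1]], components[worst[2]]), call. = FALSE)
  }
  y <- mu_a$values
  coef <- if (mode == "unconstrained") {
    as.vector(solve(EtE, crossprod(E, y)))
  } else {
    pracma::lsqnonneg(E, y)$x
  }
  names(coef) <- components
  resid <- y - as.vector(E %*% coef)
  chi2 <- sum(resid^2)
  dof <- nwl - p
  sigma <- sqrt(pmax(diag(solve(EtE)), 0) * chi2 / dof)
  names(sigma) <- components
  structure(list(concentrations = coef, uncertainties = sigma,
                 chi2 = chi2, dof = dof, mode = mode,
                 fitted = spectrum(basis$grid,
                                   pmax(as.vector(E %*% coef), 0),
                                   "absorption mm^-1"),
                 residual = resid),
            class = "concentration_fit")
}

#' @export
print.concentration_fit <- function(x, ...) {
  cat(sprintf("<concentration fit (%s), chi2 = %.4g, dof = %d>\n",
              x$mode, x$chi2, x$dof))
  for (nm in names(x$concentrations))
    cat(sprintf("  %-8s %10.4g +/- %.4g\n", nm,
                x$concentrations[[nm]], x$uncertainties[[nm]]))
  invisible(x)
}

#' Unmix a timecourse of optical-property measurements
#'
#' Applies [fit_concentrations()] independently at each timepoint; output
#' is ordered by time regardless of input order.
#'
#' @param timepoints numeric times (days).
#' @param props list of `optical_properties` (or absorption [spectrum()]s),
#'   one per timepoint.
#' @param basis a [chromophore_basis()].
#' @param components components to fit.
#' @param mode fit mode, as in [fit_concentrations()].
#' @return List of `list(timepoint, fit)` records sorted by timepoint.
#' @export
unmix_timecourse <- function(timepoints, props, basis,
                             components = names(basis$components),
                             mode = "nonnegative") {
  if (length(timepoints) < 1L || length(timepoints) != length(props))
    stop("need one optical-property set per timepoint", call. = FALSE)
  ord <- order(timepoints)
  lapply(ord, function(i) {
    mu_a <- props[[i]]
    if (inherits(mu_a, "optical_properties"))
      mu_a <- spectrum(mu_a$wavelengths_nm, pmax(mu_a$mu_a, 0),
                       "absorption mm^-1")
    fit <- tryCatch(
      fit_concentrations(mu_a, basis, components, mode),
      error = function(e) stop(sprintf("timepoint %g: %s", timepoints[i],
                                       conditionMessage(e)), call. = FALSE))
    list(timepoint = timepoints[i], fit = fit)
  })
}

#' Write a fitted timecourse as CSV
#'
#' Mirrors the study's concentration tables: one row per timepoint with
#' columns `timepoint,HbO2_uM,HbO2_sd,Hb_uM,Hb_sd,MetHb_uM,MetHb_sd,
#' water_frac,water_sd,chi2` (components absent from the fit are written
#' as NA).
#'
#' @param tc result of [unmix_timecourse()].
#' @param path CSV file path.
#' @export
write_timecourse_csv <- function(tc, path) {
  get <- function(fit, nm, what)
    if (nm %in% names(fit$concentrations)) fit[[what]][[nm]] else NA_real_
  d <- do.call(rbind, lapply(tc, function(rec) {
    f <- rec$fit
    data.frame(timepoint = rec$timepoint,
               HbO2_uM = get(f, "HbO2", "concentrations"),
               HbO2_sd = get(f, "HbO2", "uncertainties"),
               Hb_uM = get(f, "Hb", "concentrations"),
               Hb_sd = get(f, "Hb", "uncertainties"),
               MetHb_uM = get(f, "MetHb", "concentrations"),
               MetHb_sd = get(f, "MetHb", "uncertainties"),
               water_frac = get(f, "water", "concentrations"),
               water_sd = get(f, "water", "uncertainties"),
               chi2 = f$chi2)
  }))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
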