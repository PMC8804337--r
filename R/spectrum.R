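#' Wavelength-indexed spectrum
#'
#' The elementary container of the package: a strictly increasing wavelength
#' grid (nm) with one value per wavelength and a unit tag identifying what
#' the values are (absorption, specific absorption, reduced scattering, or
#' dimensionless).
#'
#' @param wavelengths_nm strictly increasing numeric vector, within
#'   \[250, 1100\] nm.
#' @param values numeric vector, same length as `wavelengths_nm`, finite.
#'   Absorption-typed spectra must be non-negative.
#' @param unit_tag one of `"absorption mm^-1"`,
#'   `"specific-absorption mm^-1.uM^-1"`,
#'   `"specific-absorption mm^-1 per unit volume-fraction"`,
#'   `"specific-absorption mm^-1 per unit mass-fraction"`,
#'   `"reduced-scattering mm^-1"`, `"dimensionless"`.
#' @return An object of class `spectrum_sfd`.
#' @export
spectrum <- function(wavelengths_nm, values,
                     unit_tag = c("absorption mm^-1",
                                  "specific-absorption mm^-1.uM^-1",
                                  "specific-absorption mm^-1 per unit volume-fraction",
                                  "specific-absorption mm^-1 per unit mass-fraction",
                                  "reduced-scattering mm^-1",
                                  "dimensionless")) {
  unit_tag <- match.arg(unit_tag)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.numeric(values)
  if (length(values) != length(wavelengths_nm))
    stop("values and wavelengths_nm must have equal length", call. = FALSE)
  if (length(wavelengths_nm) < 1L || any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (min(wavelengths_nm) < 250 || max(wavelengths_nm) > 1100)
    stop("wavelengths must lie within [250, 1100] nm", call. = FALSE)
  if (any(!is.finite(values)))
    stop("spectrum values must be finite", call. = FALSE)
  if (grepl("absorption", unit_tag) && any(values < 0))
    stop("absorption-typed spectrum values must be non-negative", call. = FALSE)
  structure(list(wavelengths_nm = wavelengths_nm, values = values,
                 unit_tag = unit_tag),
            class = "spectrum_sfd")
}

#' @export
print.spectrum_sfd <- function(x, ...) {
  cat(sprintf("<spectrum: %d points, %.1f-%.1f nm, %s>\n",
              length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm), x$unit_tag))
  invisible(x)
}

#' Linearly resample a spectrum onto a new wavelength grid
#'
#' Exact on shared nodes, linear (hence monotone) between nodes.
#' Extrapolation is refused: the target grid must lie within the native span.
#'
#' @param x a [spectrum()].
#' @param target_grid strictly increasing wavelengths (nm).
#' @return A [spectrum()] on `target_grid` with the unit tag preserved.
#' @export
resample_spectrum <- function(x, target_grid) {
  stopifnot(inherits(x, "spectrum_sfd"))
  target_grid <- as.numeric(target_grid)
  if (min(target_grid) < min(x$wavelengths_nm) - 1e-9 ||
      max(target_grid) > max(x$wavelengths_nm) + 1e-9)
    stop(sprintf(
      "resampling target [%g, %g] nm outside native span [%g, %g] nm",
      min(target_grid), max(target_grid),
      min(x$wavelengths_nm), max(x$wavelengths_nm)), call. = FALSE)
  v <- stats::approx(x$wavelengths_nm, x$values, xout = target_grid,
                     method = "linear", rule = 1)$y
  spectrum(target_grid, v, x$unit_tag)
}

#' Read a spectrum from a two-column CSV
#'
#' Expects columns `wavelength_nm,value`, a mandatory header row, and
#' optional leading `#` comment lines that may carry a
#' `# unit_tag: <tag>` metadata line.
#'
#' @param path CSV file path.
#' @param unit_tag override for the unit tag; default reads it from the
#'   `# unit_tag:` comment, falling back to `"dimensionless"`.
#' @return A [spectrum()].
#' @export
read_spectrum_csv <- function(path, unit_tag = NULL) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  comments <- lines[startsWith(lines, "#")]
  if (is.null(unit_tag)) {
    m <- grep("^#\\s*unit_tag:", comments, value = TRUE)
    unit_tag <- if (length(m)) trimws(sub("^#\\s*unit_tag:", "", m[1]))
                else "dimensionless"
  }
  d <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  if (!all(c("wavelength_nm", "value") %in% names(d)))
    stop("spectrum CSV must have columns wavelength_nm,value", call. = FALSE)
  spectrum(d$wavelength_nm, d$value, unit_tag)
}

#' Write a spectrum to CSV
#'
#' Inverse of [read_spectrum_csv()]; values are written with 10 significant
#' digits so the round trip is value-exact at that precision.
#'
#' @param x a [spectrum()].
#' @param path output file path.
#' @export
write_spectrum_csv <- function(x, path) {
  stopifnot(inherits(x, "spectrum_sfd"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unit_tag: %s", x$unit_tag), con)
  utils::write.csv(
    data.frame(wavelength_nm = x$wavelengths_nm,
               value = signif(x$values, 10)),
    con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
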