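#' Spatial-frequency-domain diffuse reflectance (diffusion approximation)
#'
#' Closed-form diffuse reflectance of a homogeneous semi-infinite medium
#' under sinusoidal illumination at spatial frequency `fx`. With
#' `mu_tr = mu_a + mu_s'`, reduced albedo `a' = mu_s'/mu_tr` and
#' `mu_eff'(fx) = sqrt(3 mu_a mu_tr + (2 pi fx)^2)`,
#' `Rd = 3 A a' / ((mu_eff'/mu_tr + 1) (mu_eff'/mu_tr + 3A))`,
#' where `A = (1 - R_eff) / (2 (1 + R_eff))` and `R_eff` is the standard
#' cubic-in-1/n polynomial for the effective internal reflection
#' coefficient. The factor `2 pi` sits inside `mu_eff'`, i.e. `fx` is a
#' plain spatial frequency in mm^-1. Arguments recycle elementwise.
#'
#' @param mu_a absorption coefficient(s), mm^-1, > 0.
#' @param mu_s_prime reduced scattering coefficient(s), mm^-1, > 0.
#' @param fx spatial frequency(ies), mm^-1, >= 0.
#' @param n refractive index of the medium (default 1.4).
#' @return Reflectance value(s) in (0, 1).
#' @export
diffusion_reflectance <- function(mu_a, mu_s_prime, fx, n = 1.4) {
  if (any(mu_a <= 0) || any(mu_s_prime <= 0))
    stop("optical properties must be positive", call. = FALSE)
  if (any(fx < 0)) stop("spatial frequencies must be >= 0", call. = FALSE)
  A <- effective_A(n)
  mu_tr <- mu_a + mu_s_prime
  a_prime <- mu_s_prime / mu_tr
  x <- sqrt(3 * mu_a * mu_tr + (2 * pi * fx)^2) / mu_tr
  3 * A * a_prime / ((x + 1) * (x + 3 * A))
}

#' Boundary coefficient A from the refractive index
#'
#' `R_eff = -1.440 n^-2 + 0.710 n^-1 + 0.668 + 0.0636 n`, then
#' `A = (1 - R_eff) / (2 (1 + R_eff))`.
#'
#' @param n refractive index.
#' @return Boundary coefficient A.
#' @export
effective_A <- function(n) {
  r_eff <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  (1 - r_eff) / (2 * (1 + r_eff))
}

#' Default spatial-frequency set
#'
#' Five evenly spaced frequencies over 0 to 0.2 mm^-1.
#'
#' @return Numeric vector of spatial frequencies (mm^-1).
#' @export
default_frequencies <- function() seq(0, 0.2, by = 0.05)

#' Calibrated SFD measurement container
#'
#' Diffuse reflectance indexed by wavelength and spatial frequency.
#' Physically consistent homogeneous samples have reflectance
#' non-increasing along the frequency axis; violations are allowed (real
#' noisy data violate it) and surfaced by the inverse solver as a
#' `poor_fit` flag, not rejected here.
#'
#' @param wavelengths_nm wavelength grid (nm).
#' @param fx spatial frequencies (mm^-1), strictly increasing.
#' @param reflectance matrix (wavelength x frequency) with values in
#'   \[0, 1\].
#' @param reference calibration reference label.
#' @return An object of class `sfd_measurement`.
#' @export
sfd_measurement <- function(wavelengths_nm, fx, reflectance,
                            reference = "unspecified") {
  reflectance <- as.matrix(reflectance)
  if (nrow(reflectance) != length(wavelengths_nm) ||
      ncol(reflectance) != length(fx))
    stop("reflectance must be wavelength x frequency", call. = FALSE)
  if (any(diff(fx) <= 0))
    stop("spatial frequencies must be strictly increasing", call. = FALSE)
  if (any(reflectance < 0) || any(reflectance > 1))
    stop("reflectance values must lie in [0, 1]", call. = FALSE)
  structure(list(wavelengths_nm = as.numeric(wavelengths_nm),
                 fx = as.numeric(fx), reflectance = reflectance,
                 reference = reference),
            class = "sfd_measurement")
}

#' @export
print.sfd_measurement <- function(x, ...) {
  cat(sprintf("<SFD measurement: %d wavelengths x %d frequencies (%s)>\n",
              length(x$wavelengths_nm), length(x$fx), x$reference))
  invisible(x)
}

#' Calibrate raw intensities against a reference phantom
#'
#' `Rd_sample = (raw_sample / raw_reference) * Rd_model(reference)`
#' elementwise, where the model prediction for the reference phantom of
#' known optical properties comes from [diffusion_reflectance()]. Any
#' common gain cancels.
#'
#' @param raw_sample,raw_reference raw intensity matrices
#'   (wavelength x frequency), equal shapes; reference > 0 everywhere.
#' @param reference_mu_a,reference_mu_s_prime known reference optical
#'   properties per wavelength (mm^-1).
#' @param wavelengths_nm wavelength grid (nm).
#' @param fx spatial frequencies (mm^-1).
#' @param n refractive index.
#' @param reference label recorded on the output.
#' @return An [sfd_measurement()].
#' @export
calibrate_reflectance <- function(raw_sample, raw_reference,
                                  reference_mu_a, reference_mu_s_prime,
                                  wavelengths_nm, fx, n = 1.4,
                                  reference = "reference phantom") {
  raw_sample <- as.matrix(raw_sample)
  raw_reference <- as.matrix(raw_reference)
  if (!all(dim(raw_sample) == dim(raw_reference)))
    stop("raw matrices must share shape", call. = FALSE)
  bad <- which(raw_reference <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(
      "non-positive reference intensity at wavelength %g nm, fx %g mm^-1",
      wavelengths_nm[bad[1, 1]], fx[bad[1, 2]]), call. = FALSE)
  ref_rd <- outer(seq_along(wavelengths_nm), seq_along(fx),
                  function(i, j) diffusion_reflectance(
                    reference_mu_a[i], reference_mu_s_prime[i], fx[j], n))
  rd <- raw_sample / raw_reference * ref_rd
  sfd_measurement(wavelengths_nm, fx, pmin(pmax(rd, 0), 1),
                  reference = reference)
}

#' Monte Carlo reflectance oracle
#'
#' Independent photon-transport check on the diffusion forward model:
#' pencil-beam photons random-walk through a semi-infinite homogeneous
#' medium (Henyey-Greenstein phase function, g = 0.8, so
#' `mu_s = mu_s'/(1-g)`; refractive-index-mismatched Fresnel boundary),
#' the radially resolved diffuse exitance is accumulated, and spatial
#' frequencies are obtained by the zeroth-order Hankel transform
#' `Rd(fx) = sum_i w_i J0(2 pi fx r_i) / N`, evaluated photon-by-photon so
#' that `fx = 0` reduces exactly to the plain diffuse reflectance tally.
#' The same seed gives bitwise-identical output (own internal RNG,
#' independent of R's RNG state).
#'
#' @param mu_a,mu_s_prime optical properties (mm^-1), scalars.
#' @param fx spatial frequencies (mm^-1).
#' @param n refractive index.
#' @param photons number of photons (>= 1e4).
#' @param seed integer RNG seed.
#' @param g scattering anisotropy (default 0.8).
#' @return List with `fx`, `Rd` (estimates) and `se` (standard errors).
#' @export
mc_reflectance_oracle <- function(mu_a, mu_s_prime, fx, n = 1.4,
                                  photons = 1e5, seed = 1, g = 0.8) {
  if (photons < 1e4)
    stop("Monte Carlo oracle needs at least 1e4 photons", call. = FALSE)
  if (mu_a <= 0 || mu_s_prime <= 0)
    stop("optical properties must be positive", call. = FALSE)
  res <- mc_reflectance_cpp(mu_a, mu_s_prime, as.numeric(fx), n,
                            as.integer(photons), as.integer(seed), g)
  list(fx = as.numeric(fx), Rd = res$Rd, se = res$se)
}
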