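Package: sfdphantom
Title: Gelatin Tissue Phantom Design and Spatial Frequency Domain
    Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs gelatin/Intralipid tissue-simulating phantoms with
    adjustable water and hemoglobin fractions and implements their optical
    characterization chain: a diffusion-approximation forward model of
    spatial-frequency-domain diffuse reflectance validated against a
    bundled Monte Carlo photon-transport oracle, per-wavelength
    lookup-table inversion to absorption and reduced scattering,
    linear least-squares spectral unmixing into chromophore
    concentrations (oxy-, deoxy- and methemoglobin, water, gelatin) with
    chi-squared-based uncertainties, a residual-based gelatin-spectrum
    estimator, and water-fraction regression and stability-period
    analyses. Includes a seeded synthetic study generator emulating
    batch, spatial and temporal variability so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
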