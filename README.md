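# sfdphantom

Design and spatial-frequency-domain characterization of gelatin
tissue-simulating phantoms with adjustable water and hemoglobin content.

## What it does, and for whom

Phantoms that mimic inflamed or oedematous tissue need two independently
controllable absorption handles — water fraction and hemoglobin — on top of
a fixed, tissue-like scattering background. A gelatin/Intralipid matrix
provides exactly that: the water-to-gelatin ratio sets the water fraction
while a constant 10 wt% of Intralipid 20% pins the scattering. This package
is for biomedical-optics groups who build such phantoms and characterize
them with spatial frequency domain spectroscopy (SFDS); it implements the
complete computational chain so that every stage can be exercised, tested
and rehearsed on synthetic data before an instrument ever runs.

The chain, in the field's standard notation:

* **Recipes.** Weight-percent compositions → total water fraction
  ((w + 0.8·i)/100, since Intralipid 20% is 80% water by mass) and nominal
  chromophore concentrations (hemoglobin tetramer, MW 64,500 g/mol, in µM).
* **Forward model.** Diffusion-approximation diffuse reflectance of a
  homogeneous semi-infinite medium under sinusoidal illumination:
  with μtr = μa + μs′, a′ = μs′/μtr and
  μeff′(fx) = √(3 μa μtr + (2π fx)²),

  Rd(fx) = 3 A a′ / ((μeff′/μtr + 1)(μeff′/μtr + 3A)),

  A = (1 − Reff)/(2(1 + Reff)), n = 1.40 by default, five frequencies over
  0–0.2 mm⁻¹. A compiled Monte Carlo photon-transport oracle
  (Henyey–Greenstein, g = 0.8, mismatched Fresnel boundary, photon-wise
  Hankel transform) quantifies the approximation error.
* **Inverse solver.** Per-wavelength lookup-table inversion of
  multi-frequency reflectance to (μa, μs′) with local refinement on the
  continuous forward model — no spectral priors, wavelengths fully
  independent.
* **Unmixing.** Linear least squares of μa(λ) over tabulated
  specific-absorption spectra of HbO₂, Hb, MetHb, water and gelatin —
  non-negative (NNLS) or unconstrained — with χ²-scaled 1σ uncertainties,
  plus the residual-based estimator of the gelatin spectrum from a
  water/gelatin dilution series.
* **Analyses.** Estimated-vs-total water-fraction regression (ordinary and
  through-origin) and the 10% stability-period rule for chromophore drift.
* **Synthetic studies.** A seeded generator producing full studies —
  recipe ladder, batches, spatial repeats, HbO₂→MetHb conversion, early
  water loss, reflectance noise — so the acceptance surface is parameter
  recovery.

## Worked example

```r
library(sfdphantom)

# the four-level water ladder at fixed 10 wt% Intralipid 20%
sapply(water_ladder_recipes(), total_water_fraction)
#> [1] 0.97 0.88 0.68 0.48

# forward-mix an absorption spectrum, then unmix it
basis <- make_reference_basis(gelatin_spectra = list(
  gelatin = gelatin_spectrum("store_bought")))
mu_a <- expected_absorption(basis, c(HbO2 = 2.0, MetHb = 1.1, water = 0.8))
fit_concentrations(mu_a, basis, c("HbO2", "Hb", "MetHb", "water", "gelatin"),
                   mode = "nonnegative")
#> <concentration fit (nonnegative), chi2 = 5.547e-34, dof = 271>
#>   HbO2              2 +/- 6.579e-17
#>   Hb                0 +/- 6.771e-17
#>   MetHb           1.1 +/- 2.536e-16
#>   water           0.8 +/- 6.338e-18
#>   gelatin   2.735e-16 +/- 3.97e-17
```

The fit recovers the generating concentrations exactly (2 µM HbO₂, 1.1 µM
MetHb, water fraction 0.8); deoxyhemoglobin and gelatin, absent from the
mixture, are pinned at zero yet still carry uncertainties — the "0 ± sd"
convention of hemoglobin concentration tables.

A full synthetic water-ladder study — simulate, invert, unmix, regress:

```r
cfg <- synthetic_study_config(timepoints = 0, seed = 42)
res <- analyze_water_study(generate_study(cfg))
res$regression
#> <water regression: y = 1.083*x -0.05533, R2 = 0.9832, RMSE = 0.0267, n = 4>
res$regression_constrained
#> <water regression (through origin): y = 1.014*x +0, R2 = 0.979, RMSE = 0.03, n = 4>
```

Under the default noise model (1% reflectance noise, 5% batch and 3%
spatial variability over 3 batches × 3 repeats) the recovered water
fractions track the fabricated ones with a slope near unity; with all
noise switched off the regression is the identity to five decimal places.

A command-line surface over the same functions is available through
`run_pipeline()` and the wrapper script `inst/scripts/sfdphantom.R`
(subcommands `design`, `simulate`, `invert`, `unmix`, `fit-gelatin`,
`stability`, `report`).

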