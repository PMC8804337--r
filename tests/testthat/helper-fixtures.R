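# shared fixtures: coarse grids keep the suite fast without changing the
# physics; the full 2-nm grid is exercised where resolution matters
coarse_grid <- seq(450, 1000, by = 10)

coarse_basis <- function(gelatin = TRUE) {
  gel <- if (gelatin)
    list(gelatin = gelatin_spectrum("store_bought", coarse_grid)) else NULL
  make_reference_basis(coarse_grid, gelatin_spectra = gel)
}

# one LUT per session, shared across tests
shared_lut <- local({
  lut <- NULL
  function() {
    if (is.null(lut)) lut <<- build_lookup()
    lut
  }
})

# noiseless single-shot ladder study config
noiseless_ladder_config <- function(grid = coarse_grid, seed = 1)
  synthetic_study_config(noise_sd = 0, batch_sd = 0, spatial_sd = 0,
                         n_batches = 1, n_spatial_repeats = 1,
                         timepoints = 0, water_early_loss = 0,
                         grid = grid, seed = seed)
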