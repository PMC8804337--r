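test_that("hemoglobin drift starts at the initial state and conserves total heme", {
  times <- c(0, 0.5, 1, 2, 4)
  d <- methb_drift(2.5, 0.7, 0.8, times)
  expect_equal(c(d$HbO2[1], d$MetHb[1]), c(2.5, 0.7))
  expect_equal(d$HbO2 + d$MetHb, rep(3.2, 5))
  # half-life check
  h <- methb_drift(2.5, 0, log(2), 1)
  expect_equal(h$HbO2, 1.25)
  expect_error(methb_drift(2.5, 0.7, 0.8, -1), "negative time")
  expect_error(methb_drift(-1, 0, 0.8, 0), "non-negative")
})

test_that("water drift declines linearly to the plateau and holds", {
  expect_equal(water_drift(0.9, times = 0), 0.9)
  expect_equal(water_drift(0.9, times = 2), 0.9 * 0.92)
  expect_equal(water_drift(0.9, times = c(2, 5, 10)), rep(0.9 * 0.92, 3))
  expect_equal(water_drift(0.9, times = 1), 0.9 * 0.96)
  expect_error(water_drift(0.9, early_loss = 1), "early_loss")
})

test_that("study generation is bit-reproducible from (config, seed)", {
  cfg <- synthetic_study_config(grid = coarse_grid, timepoints = c(0, 1),
                                n_batches = 2, n_spatial_repeats = 2,
                                seed = 7)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$cells, s2$cells)
  s3 <- generate_study(synthetic_study_config(grid = coarse_grid,
                                              timepoints = c(0, 1),
                                              n_batches = 2,
                                              n_spatial_repeats = 2,
                                              seed = 8))
  expect_false(identical(s1$cells, s3$cells))
  # observations satisfy the physical-range invariant
  for (cell in s1$cells) {
    expect_true(all(cell$obs$reflectance >= 0 & cell$obs$reflectance <= 1))
  }
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(3)
  set.seed(123)
  invisible(generate_study(noiseless_ladder_config()))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("hemoglobin scenarios set the initial methemoglobin state", {
  cfg_f <- synthetic_study_config(recipes = water_ladder_recipes()[2],
                                  hemoglobin_scenario = "ferrous_powder",
                                  grid = coarse_grid, timepoints = 0,
                                  n_batches = 1, n_spatial_repeats = 1,
                                  noise_sd = 0, batch_sd = 0,
                                  spatial_sd = 0, seed = 1)
  truth_f <- generate_study(cfg_f)$cells[[1]]$truth$concentrations
  expect_gt(truth_f[["MetHb"]], 0)

  cfg_w <- synthetic_study_config(recipes = water_ladder_recipes()[2],
                                  hemoglobin_scenario = "whole_blood",
                                  grid = coarse_grid, timepoints = 0,
                                  n_batches = 1, n_spatial_repeats = 1,
                                  noise_sd = 0, batch_sd = 0,
                                  spatial_sd = 0, seed = 1)
  truth_w <- generate_study(cfg_w)$cells[[1]]$truth$concentrations
  expect_equal(truth_w[["MetHb"]], 0)
  expect_gt(truth_w[["HbO2"]], 0)
})

test_that("noiseless single-batch study is recovered end to end within 1e-3", {
  study <- generate_study(noiseless_ladder_config())
  lut <- shared_lut()
  for (cell in study$cells) {
    inv <- invert_reflectance(cell$obs, lut)
    truth <- cell$truth$concentrations
    fit <- fit_concentrations(
      spectrum(inv$wavelengths_nm, pmax(inv$mu_a, 0), "absorption mm^-1"),
      study$basis, names(truth), "unconstrained")
    rel <- abs(fit$concentrations - truth) / truth
    expect_lt(max(rel), 1e-3)
  }
})

test_that("recovered batch variability matches the configured batch sd", {
  # batch factors only: no spatial or reflectance noise
  lut <- shared_lut()
  batch_sd <- 0.05
  sds <- vapply(1:60, function(s) {
    cfg <- synthetic_study_config(recipes = water_ladder_recipes()[2],
                                  noise_sd = 0, batch_sd = batch_sd,
                                  spatial_sd = 0, n_batches = 3,
                                  n_spatial_repeats = 1, timepoints = 0,
                                  water_early_loss = 0,
                                  grid = coarse_grid, seed = s)
    a <- analyze_water_study(generate_study(cfg), lut = lut)
    stats::sd(log(a$per_cell$water))
  }, numeric(1))
  # E[sd of 3 lognormal draws] = c4(3) * sigma with c4(3) = 0.8862
  expect_equal(mean(sds) / 0.8862, batch_sd, tolerance = 0.3)
})

test_that("study bundles round-trip their reflectance through disk", {
  cfg <- synthetic_study_config(recipes = water_ladder_recipes()[1:2],
                                grid = coarse_grid, timepoints = 0,
                                n_batches = 1, n_spatial_repeats = 1,
                                seed = 5)
  study <- generate_study(cfg)
  dir <- withr::local_tempdir()
  write_study_bundle(study, dir)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 5)
  expect_length(manifest$cells, 2)
  back <- read_reflectance_csv(file.path(dir, manifest$cells[[1]]))
  expect_equal(back$reflectance,
               signif(study$cells[[1]]$obs$reflectance, 10),
               ignore_attr = TRUE)
})
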