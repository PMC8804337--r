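test_that("noiseless mixtures are recovered exactly with zero components pinned", {
  basis <- make_reference_basis(gelatin_spectra = list(
    gelatin = gelatin_spectrum("store_bought")))
  truth <- c(HbO2 = 2.0, Hb = 0, MetHb = 1.1, water = 0.8, gelatin = 0)
  mu_a <- expected_absorption(basis, truth[truth > 0])
  fit <- fit_concentrations(mu_a, basis,
                            c("HbO2", "Hb", "MetHb", "water", "gelatin"),
                            mode = "nonnegative")
  expect_equal(unname(fit$concentrations), unname(truth), tolerance = 1e-8)
  expect_lt(fit$chi2, 1e-16)
  # pinned-at-zero components still carry an uncertainty
  expect_gt(fit$uncertainties[["Hb"]], 0)
  expect_equal(fit$dof, length(basis$grid) - 5L)
})

test_that("unconstrained water-only fit can exceed unity", {
  basis <- coarse_basis(gelatin = FALSE)
  mu_a <- spectrum(coarse_grid, 1.09 * basis$components$water$values,
                   "absorption mm^-1")
  fit <- fit_concentrations(mu_a, basis, "water", mode = "unconstrained")
  expect_equal(fit$concentrations[["water"]], 1.09, tolerance = 1e-10)
})

test_that("single-component projection is exact for any scale", {
  basis <- coarse_basis(gelatin = FALSE)
  for (k in c(0.25, 1, 7.5)) {
    mu_a <- spectrum(coarse_grid, k * basis$components$MetHb$values,
                     "absorption mm^-1")
    fit <- fit_concentrations(mu_a, basis, "MetHb")
    expect_equal(fit$concentrations[["MetHb"]], k, tolerance = 1e-10)
  }
})

test_that("nonnegative mode never returns negatives; unconstrained matches normal equations", {
  basis <- coarse_basis()
  comps <- c("HbO2", "Hb", "MetHb", "water", "gelatin")
  E <- basis_matrix(basis, comps)
  set.seed(13)
  for (i in 1:10) {
    y <- pmax(as.vector(E %*% runif(5, 0, 2)) +
                rnorm(length(coarse_grid), 0, 2e-4), 0)
    mu_a <- spectrum(coarse_grid, y, "absorption mm^-1")
    nn <- fit_concentrations(mu_a, basis, comps, "nonnegative")
    expect_true(all(nn$concentrations >= 0))
    un <- fit_concentrations(mu_a, basis, comps, "unconstrained")
    normal_eq <- solve(crossprod(E), crossprod(E, y))
    expect_equal(unname(un$concentrations), as.vector(normal_eq),
                 tolerance = 1e-10)
  }
})

test_that("a collinear basis is refused with the offending pair named", {
  w <- gelatin_spectrum("store_bought", coarse_grid)
  basis <- chromophore_basis(list(a = w, b = w))
  mu_a <- spectrum(coarse_grid, w$values, "absorption mm^-1")
  expect_error(fit_concentrations(mu_a, basis, c("a", "b")),
               "collinear.*a.*b")
})

test_that("reported uncertainties track empirical scatter under additive noise", {
  basis <- coarse_basis()
  comps <- c("HbO2", "MetHb", "water", "gelatin")
  truth <- c(HbO2 = 2.0, MetHb = 1.1, water = 0.8, gelatin = 0.1)
  clean <- expected_absorption(basis, truth)$values
  sigma <- 2e-4
  set.seed(31)
  n_rep <- 200
  est <- matrix(NA_real_, n_rep, length(comps))
  rep_sd <- rep(NA_real_, n_rep)
  for (i in seq_len(n_rep)) {
    y <- pmax(clean + rnorm(length(clean), 0, sigma), 0)
    fit <- fit_concentrations(spectrum(coarse_grid, y, "absorption mm^-1"),
                              basis, comps, "unconstrained")
    est[i, ] <- fit$concentrations
    rep_sd[i] <- fit$uncertainties[["HbO2"]]
  }
  expect_equal(mean(rep_sd), sd(est[, 1]), tolerance = 0.2)
})

test_that("timecourse unmixing is per-timepoint, time-sorted, and tracks drift", {
  basis <- coarse_basis(gelatin = FALSE)
  times <- c(2, 4, 24, 48, 72) / 24
  hb <- methb_drift(2.5, 0.7, 1.0, times)
  specs <- lapply(seq_along(times), function(i)
    expected_absorption(basis, c(HbO2 = hb$HbO2[i], MetHb = hb$MetHb[i],
                                 water = 0.8)))
  comps <- c("HbO2", "Hb", "MetHb", "water")

  tc <- unmix_timecourse(times, specs, basis, comps)
  methb_hat <- vapply(tc, function(r) r$fit$concentrations[["MetHb"]],
                      numeric(1))
  hbo2_hat <- vapply(tc, function(r) r$fit$concentrations[["HbO2"]],
                     numeric(1))
  expect_true(all(diff(methb_hat) > 0))
  expect_true(all(diff(hbo2_hat) < 0))

  # permuted input comes back time-sorted
  perm <- c(3, 1, 5, 2, 4)
  tc_p <- unmix_timecourse(times[perm], specs[perm], basis, comps)
  expect_equal(vapply(tc_p, `[[`, numeric(1), "timepoint"), times)
  expect_equal(vapply(tc_p, function(r) r$fit$concentrations[["MetHb"]],
                      numeric(1)), methb_hat)

  # singleton equals a direct fit
  one <- unmix_timecourse(times[1], specs[1], basis, comps)
  expect_length(one, 1)
  expect_equal(one[[1]]$fit$concentrations,
               fit_concentrations(specs[[1]], basis, comps)$concentrations)

  f <- withr::local_tempfile(fileext = ".csv")
  write_timecourse_csv(tc, f)
  d <- read.csv(f)
  expect_equal(d$timepoint, times)
  expect_equal(d$MetHb_uM, methb_hat, tolerance = 1e-6)
})
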