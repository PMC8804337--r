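test_that("lookup table entries equal direct forward evaluations", {
  lut <- build_lookup(grid_sizes = c(16, 16))
  expect_true(all(lut$table > 0 & lut$table < 1))
  set.seed(2)
  for (k in sample(nrow(lut$nodes), 10)) {
    direct <- diffusion_reflectance(lut$nodes[k, "mu_a"],
                                    lut$nodes[k, "mu_s"], lut$fx, lut$n)
    expect_equal(unname(lut$table[k, ]), direct, tolerance = 1e-14)
  }
  expect_error(build_lookup(mu_a_range = c(0.1, 0.1)), "degenerate")
  expect_error(build_lookup(grid_sizes = c(8, 16)), ">= 16")
})

test_that("refining the grid leaves shared nodes unchanged", {
  # a log-spaced grid of 2n-1 points contains the n-point grid
  lut16 <- build_lookup(grid_sizes = c(16, 16))
  lut31 <- build_lookup(grid_sizes = c(31, 31))
  ia <- match(round(log(lut16$mu_a_grid), 10),
              round(log(lut31$mu_a_grid), 10))
  expect_false(anyNA(ia))
  expect_equal(lut31$mu_a_grid[ia], lut16$mu_a_grid, tolerance = 1e-12)
})

test_that("noiseless forward-inverse round trip recovers within 1%", {
  lut <- shared_lut()
  truths <- expand.grid(mu_a = 10^seq(log10(0.005), log10(0.05), length = 5),
                        mu_s = 10^seq(log10(0.5), log10(3), length = 5))
  rd <- t(apply(truths, 1, function(p)
    diffusion_reflectance(p[1], p[2], lut$fx)))
  meas <- sfd_measurement(seq(500, by = 2, length.out = nrow(truths)),
                          lut$fx, rd)
  inv <- invert_reflectance(meas, lut)
  expect_lt(max(abs(inv$mu_a - truths$mu_a) / truths$mu_a), 0.01)
  expect_lt(max(abs(inv$mu_s_prime - truths$mu_s) / truths$mu_s), 0.01)
  expect_true(all(inv$flags == "ok"))
})

test_that("unphysical rising reflectance is flagged poor_fit, not rejected", {
  lut <- shared_lut()
  rd_ok <- diffusion_reflectance(0.01, 1.5, lut$fx)
  rd_bad <- rev(rd_ok)  # rises with frequency
  meas <- sfd_measurement(c(500, 502), lut$fx, rbind(rd_ok, rd_bad))
  inv <- invert_reflectance(meas, lut)
  expect_equal(inv$flags, c("ok", "poor_fit"))
})

test_that("estimates clamped at the table edge are flagged at_bound", {
  lut <- shared_lut()
  rd <- diffusion_reflectance(5, 1.5, lut$fx)  # mu_a above the LUT maximum
  meas <- sfd_measurement(500, lut$fx, matrix(rd, 1))
  inv <- invert_reflectance(meas, lut)
  expect_true(inv$flags %in% c("at_bound", "poor_fit"))
})

test_that("nearest-node search without refinement recovers exact nodes", {
  lut <- build_lookup(grid_sizes = c(16, 16))
  i <- 7; j <- 9
  rd <- diffusion_reflectance(lut$mu_a_grid[i], lut$mu_s_prime_grid[j],
                              lut$fx)
  meas <- sfd_measurement(500, lut$fx, matrix(rd, 1))
  inv <- invert_reflectance(meas, lut, refine = FALSE)
  expect_equal(inv$mu_a, lut$mu_a_grid[i], tolerance = 1e-12)
  expect_equal(inv$mu_s_prime, lut$mu_s_prime_grid[j], tolerance = 1e-12)
})

test_that("wavelengths are inverted independently: permutation and spike", {
  lut <- shared_lut()
  mu_a <- c(0.01, 0.012, 0.2, 0.011, 0.013)  # spike at the middle wavelength
  mu_s <- rep(1.5, 5)
  rd <- t(vapply(1:5, function(i)
    diffusion_reflectance(mu_a[i], mu_s[i], lut$fx),
    numeric(length(lut$fx))))
  meas <- sfd_measurement(seq(500, 540, 10), lut$fx, rd)
  inv <- invert_reflectance(meas, lut)
  # spike recovered, no smoothing
  expect_equal(inv$mu_a, mu_a, tolerance = 1e-3)

  perm <- c(3, 1, 5, 2, 4)
  meas_p <- sfd_measurement(seq(500, 540, 10), lut$fx, rd[perm, ])
  inv_p <- invert_reflectance(meas_p, lut)
  expect_equal(inv_p$mu_a, inv$mu_a[perm], tolerance = 1e-12)
  expect_equal(inv_p$mu_s_prime, inv$mu_s_prime[perm], tolerance = 1e-12)
})

test_that("frequency mismatch between measurement and LUT is an interface error", {
  lut <- shared_lut()
  meas <- sfd_measurement(500, c(0, 0.1), matrix(c(0.5, 0.4), 1))
  expect_error(invert_reflectance(meas, lut), "frequencies")
})

test_that("reflectance and optical-property CSVs round-trip", {
  lut <- shared_lut()
  rd <- rbind(diffusion_reflectance(0.01, 1.5, lut$fx),
              diffusion_reflectance(0.03, 1.0, lut$fx))
  meas <- sfd_measurement(c(500, 600), lut$fx, rd)
  f <- withr::local_tempfile(fileext = ".csv")
  write_reflectance_csv(meas, f)
  back <- read_reflectance_csv(f)
  expect_equal(back$reflectance, signif(meas$reflectance, 10),
               ignore_attr = TRUE)

  inv <- invert_reflectance(meas, lut)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_optical_properties_csv(inv, f2)
  back2 <- read_optical_properties_csv(f2)
  expect_equal(back2$mu_a, signif(inv$mu_a, 10))
  expect_equal(back2$flags, inv$flags)
})
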