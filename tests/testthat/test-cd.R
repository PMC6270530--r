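test_that("mean residue molar ellipticity normalization", {
  grid <- seq(190, 260, 0.5)
  zero <- raw_cd_spectrum(grid, rep(0, length(grid)), 45e-6, 0.2, 11)
  expect_equal(normalize_ellipticity(zero)$theta, rep(0, length(grid)))

  one <- raw_cd_spectrum(c(203, 204), c(-16.14, -16.14), 45e-6, 0.2, 11)
  expect_equal(normalize_ellipticity(one)$theta[1],
               -16.14 / (10 * 45e-6 * 0.2 * 11))
  expect_equal(round(normalize_ellipticity(one)$theta[1]), -16303)

  # linear in 1/C: doubling the concentration halves [theta]
  two <- raw_cd_spectrum(c(203, 204), c(-16.14, -16.14), 90e-6, 0.2, 11)
  expect_equal(normalize_ellipticity(two)$theta,
               normalize_ellipticity(one)$theta / 2)
  expect_error(raw_cd_spectrum(c(203, 204), c(1, 1), -1, 0.2, 11),
               "metadata")
})

test_that("normalization round-trips exactly", {
  cfg <- synth_config(seed = 7, cd_noise_sd = 150)
  raw <- synth_cd(0.6, cfg)
  back <- denormalize_ellipticity(normalize_ellipticity(raw))
  expect_equal(back$signal_mdeg, raw$signal_mdeg)
  expect_equal(back$wavelengths, raw$wavelengths)
})

test_that("interpolation is exact at nodes and linear between", {
  sp <- normalize_ellipticity(
    raw_cd_spectrum(c(200, 210, 220), c(-1, -3, -2), 1e-5, 1, 10))
  expect_equal(cd_value_at(sp, 210), sp$theta[2])
  expect_equal(cd_value_at(sp, 205), mean(sp$theta[1:2]))
  expect_error(cd_value_at(sp, 190), "outside")

  # quadratic sampled at 0.5 nm: linear interpolation error <= h^2/8 * |f''|
  grid <- seq(190, 260, 0.5)
  quad <- function(l) -20000 + 30 * (l - 210)^2
  spq <- structure(list(wavelengths = grid, theta = quad(grid),
                        concentration_M = 1e-5, path_cm = 1,
                        n_residues = 10, solvent = ""),
                   class = "cd_spectrum")
  q <- seq(195.1, 250.7, by = 3.3)
  expect_lt(max(abs(cd_value_at(spq, q) - quad(q))),
            0.5^2 / 8 * 2 * 30 + 1e-9)
})

test_that("single-wavelength helicity estimator", {
  expect_equal(helical_fraction(640, 11), 0)
  expect_equal(helical_fraction(-42500 * (8 / 11), 11), 1)
  expect_equal(helical_fraction(-25000, 11),
               (-25000 - 640) / (-42500 * (8 / 11) - 640))
  expect_equal(round(helical_fraction(-25000, 11), 3), 0.813)
  # clipped outside the model range
  expect_equal(helical_fraction(5000, 11), 0)
  expect_equal(helical_fraction(-40000, 11), 1)
  # monotone non-increasing in theta_222
  th <- seq(-32000, 2000, length.out = 50)
  expect_true(all(diff(helical_fraction(th, 11)) <= 0))
})

test_that("theta product preserves sign and magnitude", {
  expect_equal(theta_product(-20000, -22000), 4.4e8)
  expect_equal(theta_product(0, -12345), 0)
  # deeper 222 trough at fixed negative 208 increases the product
  expect_gt(theta_product(-25000, -20000), theta_product(-20000, -20000))
})

test_that("helicity recovery on noiseless two-state spectra", {
  cfg <- synth_config(seed = 3, cd_noise_sd = 0)
  for (f in c(0, 0.25, 0.5, 0.8, 1)) {
    sp <- normalize_ellipticity(synth_cd(f, cfg))
    expect_equal(helical_fraction(cd_value_at(sp, 222), 11), f,
                 tolerance = 0.02)
  }
})

test_that("isodichroic point of a two-state family", {
  cfg <- synth_config(seed = 5, cd_noise_sd = 0)
  fs <- c(0, 0.25, 0.5, 0.75, 1)
  fam <- lapply(fs, function(f) normalize_ellipticity(synth_cd(f, cfg)))

  # oracle: solve B_H(lambda) = B_C(lambda) numerically
  cross <- uniroot(function(l) {
    b <- cd_two_state_basis(l, 11)
    b$helix - b$coil
  }, c(198, 210))$root
  found <- isodichroic_point(fam)
  expect_lt(abs(found - cross), 0.5)   # grid resolution

  # identical spectra: zero deviation everywhere, tie breaks to window start
  same <- rep(fam[3], 3)
  expect_equal(isodichroic_point(same, window = c(195, 215)), 195)

  # small independent noise moves the detected point < 1 nm
  cfgn <- synth_config(seed = 5, cd_noise_sd = 150)
  noisy <- lapply(seq_along(fs), function(i) {
    normalize_ellipticity(synth_cd(fs[i], cfgn, seed = 100 + i))
  })
  expect_lt(abs(isodichroic_point(noisy) - cross), 1)

  # differing grids are an error, and < 3 spectra are rejected
  off <- resample_cd(fam[[1]], range = c(195, 250))
  expect_error(isodichroic_point(list(off, fam[[2]], fam[[3]])), "grid")
  expect_error(isodichroic_point(fam[1:2]))

  # a family with no common crossing returns NA
  shifted <- fam
  shifted[[1]]$theta <- shifted[[1]]$theta + 8000
  shifted[[3]]$theta <- shifted[[3]]$theta - 8000
  expect_true(is.na(isodichroic_point(shifted)))
})

test_that("cd_summary collects the scalar descriptors", {
  cfg <- synth_config(seed = 9, cd_noise_sd = 0)
  s <- cd_summary(normalize_ellipticity(synth_cd(0.75, cfg)))
  expect_equal(s$theta_product, s$theta_222 * s$theta_208)
  expect_equal(s$helical_fraction, 0.75, tolerance = 0.02)
  expect_lt(s$theta_222, 0)
  expect_lt(s$theta_208, 0)
})
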