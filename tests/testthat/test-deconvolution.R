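# Compact settings used by the unit tests: a narrower m/z window than the
# full-range defaults keeps each case fast while exercising the same code.
test_config <- function(...) {
  deconv_config(mz_range = c(4000, 12000), z_range = c(5, 30), ...)
}

sim_ensemble <- function(masses, abundances, z_center = 14, z_sigma = 1.2) {
  simulate_spectrum(tibble::tibble(mass = masses, abundance = abundances),
                    charge_model(z_center, z_sigma),
                    mz_range = c(4000, 12000), mz_step = 0.25)
}

test_that("deconvolution conserves total intensity", {
  sp <- sim_ensemble(c(99600, 100350), c(0.6, 0.4))
  zc <- deconvolve(sp, test_config())
  expect_equal(sum(zc$mass_spectrum$intensity), sum(sp$intensity),
               tolerance = 1e-6)
  expect_equal(sum(zc$charge_marginal$intensity), sum(sp$intensity),
               tolerance = 1e-6)
})

test_that("a known single species is recovered at its neutral mass", {
  sp <- sim_ensemble(99600, 1)
  zc <- deconvolve(sp, test_config())
  apex <- zc$mass_spectrum$mass[which.max(zc$mass_spectrum$intensity)]
  expect_lt(abs(apex - 99600), 2)
  pk <- pick_peaks(zc, 0.5)
  expect_lt(abs(pk$mass[which.max(pk$height)] - 99600), 2)
})

test_that("a single known charge state maps back exactly", {
  sp <- simulate_spectrum(tibble::tibble(mass = 99600, abundance = 1),
                          charge_model(14, 0.2, 14, 14),
                          mz_range = c(6000, 8000), mz_step = 0.05)
  apex_mz <- sp$mz[which.max(sp$intensity)]
  zc <- deconvolve(sp, deconv_config(mz_range = c(6000, 8000),
                                     z_range = c(14, 14)))
  expect_equal(average_charge(zc), 14)
  expect_equal(zc$charge_marginal$intensity[1], sum(sp$intensity),
               tolerance = 1e-9)
  apex_mass <- zc$mass_spectrum$mass[which.max(zc$mass_spectrum$intensity)]
  expect_lt(abs(apex_mass - 14 * (apex_mz - 1.00728)), 2)
})

test_that("two resolved species keep their abundance ratio", {
  sp <- sim_ensemble(c(99600, 100350), c(0.6, 0.4))
  zc <- deconvolve(sp, test_config())
  asg <- assign_species(zc, 99600, 750, 2)
  expect_equal(asg$mole_fraction[1:2], c(0.6, 0.4), tolerance = 0.02)
  expect_equal(sum(asg$mole_fraction), 1, tolerance = 1e-9)
})

test_that("deconvolved Zavg matches the simulated charge distribution", {
  cm <- charge_model(14, 1.2)
  sp <- simulate_spectrum(tibble::tibble(mass = 99600, abundance = 1), cm,
                          mz_range = c(4000, 12000), mz_step = 0.25)
  zc <- deconvolve(sp, test_config())
  expect_lt(abs(average_charge(zc) - sum(cm$z * cm$prob)), 0.2)
})

test_that("average_charge is the intensity-weighted mean", {
  expect_equal(average_charge(tibble::tibble(z = 10, intensity = 3)), 10)
  expect_equal(average_charge(tibble::tibble(z = c(13, 14),
                                             intensity = c(1, 3))), 13.75)
  expect_error(average_charge(tibble::tibble(z = 10, intensity = 0)),
               "no intensity")
})

test_that("species assignment handles apo-only input and window overlap", {
  sp <- sim_ensemble(99600, 1)
  zc <- deconvolve(sp, test_config())
  asg <- assign_species(zc, 99600, 750, 3)
  expect_equal(asg$mole_fraction, c(1, 0, 0, 0), tolerance = 0.01)
  expect_error(assign_species(zc, 99600, 750, 3, window_halfwidth = 400),
               "overlap")
  expect_error(assign_species(zc, 5000, 10, 2), "no intensity")
})

test_that("assignment mole fractions ignore uniform intensity scaling", {
  sp <- sim_ensemble(c(99600, 100350), c(0.5, 0.5))
  sp2 <- sp
  sp2$intensity <- sp2$intensity * 37
  a1 <- assign_species(deconvolve(sp, test_config()), 99600, 750, 1)
  a2 <- assign_species(deconvolve(sp2, test_config()), 99600, 750, 1)
  expect_equal(a1$mole_fraction, a2$mole_fraction, tolerance = 1e-9)
})

test_that("peak picking reports centroids and survives flat input", {
  grid <- seq(1000, 1100, by = 0.5)
  one <- tibble::tibble(mass = grid, intensity = dnorm(grid, 1050, 2))
  pk <- pick_peaks(one, 0.1)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$mass, 1050, tolerance = 0.01)

  two <- tibble::tibble(mass = grid,
                        intensity = dnorm(grid, 1030, 2) + dnorm(grid, 1044.1, 2))
  pk2 <- pick_peaks(two, 0.1)  # peaks 3 fwhm apart
  expect_equal(nrow(pk2), 2)
  expect_equal(pk2$mass, c(1030, 1044.1), tolerance = 0.05)

  flat <- tibble::tibble(mass = grid, intensity = rep(0, length(grid)))
  expect_equal(nrow(pick_peaks(flat, 0.5)), 0)
})

test_that("degenerate spectra are rejected", {
  expect_error(deconvolve(tibble::tibble(mz = numeric(0),
                                         intensity = numeric(0))), "empty")
  expect_error(deconvolve(tibble::tibble(mz = c(5000, 6000),
                                         intensity = c(0, 0)),
                          test_config()), "no positive intensity")
  expect_error(deconvolve(tibble::tibble(mz = c(100, 200),
                                         intensity = c(1, 1)),
                          test_config()), "inside")
  expect_error(deconvolve(tibble::tibble(mz = c(5000, 5000),
                                         intensity = c(1, 1)),
                          test_config()), "strictly increasing")
})
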