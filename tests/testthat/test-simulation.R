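test_that("a single-charge peak lands at the electrospray m/z", {
  sp <- simulate_spectrum(tibble::tibble(mass = 1e5, abundance = 1),
                          charge_model(10, 0.2, 10, 10),
                          mz_range = c(9000, 11000), mz_step = 0.05)
  apex <- sp$mz[which.max(sp$intensity)]
  expect_equal(apex, (1e5 + 10 * 1.00728) / 10, tolerance = 0.05)
})

test_that("integrated intensity equals total abundance with noise off", {
  set.seed(11)
  for (rep in 1:4) {
    species <- tibble::tibble(mass = runif(3, 8e4, 1.2e5),
                              abundance = runif(3, 0.2, 2))
    sp <- simulate_spectrum(species, charge_model(14, 1.3),
                            mz_range = c(3500, 16500), mz_step = 0.2)
    area <- sum(sp$intensity) * 0.2
    expect_equal(area, sum(species$abundance), tolerance = 1e-3)
  }
})

test_that("the grid must cover every species/charge peak", {
  expect_error(
    simulate_spectrum(tibble::tibble(name = "apoZ", mass = 99600, abundance = 1),
                      charge_model(14, 1, 12, 16), mz_range = c(2000, 5000)),
    "apoZ.*charge")
})

test_that("charge model mean tracks its centre on a wide support", {
  for (zc in c(11, 14, 17)) {
    cm <- charge_model(zc, 1.5)
    expect_equal(sum(cm$z * cm$prob), zc, tolerance = 0.05)
    expect_equal(sum(cm$prob), 1, tolerance = 1e-12)
  }
})

test_that("simulation is deterministic given a seed", {
  species <- tibble::tibble(mass = 99600, abundance = 1)
  s1 <- simulate_spectrum(species, charge_model(14, 1), noise = "ion_count",
                          n_ions = 5000, seed = 3, mz_range = c(5000, 10000))
  s2 <- simulate_spectrum(species, charge_model(14, 1), noise = "ion_count",
                          n_ions = 5000, seed = 3, mz_range = c(5000, 10000))
  expect_identical(s1, s2)
  t1 <- simulate_titration(c(1, 5), 1, default_l_totals, n_ions = 800,
                           n_replicates = 3, seed = 4)
  t2 <- simulate_titration(c(1, 5), 1, default_l_totals, n_ions = 800,
                           n_replicates = 3, seed = 4)
  expect_identical(t1, t2)
  # different replicates are different draws
  expect_false(identical(t1[t1$replicate == 1, -1], t1[t1$replicate == 2, -1]))
})

test_that("lipid ensembles inherit equilibrium mole fractions", {
  e0 <- simulate_lipid_ensemble(binding_system(c(1, 5), 1, 0), 99600, 750)
  expect_equal(e0$abundance, c(1, 0, 0))
  expect_equal(e0$mass, c(99600, 100350, 101100))

  e1 <- simulate_lipid_ensemble(binding_system(1, 1, 1), 99600, 750)
  expect_equal(e1$abundance, c(0.61803, 0.38197), tolerance = 1e-4)

  e7 <- simulate_lipid_ensemble(binding_system(rep(2, 7), 1, 25), 99600, 750)
  expect_equal(e7$name, paste0("PL", 0:7))
})

test_that("titration rows sum to one and approach the model at high ion counts", {
  tit <- simulate_titration(c(0.5, 2, 8), 1, default_l_totals,
                            n_ions = 1e6, seed = 12)
  fm <- as.matrix(tit[paste0("f", 0:3)])
  expect_equal(rowSums(fm), rep(1, nrow(fm)))
  model <- as.matrix(
    simulate_titration(c(0.5, 2, 8), 1, default_l_totals,
                       n_ions = Inf)[paste0("f", 0:3)])
  expect_lt(max(abs(fm - model)), 0.005)
  # exact fractions when noiseless
  expect_equal(as.matrix(simulate_titration(c(0.5, 2, 8), 1, default_l_totals,
                                            n_ions = Inf)[paste0("f", 0:3)]),
               model)
})

test_that("titration lipid concentrations must increase strictly", {
  expect_error(simulate_titration(1, 1, c(0, 5, 5), n_ions = 100, seed = 1),
               "strictly increasing")
})
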