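donor_ctrl <- tibble::tibble(i_donor_ch = 1000, i_acceptor_ch = 0, i_fret_ch = 100)
acceptor_ctrl <- tibble::tibble(i_donor_ch = 0, i_acceptor_ch = 800, i_fret_ch = 200)

test_that("correction factors are the single-label channel ratios", {
  cf <- compute_correction_factors(donor_ctrl, acceptor_ctrl)
  expect_equal(cf$d_bleed, 0.1)
  expect_equal(cf$a_cross, 0.25)

  clean <- compute_correction_factors(
    dplyr::mutate(donor_ctrl, i_fret_ch = 0), acceptor_ctrl)
  expect_equal(clean$d_bleed, 0)

  expect_error(compute_correction_factors(
    dplyr::mutate(donor_ctrl, i_donor_ch = 0), acceptor_ctrl), "positive")
})

test_that("corrected FRET removes bleed-through and cross-excitation", {
  cf <- compute_correction_factors(donor_ctrl, acceptor_ctrl)
  sample <- tibble::tibble(i_donor_ch = 1000, i_acceptor_ch = 800,
                           i_fret_ch = 500)
  expect_equal(corrected_fret(sample, cf)$fc, 200)

  # self-consistency: controls corrected with their own factors give 0
  expect_equal(corrected_fret(donor_ctrl, cf)$fc, 0)
  expect_equal(corrected_fret(acceptor_ctrl, cf)$fc, 0)
})

test_that("max-normalization scales to unit maximum and is idempotent", {
  expect_equal(normalize_to_max(c(200, 100, 50)), c(1, 0.5, 0.25))
  expect_equal(normalize_to_max(7), 1)
  v <- c(3, 9, 1)
  expect_equal(normalize_to_max(normalize_to_max(v)), normalize_to_max(v))
  expect_equal(max(normalize_to_max(c(0.3, 0.02))), 1.0)
  # permutation equivariance
  p <- c(2, 3, 1)
  expect_equal(normalize_to_max(v[p]), normalize_to_max(v)[p])
  expect_error(normalize_to_max(c(-1, 0)), "positive")
})

test_that("simulated plates are linear in binding fraction with noise off", {
  fc_at <- function(b) {
    plate <- simulate_plate(b)
    suppressWarnings(analyze_plate(plate)$fc)
  }
  expect_equal(fc_at(0), 0)
  expect_equal(fc_at(0.8) / fc_at(0.4), 2.0)
  bs <- seq(0.1, 1, by = 0.1)
  fcs <- vapply(bs, fc_at, numeric(1))
  expect_equal(fcs, fcs[1] * bs / bs[1], tolerance = 1e-9)
})

test_that("noisy plates are reproducible for a fixed seed", {
  p1 <- simulate_plate(0.5, noise_sd = 5, seed = 21)
  p2 <- simulate_plate(0.5, noise_sd = 5, seed = 21)
  expect_identical(p1, p2)
  p3 <- simulate_plate(0.5, noise_sd = 5, seed = 22)
  expect_false(identical(p1, p3))
  expect_error(simulate_plate(1.2), "binding_fraction")
})

test_that("plate analysis subtracts blanks before computing factors", {
  plate <- simulate_plate(0.6)
  offset <- 50   # constant background in every channel
  plate_bg <- dplyr::mutate(plate,
                            i_donor_ch = i_donor_ch + offset,
                            i_acceptor_ch = i_acceptor_ch + offset,
                            i_fret_ch = i_fret_ch + offset)
  res <- analyze_plate(plate)
  res_bg <- analyze_plate(plate_bg)
  expect_equal(res_bg$fc, res$fc, tolerance = 1e-9)
})
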