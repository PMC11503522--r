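test_that("free lipid matches closed-form and brute-force oracles", {
  # no lipid present
  expect_identical(solve_free_lipid(binding_system(c(1, 5), 1, 0)), 0)

  # one site: quadratic closed form
  or <- oracle_one_site(1, 1, 1)
  expect_equal(solve_free_lipid(binding_system(1, 1, 1)), or$l_free,
               tolerance = 1e-9)
  expect_equal(or$l_free, 0.61803, tolerance = 1e-4)

  # two sites: brute-force root of the mass balance
  expect_equal(solve_free_lipid(binding_system(c(1, 5), 1, 10)),
               oracle_free_lipid(c(1, 5), 1, 10), tolerance = 1e-9)
  expect_equal(solve_free_lipid(binding_system(c(1, 5), 1, 10)), 8.441,
               tolerance = 1e-3)
})

test_that("species distribution satisfies both conservation laws", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(1:10, 1)
    sys <- binding_system(kd = 10^runif(n, -2, 2),
                          p_total = runif(1, 0.1, 10),
                          l_total = runif(1, 0, 100))
    dist <- species_distribution(sys)
    l_free <- attr(dist, "l_free_uM")
    expect_true(all(dist$concentration_uM >= 0))
    expect_equal(sum(dist$concentration_uM), sys$p_total, tolerance = 1e-9)
    expect_equal(l_free + sum(dist$n_lipids * dist$concentration_uM),
                 sys$l_total, tolerance = 1e-9)
  }
})

test_that("species distribution handles the trivial and symmetric cases", {
  d0 <- species_distribution(binding_system(c(1, 5), 1, 0))
  expect_equal(d0$mole_fraction, c(1, 0, 0))

  # all Kd equal to K and free lipid equal to K: every binding-polynomial
  # term is 1, so all states are equally populated. Choose l_total to land
  # free lipid exactly at K using the conservation law.
  K <- 2; n <- 3; p <- 0.5
  f_flat <- rep(1 / (n + 1), n + 1)
  l_tot <- K + p * sum((0:n) * f_flat)
  d <- species_distribution(binding_system(rep(K, n), p, l_tot))
  expect_equal(d$mole_fraction, f_flat, tolerance = 1e-9)

  # one site at the quadratic oracle
  expect_equal(species_distribution(binding_system(1, 1, 1))$mole_fraction[2],
               0.38197, tolerance = 1e-4)
})

test_that("one-site distribution matches the quadratic across a parameter grid", {
  g <- expand.grid(kd = 10^seq(-2, 2, length.out = 7),
                   p = 10^seq(-2, 2, length.out = 7),
                   l = 10^seq(-2, 2, length.out = 7))
  for (i in seq_len(nrow(g))) {
    or <- oracle_one_site(g$kd[i], g$p[i], g$l[i])
    d <- species_distribution(binding_system(g$kd[i], g$p[i], g$l[i]))
    expect_equal(d$mole_fraction, or$f, tolerance = 1e-9)
  }
})

test_that("expected bound lipids increase monotonically with total lipid", {
  set.seed(7)
  for (rep in 1:5) {
    kd <- 10^runif(sample(2:6, 1), -1, 2)
    lt <- seq(0, 50, length.out = 40)
    nbar <- vapply(lt, function(l) {
      d <- species_distribution(binding_system(kd, 1, l))
      sum(d$n_lipids * d$mole_fraction)
    }, numeric(1))
    expect_true(all(diff(nbar) >= -1e-12))
  }
})

test_that("fold changes are ratios of successive constants and scale-free", {
  expect_equal(fold_changes(c(1, 1, 1)), c(1, 1))
  expect_equal(fold_changes(c(0.5, 2)), 4)
  expect_identical(fold_changes(3), numeric(0))
  kd <- c(0.3, 1.7, 9.2)
  expect_equal(fold_changes(kd * 137), fold_changes(kd))
  expect_error(fold_changes(c(1, -1)), "positive")
})

test_that("replicate summaries report element-wise mean and sample sd", {
  f <- function(kd) structure(list(kd_hat = kd, n_sites = length(kd)),
                              class = "kd_fit")
  s3 <- replicate_summary(list(f(c(1, 2)), f(c(1, 2)), f(c(1, 2))))
  expect_equal(s3$kd_mean_uM, c(1, 2))
  expect_equal(s3$kd_sd_uM, c(0, 0))

  s <- replicate_summary(list(f(1), f(2), f(3)))
  expect_equal(s$kd_mean_uM, 2)
  expect_equal(s$kd_sd_uM, 1)  # sample sd of 1,2,3

  s1 <- replicate_summary(list(f(c(4, 5))))
  expect_equal(s1$kd_sd_uM, c(0, 0))
  expect_error(replicate_summary(list()), "at least one")
  expect_error(replicate_summary(list(f(1), f(c(1, 2)))), "share")
})

test_that("invalid systems are rejected", {
  expect_error(binding_system(numeric(0), 1, 1))
  expect_error(binding_system(c(1, 0), 1, 1))
  expect_error(binding_system(1, -1, 1))
  expect_error(binding_system(1, 1, -1))
})
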