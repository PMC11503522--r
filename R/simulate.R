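#' Discrete charge-state model for nanoESI ions
#'
#' Charge states of an electrosprayed protein complex are modelled as a
#' discretised Gaussian over an integer support: \eqn{P(z) \propto
#' \exp(-(z - z_{center})^2 / 2\sigma_z^2)} for \eqn{z_{min} \le z \le
#' z_{max}}, normalised to 1. Charge reduction (by additives such as
#' spermine or TMAO, or by charge-reducing detergents) is represented by
#' lowering `z_center`.
#'
#' @param z_center Target average charge state (need not be an integer).
#' @param z_sigma Width of the charge-state distribution (> 0).
#' @param z_min,z_max Integer support of the distribution.
#' @return An object of class `charge_model` with a `prob` vector over
#'   `z_min:z_max`.
#' @examples
#' charge_model(14, 1.2)
#' @export
charge_model <- function(z_center, z_sigma = 1.5, z_min = NULL, z_max = NULL) {
  stopifnot(is.numeric(z_center), z_center > 0, is.numeric(z_sigma), z_sigma > 0)
  if (is.null(z_min)) z_min <- max(1L, as.integer(floor(z_center - 4 * z_sigma)))
  if (is.null(z_max)) z_max <- as.integer(ceiling(z_center + 4 * z_sigma))
  stopifnot(z_min >= 1, z_max >= z_min)
  z <- z_min:z_max
  p <- exp(-(z - z_center)^2 / (2 * z_sigma^2))
  structure(list(z = z, prob = p / sum(p), z_center = z_center,
                 z_sigma = z_sigma, z_min = z_min, z_max = z_max),
            class = "charge_model")
}

#' @export
print.charge_model <- function(x, ...) {
  cat("Charge model: z", x$z_min, "-", x$z_max, ", center", x$z_center,
      ", sigma", x$z_sigma, "; mean", signif(sum(x$z * x$prob), 4), "\n")
  invisible(x)
}

#' Simulate a nanoESI mass spectrum of a protein(-lipid) ensemble
#'
#' For each species of neutral mass M and each charge z, a Gaussian peak of
#' area `abundance * P(z)` is placed at the electrospray position
#' \eqn{m/z = (M + z m_H) / z} (protonation only, \eqn{m_H = 1.00728} Da)
#' with the stated full width at half maximum, then all peaks are summed and
#' sampled on a regular m/z grid. Integrated intensity (trapezoidal) equals
#' total species abundance when noise is off.
#'
#' @param species Data frame with columns `mass` (Da), `abundance`
#'   (non-negative weight) and optionally `name`.
#' @param charges A [charge_model()].
#' @param mz_range Length-2 m/z window of the simulated grid, Thomson.
#' @param mz_step Grid spacing, Thomson.
#' @param peak_fwhm Peak full width at half maximum in m/z, Thomson.
#' @param noise One of `"none"`, `"gaussian"` (additive, sd `noise_sd`,
#'   clamped at zero) or `"ion_count"` (total signal redistributed as
#'   `n_ions` multinomial draws over the grid, rescaled to the original
#'   total).
#' @param noise_sd Standard deviation of additive Gaussian noise, intensity
#'   units.
#' @param n_ions Ion count for `"ion_count"` noise.
#' @param seed Integer seed; the output is deterministic given the seed.
#' @param proton_mass Charge-carrier mass, Da.
#' @return A tibble of class `ms_spectrum` with columns `mz`, `intensity`.
#' @examples
#' sp <- tibble::tibble(mass = 99600, abundance = 1)
#' simulate_spectrum(sp, charge_model(14), mz_range = c(5000, 10000))
#' @export
simulate_spectrum <- function(species, charges,
                              mz_range = c(2000, 20000), mz_step = 0.25,
                              peak_fwhm = 0.85,
                              noise = c("none", "gaussian", "ion_count"),
                              noise_sd = 0, n_ions = 10000, seed = NULL,
                              proton_mass = PROTON_MASS) {
  stopifnot(is.data.frame(species), nrow(species) >= 1,
            all(c("mass", "abundance") %in% names(species)),
            inherits(charges, "charge_model"),
            length(mz_range) == 2, mz_range[1] < mz_range[2], mz_step > 0,
            peak_fwhm > 0)
  if (any(species$mass <= 0)) stop("species masses must be positive", call. = FALSE)
  if (any(species$abundance < 0) || all(species$abundance == 0)) {
    stop("species abundances must be non-negative and not all zero", call. = FALSE)
  }
  noise <- match.arg(noise)
  nm <- if ("name" %in% names(species)) species$name else
    paste0("species", seq_len(nrow(species)))

  mz <- seq(mz_range[1], mz_range[2], by = mz_step)
  intensity <- numeric(length(mz))
  sigma <- peak_fwhm * FWHM_TO_SIGMA
  for (s in seq_len(nrow(species))) {
    if (species$abundance[s] == 0) next
    for (k in seq_along(charges$z)) {
      z <- charges$z[k]
      center <- (species$mass[s] + z * proton_mass) / z
      if (center < mz_range[1] || center > mz_range[2]) {
        stop("m/z grid [", mz_range[1], ", ", mz_range[2], "] does not cover ",
             "the peak of ", nm[s], " at charge ", z, " (", signif(center, 8),
             " Th)", call. = FALSE)
      }
      area <- species$abundance[s] * charges$prob[k]
      lo <- max(1L, ceiling((center - 8 * sigma - mz_range[1]) / mz_step) + 1L)
      hi <- min(length(mz), floor((center + 8 * sigma - mz_range[1]) / mz_step) + 1L)
      if (hi >= lo) {
        idx <- lo:hi
        intensity[idx] <- intensity[idx] + area * stats::dnorm(mz[idx], center, sigma)
      }
    }
  }

  if (noise == "gaussian" && noise_sd > 0) {
    intensity <- with_local_seed(seed,
      pmax(0, intensity + stats::rnorm(length(intensity), 0, noise_sd)))
  } else if (noise == "ion_count") {
    stopifnot(n_ions >= 1)
    tot <- sum(intensity)
    if (tot > 0) {
      counts <- with_local_seed(seed,
        as.numeric(stats::rmultinom(1, n_ions, intensity / tot)))
      intensity <- counts * tot / n_ions
    }
  }

  out <- tibble::tibble(mz = mz, intensity = intensity)
  class(out) <- c("ms_spectrum", class(out))
  out
}

#' Species ensemble of a lipid-bound protein complex at equilibrium
#'
#' Converts a sequential binding system into a simulatable species list:
#' masses are `base_mass + i * ligand_mass` for the i-lipid-bound states and
#' abundances are the equilibrium mole fractions from
#' [species_distribution()].
#'
#' @param system A [binding_system()].
#' @param base_mass Mass of the lipid-free protein complex, Da.
#' @param ligand_mass Mass of one bound lipid, Da.
#' @return A tibble with columns `name`, `mass`, `abundance` (one row per
#'   `PL0..PLn` state).
#' @examples
#' simulate_lipid_ensemble(binding_system(1, 1, 1), 99600, 750)
#' @export
simulate_lipid_ensemble <- function(system, base_mass, ligand_mass) {
  stopifnot(inherits(system, "binding_system"),
            is.numeric(base_mass), base_mass > 0,
            is.numeric(ligand_mass), ligand_mass > 0)
  dist <- species_distribution(system)
  tibble::tibble(
    name = paste0("PL", dist$n_lipids),
    mass = base_mass + dist$n_lipids * ligand_mass,
    abundance = dist$mole_fraction
  )
}

#' Simulate a lipid titration observed with ion-counting noise
#'
#' For each total lipid concentration the equilibrium mole fractions of the
#' sequential binding model are computed (with lipid depletion), then the
#' observed fractions are drawn as a multinomial of `n_ions` ions divided by
#' `n_ions` — the counting-statistics model of mole fractions extracted from
#' a mass spectrum. Replicates use independent deterministic sub-streams of
#' `seed`. `n_ions = Inf` returns the exact model fractions.
#'
#' @param kd Vector of per-site dissociation constants, uM.
#' @param p_total Total protein concentration, uM.
#' @param l_totals Vector of non-negative total lipid concentrations, uM,
#'   strictly increasing.
#' @param n_ions Ions counted per titration point (>= 1), or `Inf` for
#'   noiseless fractions.
#' @param n_replicates Number of independent replicates.
#' @param seed Integer seed.
#' @return A tibble with columns `replicate`, `l_total_uM`, `f0..fn`; every
#'   row sums to exactly 1.
#' @examples
#' simulate_titration(kd = c(0.5, 2), p_total = 1,
#'                    l_totals = c(0, 1, 5, 25), n_ions = 2000, seed = 1)
#' @export
simulate_titration <- function(kd, p_total, l_totals, n_ions = Inf,
                               n_replicates = 1, seed = NULL) {
  stopifnot(is.numeric(kd), all(kd > 0), is.numeric(p_total), p_total > 0,
            is.numeric(l_totals), all(l_totals >= 0), n_replicates >= 1)
  if (length(l_totals) > 1 && any(diff(l_totals) <= 0)) {
    stop("`l_totals` must be strictly increasing", call. = FALSE)
  }
  if (!is.infinite(n_ions) && n_ions < 1) stop("`n_ions` must be >= 1", call. = FALSE)

  lf <- free_lipid(kd, p_total, l_totals)
  model <- binding_fractions(lf, kd)

  one_replicate <- function(r) {
    fm <- if (is.infinite(n_ions)) {
      model
    } else {
      with_local_seed(if (is.null(seed)) NULL else derive_seed(seed, r),
                      t(apply(model, 1, function(p)
        as.numeric(stats::rmultinom(1, n_ions, p)) / n_ions)))
    }
    out <- tibble::as_tibble(stats::setNames(as.data.frame(fm),
                                             paste0("f", 0:length(kd))))
    dplyr::bind_cols(tibble::tibble(replicate = r, l_total_uM = l_totals), out)
  }
  dplyr::bind_rows(lapply(seq_len(n_replicates), one_replicate))
}
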