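#' Define a sequential lipid-binding system
#'
#' Constructs the description of a sequential binding equilibrium in which a
#' protein complex P binds up to `length(kd)` lipids one at a time,
#' \eqn{PL_{i-1} + L \rightleftharpoons PL_i}, each step governed by its own
#' macroscopic dissociation constant
#' \eqn{K_{d,i} = [PL_{i-1}][L]/[PL_i]} (in micromolar).
#'
#' @param kd Numeric vector of per-site dissociation constants, uM. Its
#'   length sets the number of sequential sites.
#' @param p_total Total protein complex concentration, uM.
#' @param l_total Total lipid concentration, uM.
#' @return An object of class `binding_system`: a list with elements
#'   `kd`, `n_sites`, `p_total`, `l_total`.
#' @examples
#' sys <- binding_system(kd = c(1, 5), p_total = 1, l_total = 10)
#' species_distribution(sys)
#' @export
binding_system <- function(kd, p_total, l_total) {
  if (length(kd) < 1 || !is.numeric(kd) || any(!is.finite(kd)) || any(kd <= 0)) {
    stop("`kd` must be a non-empty numeric vector of positive dissociation constants", call. = FALSE)
  }
  if (!is.numeric(p_total) || length(p_total) != 1 || !is.finite(p_total) || p_total < 0) {
    stop("`p_total` must be a single non-negative concentration (uM)", call. = FALSE)
  }
  if (!is.numeric(l_total) || length(l_total) != 1 || !is.finite(l_total) || l_total < 0) {
    stop("`l_total` must be a single non-negative concentration (uM)", call. = FALSE)
  }
  structure(
    list(kd = as.numeric(kd), n_sites = length(kd),
         p_total = as.numeric(p_total), l_total = as.numeric(l_total)),
    class = "binding_system"
  )
}

#' @export
print.binding_system <- function(x, ...) {
  cat("Sequential lipid-binding system\n")
  cat("  sites:  ", x$n_sites, "\n")
  cat("  Kd (uM):", paste(signif(x$kd, 4), collapse = ", "), "\n")
  cat("  [P]tot: ", x$p_total, "uM   [L]tot:", x$l_total, "uM\n")
  invisible(x)
}

# Mole fractions F_0..F_n of the sequential scheme at free lipid L (vectorised
# over L). Terms of the binding polynomial are accumulated in log space so that
# ladders spanning many orders of magnitude neither overflow nor underflow.
binding_fractions <- function(l_free, kd) {
  n <- length(kd)
  out <- matrix(0, nrow = length(l_free), ncol = n + 1L)
  zero <- l_free <= 0
  out[zero, 1L] <- 1
  if (any(!zero)) {
    lf <- l_free[!zero]
    # log term_i = i*log(L) - sum_{j<=i} log(Kd_j), term_0 = 0
    csum <- cumsum(log(kd))
    logt <- cbind(0, outer(log(lf), 1:n) - rep(csum, each = length(lf)))
    m <- apply(logt, 1L, max)
    w <- exp(logt - m)
    out[!zero, ] <- w / rowSums(w)
  }
  out
}

# Expected number of bound lipids per protein at free lipid L (vectorised).
bound_lipids_per_protein <- function(l_free, kd) {
  f <- binding_fractions(l_free, kd)
  as.numeric(f %*% (0:length(kd)))
}

#' Solve for the free lipid concentration
#'
#' Finds the unique free lipid concentration satisfying the lipid mass
#' balance \eqn{L_{free} + P_{tot}\sum_i i F_i(L_{free}) = L_{tot}} for a
#' sequential binding system. The residual is strictly increasing in
#' \eqn{L_{free}}, so bisection on \eqn{[0, L_{tot}]} converges to the unique
#' root; iteration stops at an absolute half-width of
#' `1e-12 * max(1, l_total)`.
#'
#' @param system A [binding_system()].
#' @return Free lipid concentration, uM (a single number).
#' @examples
#' solve_free_lipid(binding_system(kd = 1, p_total = 1, l_total = 1))
#' @export
solve_free_lipid <- function(system) {
  stopifnot(inherits(system, "binding_system"))
  free_lipid(system$kd, system$p_total, system$l_total)
}

# Vectorised bisection over a vector of total lipid concentrations.
free_lipid <- function(kd, p_total, l_totals) {
  out <- numeric(length(l_totals))
  pos <- l_totals > 0
  if (!any(pos)) return(out)
  lt <- l_totals[pos]
  lo <- numeric(length(lt))
  hi <- lt
  tol <- 1e-12 * pmax(1, lt)
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    g <- mid + p_total * bound_lipids_per_protein(mid, kd) - lt
    up <- g > 0
    hi[up] <- mid[up]
    lo[!up] <- mid[!up]
    if (all(hi - lo <= tol)) break
  }
  out[pos] <- (lo + hi) / 2
  out
}

#' Equilibrium species distribution of a sequential binding system
#'
#' Evaluates the sequential binding model at the system's total
#' concentrations: free lipid is obtained from the mass balance
#' ([solve_free_lipid()]), and the mole fraction of the i-lipid-bound state
#' is the normalised i-th term of the binding polynomial,
#' \eqn{F_i \propto L_{free}^i / \prod_{j \le i} K_{d,j}}.
#'
#' @param system A [binding_system()].
#' @return A tibble with one row per bound state `PL0..PLn` and columns
#'   `n_lipids`, `mole_fraction`, `concentration_uM`. The free lipid
#'   concentration is attached as attribute `l_free_uM`.
#' @examples
#' species_distribution(binding_system(kd = c(1, 5), p_total = 1, l_total = 10))
#' @export
species_distribution <- function(system) {
  stopifnot(inherits(system, "binding_system"))
  l_free <- solve_free_lipid(system)
  f <- binding_fractions(l_free, system$kd)[1L, ]
  out <- tibble::tibble(
    n_lipids = 0:system$n_sites,
    mole_fraction = f,
    concentration_uM = f * system$p_total
  )
  attr(out, "l_free_uM") <- l_free
  out
}

#' Fold changes of successive dissociation constants
#'
#' Ratios of each dissociation constant to the previous one,
#' \eqn{K_{d,2}/K_{d,1}, K_{d,3}/K_{d,2}, \dots}, used to compare how
#' binding weakens (or tightens) as lipids accumulate on the complex. The
#' result is invariant under a uniform rescaling of all constants.
#'
#' @param kd Numeric vector of positive dissociation constants (any unit).
#' @return Numeric vector of `length(kd) - 1` ratios (empty for a single
#'   constant).
#' @examples
#' fold_changes(c(0.5, 2, 8))
#' @export
fold_changes <- function(kd) {
  if (!is.numeric(kd) || length(kd) < 1 || any(!is.finite(kd)) || any(kd <= 0)) {
    stop("`kd` must be a vector of positive dissociation constants", call. = FALSE)
  }
  if (length(kd) == 1L) return(numeric(0))
  kd[-1] / kd[-length(kd)]
}

# Validate and renormalise observed mole-fraction rows. Deconvolution output
# is approximately, not exactly, normalised: rows off unit sum by <= 0.05 are
# rescaled (with a warning when the deviation exceeds 0.01); larger
# deviations indicate malformed input and are an error.
validate_titration <- function(titration) {
  stopifnot(is.data.frame(titration))
  fcols <- grep("^f[0-9]+$", names(titration), value = TRUE)
  if (length(fcols) < 2) {
    stop("titration must contain mole-fraction columns f0, f1, ...", call. = FALSE)
  }
  fcols <- paste0("f", seq_along(fcols) - 1L)
  if (!all(fcols %in% names(titration))) {
    stop("mole-fraction columns must be consecutive: f0, f1, ...", call. = FALSE)
  }
  if (!"l_total_uM" %in% names(titration)) {
    stop("titration must contain an `l_total_uM` column", call. = FALSE)
  }
  fm <- as.matrix(titration[fcols])
  if (any(!is.finite(fm)) || any(fm < 0)) {
    stop("mole fractions must be finite and non-negative", call. = FALSE)
  }
  rs <- rowSums(fm)
  dev <- abs(rs - 1)
  if (any(dev > 0.05)) {
    stop("mole-fraction rows deviate from unit sum by more than 0.05; ",
         "check the input (max deviation ", signif(max(dev), 3), ")", call. = FALSE)
  }
  if (any(dev > 0.01)) {
    warning("renormalising mole-fraction rows deviating from unit sum by up to ",
            signif(max(dev), 3), call. = FALSE)
  }
  titration[fcols] <- fm / rs
  titration
}

#' Fit per-site dissociation constants to a titration series
#'
#' Estimates the dissociation constants of a sequential lipid-binding model
#' from observed mole fractions across a lipid titration, by least squares on
#' all mole-fraction entries. The fit is parameterised in
#' \eqn{\log_{10} K_d} with box bounds (default \eqn{[-3, 3]}, i.e. 1 nM to
#' 1 mM), and run from multiple random starts drawn uniformly within the
#' bounds; the best objective wins, ties going to the earliest start.
#'
#' Observed rows are renormalised to unit sum on ingest (deviations above
#' 0.05 are an error). Lipid depletion is modelled throughout: the model
#' evaluates mole fractions at the free, not total, lipid concentration.
#'
#' @param titration Data frame with columns `l_total_uM` and `f0..fn`
#'   (observed mole fractions of the 0- to n-lipid-bound states). A
#'   `replicate` column, if present, must contain a single value; fit
#'   replicates separately (see [replicate_summary()]).
#' @param n_sites Number of sequential sites; defaults to (and must match)
#'   the number of mole-fraction columns minus one.
#' @param p_total Total protein complex concentration, uM.
#' @param seed Integer seed for the multi-start draws.
#' @param n_starts Number of random starts (default 10).
#' @param bounds Length-2 bounds on log10(Kd/uM).
#' @return An object of class `kd_fit`; see [tidy.kd_fit()] and
#'   [glance.kd_fit()]. Key elements: `kd_hat` (uM), `r2`, `residual_norm`,
#'   `converged`, `n_starts_used`.
#' @examples
#' tit <- simulate_titration(kd = c(0.5, 2), p_total = 1,
#'                           l_totals = c(0, 1, 2, 5, 10, 25),
#'                           n_ions = Inf, n_replicates = 1, seed = 1)
#' fit <- fit_sequential_kds(tit, p_total = 1, seed = 1)
#' tidy(fit)
#' @export
fit_sequential_kds <- function(titration, n_sites = NULL, p_total, seed = NULL,
                               n_starts = 10, bounds = c(-3, 3)) {
  titration <- validate_titration(titration)
  if ("replicate" %in% names(titration) &&
      length(unique(titration$replicate)) > 1) {
    stop("titration contains multiple replicates; fit them separately ",
         "(e.g. split by `replicate`)", call. = FALSE)
  }
  fcols <- grep("^f[0-9]+$", names(titration), value = TRUE)
  width <- length(fcols)
  if (is.null(n_sites)) n_sites <- width - 1L
  if (n_sites != width - 1L) {
    stop("`n_sites` (", n_sites, ") must equal the number of mole-fraction ",
         "columns minus one (", width - 1L, ")", call. = FALSE)
  }
  stopifnot(is.numeric(p_total), p_total > 0, length(bounds) == 2, bounds[1] < bounds[2])

  l_totals <- titration$l_total_uM
  obs <- as.matrix(titration[paste0("f", 0:n_sites)])

  objective <- function(log10_kd) {
    kd <- 10^log10_kd
    lf <- free_lipid(kd, p_total, l_totals)
    pred <- binding_fractions(lf, kd)
    sum((obs - pred)^2)
  }

  starts <- with_local_seed(seed,
    matrix(stats::runif(n_starts * n_sites, bounds[1], bounds[2]),
           nrow = n_starts))

  fits <- lapply(seq_len(n_starts), function(s) {
    stats::nlminb(starts[s, ], objective,
                  lower = rep(bounds[1], n_sites),
                  upper = rep(bounds[2], n_sites),
                  control = list(iter.max = 500, eval.max = 1000))
  })
  objs <- vapply(fits, function(f) f$objective, numeric(1))
  best_i <- which.min(objs)          # which.min takes the earliest tie
  best <- fits[[best_i]]

  kd_hat <- 10^best$par
  lf <- free_lipid(kd_hat, p_total, l_totals)
  pred <- binding_fractions(lf, kd_hat)
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_

  structure(
    list(kd_hat = kd_hat, log10_kd_hat = best$par, r2 = r2,
         residual_norm = ss_res, converged = best$convergence == 0,
         n_starts_used = n_starts, best_start = best_i,
         n_sites = n_sites, p_total = p_total, bounds = bounds, seed = seed,
         titration = tibble::as_tibble(titration),
         fitted = tibble::as_tibble(
           cbind(l_total_uM = l_totals,
                 stats::setNames(as.data.frame(pred), paste0("f", 0:n_sites))))),
    class = "kd_fit"
  )
}

#' @export
print.kd_fit <- function(x, ...) {
  cat("Sequential binding fit:", x$n_sites, "sites,",
      nrow(x$titration), "titration points\n")
  cat("  Kd (uM):", paste(signif(x$kd_hat, 3), collapse = ", "), "\n")
  cat("  R2 =", signif(x$r2, 4), " SSR =", signif(x$residual_norm, 4),
      " converged:", x$converged, "\n")
  invisible(x)
}

#' Tidy a sequential binding fit
#'
#' @param x A `kd_fit` from [fit_sequential_kds()].
#' @param ... Unused.
#' @return A tibble with one row per site: `site`, `kd_uM`, `log10_kd`.
#' @export
tidy.kd_fit <- function(x, ...) {
  tibble::tibble(site = seq_len(x$n_sites),
                 kd_uM = x$kd_hat,
                 log10_kd = x$log10_kd_hat)
}

#' One-row summary of a sequential binding fit
#'
#' @param x A `kd_fit` from [fit_sequential_kds()].
#' @param ... Unused.
#' @return A one-row tibble: `r2`, `residual_norm`, `converged`,
#'   `n_starts_used`, `nobs`.
#' @export
glance.kd_fit <- function(x, ...) {
  tibble::tibble(r2 = x$r2, residual_norm = x$residual_norm,
                 converged = x$converged, n_starts_used = x$n_starts_used,
                 nobs = nrow(x$titration) * (x$n_sites + 1L))
}

#' Summarise replicate fits
#'
#' Element-wise mean and standard deviation of the estimated dissociation
#' constants across independently fitted replicates (sample sd; reported as
#' 0 for a single replicate).
#'
#' @param fits A list of `kd_fit` objects sharing `n_sites`.
#' @return A tibble with columns `site`, `kd_mean_uM`, `kd_sd_uM`, `n`.
#' @export
replicate_summary <- function(fits) {
  if (length(fits) == 0) stop("`fits` must contain at least one fit", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "kd_fit")))
  ns <- vapply(fits, function(f) f$n_sites, integer(1))
  if (length(unique(ns)) != 1) stop("all fits must share `n_sites`", call. = FALSE)
  km <- do.call(rbind, lapply(fits, function(f) f$kd_hat))
  sds <- if (nrow(km) == 1L) rep(0, ncol(km)) else apply(km, 2, stats::sd)
  tibble::tibble(site = seq_len(ns[1]),
                 kd_mean_uM = colMeans(km),
                 kd_sd_uM = sds,
                 n = nrow(km))
}
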