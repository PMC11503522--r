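#' Spectral correction factors from single-label controls
#'
#' The sensitized-emission (three-cube) FRET readout mixes three signals in
#' the FRET channel (donor excitation / acceptor emission): true sensitized
#' emission, donor emission bleeding through into the acceptor emission
#' band, and acceptor emission from direct excitation at the donor
#' wavelength. The two contaminations are calibrated from single-label
#' wells: `d_bleed` is the FRET-channel signal of a donor-only well per
#' unit of its donor-channel signal, and `a_cross` the FRET-channel signal
#' of an acceptor-only well per unit of its acceptor-channel signal. All
#' intensities are assumed blank-subtracted.
#'
#' @param donor_only,acceptor_only Data frames (or one-row tibbles) with
#'   columns `i_donor_ch`, `i_acceptor_ch`, `i_fret_ch`. Multiple control
#'   wells are averaged channel-wise before the ratio.
#' @return A list of class `fret_correction` with elements `d_bleed`,
#'   `a_cross`.
#' @examples
#' compute_correction_factors(
#'   donor_only = tibble::tibble(i_donor_ch = 1000, i_acceptor_ch = 0, i_fret_ch = 100),
#'   acceptor_only = tibble::tibble(i_donor_ch = 0, i_acceptor_ch = 800, i_fret_ch = 200))
#' @export
compute_correction_factors <- function(donor_only, acceptor_only) {
  chans <- c("i_donor_ch", "i_acceptor_ch", "i_fret_ch")
  for (d in list(donor_only, acceptor_only)) {
    stopifnot(is.data.frame(d), all(chans %in% names(d)), nrow(d) >= 1)
  }
  dd <- colMeans(donor_only[chans])
  aa <- colMeans(acceptor_only[chans])
  if (!is.finite(dd[["i_donor_ch"]]) || dd[["i_donor_ch"]] <= 0) {
    stop("donor-only control must have positive donor-channel intensity", call. = FALSE)
  }
  if (!is.finite(aa[["i_acceptor_ch"]]) || aa[["i_acceptor_ch"]] <= 0) {
    stop("acceptor-only control must have positive acceptor-channel intensity",
         call. = FALSE)
  }
  structure(list(d_bleed = dd[["i_fret_ch"]] / dd[["i_donor_ch"]],
                 a_cross = aa[["i_fret_ch"]] / aa[["i_acceptor_ch"]]),
            class = "fret_correction")
}

#' @export
print.fret_correction <- function(x, ...) {
  cat("FRET correction factors: donor bleed-through", signif(x$d_bleed, 4),
      ", acceptor cross-excitation", signif(x$a_cross, 4), "\n")
  invisible(x)
}

#' Corrected sensitized-emission FRET
#'
#' Removes donor bleed-through and direct acceptor excitation from the FRET
#' channel: \eqn{F_c = I_{FRET} - d_{bleed} I_{donor} - a_{cross}
#' I_{acceptor}}. Negative results are reported as-is (they indicate noise
#' or over-correction, not clipped to zero).
#'
#' @param sample Data frame with columns `i_donor_ch`, `i_acceptor_ch`,
#'   `i_fret_ch` (one row per well; blank-subtracted).
#' @param cf A `fret_correction` from [compute_correction_factors()].
#' @return The input tibble with an added `fc` column (corrected FRET,
#'   intensity units).
#' @export
corrected_fret <- function(sample, cf) {
  stopifnot(is.data.frame(sample), inherits(cf, "fret_correction"),
            all(c("i_donor_ch", "i_acceptor_ch", "i_fret_ch") %in% names(sample)))
  dplyr::mutate(tibble::as_tibble(sample),
                fc = .data$i_fret_ch - cf$d_bleed * .data$i_donor_ch -
                  cf$a_cross * .data$i_acceptor_ch)
}

#' Normalize corrected FRET values to the largest response
#'
#' @param values Numeric vector of corrected FRET intensities; at least one
#'   must be positive.
#' @return `values / max(values)`; the maximum of the result is exactly 1.
#' @examples
#' normalize_to_max(c(200, 100, 50))
#' @export
normalize_to_max <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1)
  m <- max(values)
  if (!is.finite(m) || m <= 0) {
    stop("normalization requires at least one positive value", call. = FALSE)
  }
  values / m
}

#' Simulate a FRET plate experiment
#'
#' Generates blank-subtracted donor-only, acceptor-only and sample wells
#' for a sensitized-emission assay in which the true sensitized emission is
#' proportional to the bound fraction of the donor-labelled protein:
#' `fret_gain * binding_fraction * donor_brightness`. Bleed-through and
#' cross-excitation are injected according to `cf_true`, and optional
#' Gaussian read noise is added per channel. With noise off,
#' [corrected_fret()] using factors recomputed from the simulated controls
#' recovers a value exactly linear in `binding_fraction`.
#'
#' @param binding_fraction Fraction of donor-labelled protein bound to the
#'   acceptor-labelled lipid, in \[0, 1\].
#' @param donor_brightness,acceptor_brightness Channel signals of the fully
#'   labelled species, intensity units.
#' @param cf_true True contamination factors (a `fret_correction`).
#' @param fret_gain Sensitized emission per unit of bound donor signal.
#' @param noise_sd Per-channel Gaussian read noise sd (0 = noiseless).
#' @param seed Integer seed for the noise draws.
#' @return A tibble with columns `well`, `role`
#'   (`sample|donor_only|acceptor_only|blank`), `i_donor_ch`,
#'   `i_acceptor_ch`, `i_fret_ch`.
#' @export
simulate_plate <- function(binding_fraction, donor_brightness = 1000,
                           acceptor_brightness = 800,
                           cf_true = compute_correction_factors(
                             tibble::tibble(i_donor_ch = 1000, i_acceptor_ch = 0,
                                            i_fret_ch = 100),
                             tibble::tibble(i_donor_ch = 0, i_acceptor_ch = 800,
                                            i_fret_ch = 200)),
                           fret_gain = 0.3, noise_sd = 0, seed = NULL) {
  stopifnot(is.numeric(binding_fraction), length(binding_fraction) == 1,
            binding_fraction >= 0, binding_fraction <= 1,
            donor_brightness > 0, acceptor_brightness > 0,
            inherits(cf_true, "fret_correction"), fret_gain >= 0, noise_sd >= 0)
  sensitized <- fret_gain * binding_fraction * donor_brightness
  wells <- tibble::tibble(
    well = c("A1", "A2", "A3", "A4"),
    role = c("sample", "donor_only", "acceptor_only", "blank"),
    i_donor_ch = c(donor_brightness, donor_brightness, 0, 0),
    i_acceptor_ch = c(acceptor_brightness, 0, acceptor_brightness, 0),
    i_fret_ch = c(sensitized + cf_true$d_bleed * donor_brightness +
                    cf_true$a_cross * acceptor_brightness,
                  cf_true$d_bleed * donor_brightness,
                  cf_true$a_cross * acceptor_brightness,
                  0)
  )
  if (noise_sd > 0) {
    noise <- with_local_seed(seed,
      matrix(stats::rnorm(nrow(wells) * 3, 0, noise_sd), ncol = 3))
    wells$i_donor_ch <- wells$i_donor_ch + noise[, 1]
    wells$i_acceptor_ch <- wells$i_acceptor_ch + noise[, 2]
    wells$i_fret_ch <- wells$i_fret_ch + noise[, 3]
  }
  wells
}

#' Full FRET plate analysis
#'
#' Convenience wrapper: subtracts blank wells channel-wise, computes
#' correction factors from the single-label controls, applies the
#' correction to the sample wells and normalizes to the largest response.
#'
#' @param plate Data frame with columns `well`, `role`
#'   (`sample|donor_only|acceptor_only|blank`), `i_donor_ch`,
#'   `i_acceptor_ch`, `i_fret_ch`, plus any grouping columns (e.g.
#'   detergent, CMC multiple), which are carried through.
#' @return A tibble of the sample wells with added columns `fc` and
#'   `fc_norm`.
#' @export
analyze_plate <- function(plate) {
  stopifnot(is.data.frame(plate), "role" %in% names(plate))
  chans <- c("i_donor_ch", "i_acceptor_ch", "i_fret_ch")
  stopifnot(all(chans %in% names(plate)))
  blanks <- plate[plate$role == "blank", ]
  if (nrow(blanks) > 0) {
    bl <- colMeans(blanks[chans])
    plate[chans] <- sweep(as.matrix(plate[chans]), 2, bl)
  }
  cf <- compute_correction_factors(plate[plate$role == "donor_only", ],
                                   plate[plate$role == "acceptor_only", ])
  out <- corrected_fret(plate[plate$role == "sample", ], cf)
  if (any(out$fc > 0)) {
    out$fc_norm <- normalize_to_max(out$fc)
  } else {
    warning("no positive corrected FRET response; `fc_norm` set to NA", call. = FALSE)
    out$fc_norm <- NA_real_
  }
  out
}
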