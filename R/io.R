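#' Read a spectrum from two-column delimited text
#'
#' Reads `mz intensity` pairs separated by whitespace, commas or
#' semicolons; lines starting with `#` (and blank lines) are skipped.
#' Duplicate m/z values are merged by summing their intensities; unsorted
#' input is sorted with a warning. Malformed rows are reported with their
#' line numbers.
#'
#' @param path Path to the text file.
#' @return A tibble of class `ms_spectrum` with columns `mz`, `intensity`
#'   (strictly increasing m/z, non-negative intensity).
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop("empty spectrum file: ", path, call. = FALSE)
  ln <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[,;[:space:]]+")
  bad <- vapply(fields, function(f) length(f) != 2 ||
                  anyNA(suppressWarnings(as.numeric(f))), logical(1))
  if (any(bad)) {
    stop("malformed spectrum rows at line(s) ",
         paste(utils::head(ln[bad], 10), collapse = ", "),
         if (sum(bad) > 10) " ..." else "", " in ", path, call. = FALSE)
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 2, byrow = TRUE)
  if (any(m[, 2] < 0)) stop("negative intensities in ", path, call. = FALSE)
  if (is.unsorted(m[, 1], strictly = TRUE)) {
    if (is.unsorted(m[, 1])) {
      warning("m/z values in ", path, " are not sorted; sorting", call. = FALSE)
    }
    o <- order(m[, 1])
    m <- m[o, , drop = FALSE]
    if (anyDuplicated(m[, 1])) {
      agg <- rowsum(m[, 2], group = m[, 1])
      m <- cbind(as.numeric(rownames(agg)), as.numeric(agg))
    }
  }
  out <- tibble::tibble(mz = m[, 1], intensity = m[, 2])
  class(out) <- c("ms_spectrum", class(out))
  out
}

#' Write a spectrum as two-column delimited text
#'
#' @param spectrum Data frame with columns `mz`, `intensity`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  spectrum <- validate_spectrum(spectrum)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# mz intensity", con)
  writeLines(paste(format(spectrum$mz, trim = TRUE, scientific = FALSE),
                   format(spectrum$intensity, trim = TRUE, digits = 15)), con)
  invisible(path)
}

#' Read a titration series from CSV
#'
#' Expects columns `l_total_uM`, `f0..fn` and optionally `replicate`
#' (assumed 1 when absent). Mole-fraction rows are renormalised to unit sum
#' (deviations above 0.05 are an error); lipid concentrations must be
#' strictly increasing within each replicate.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble ready for [fit_sequential_kds()].
#' @export
read_titration <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tit <- readr::read_csv(path, show_col_types = FALSE)
  if (!"replicate" %in% names(tit)) tit$replicate <- 1L
  tit <- validate_titration(tit)
  bad <- tit |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(ok = all(diff(.data$l_total_uM) > 0) || dplyr::n() == 1) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    stop("`l_total_uM` must be strictly increasing within replicate(s) ",
         paste(bad$replicate, collapse = ", "), call. = FALSE)
  }
  tit
}

#' Write a titration series to CSV
#'
#' @param titration Tibble with columns `replicate`, `l_total_uM`,
#'   `f0..fn`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration <- function(titration, path) {
  stopifnot(is.data.frame(titration))
  readr::write_csv(titration, path)
  invisible(path)
}

#' Serialize a binding fit as a JSON report
#'
#' Writes the estimated dissociation constants (uM), fit quality,
#' convergence status, multi-start settings and seed.
#'
#' @param fit A `kd_fit` from [fit_sequential_kds()], or a list of them
#'   (written as a JSON array).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  as_report <- function(f) {
    stopifnot(inherits(f, "kd_fit"))
    list(kd_uM = f$kd_hat, r2 = f$r2, residual_norm = f$residual_norm,
         converged = f$converged, n_starts = f$n_starts_used,
         log10_bounds = f$bounds, seed = f$seed, n_sites = f$n_sites,
         p_total_uM = f$p_total)
  }
  rep <- if (inherits(fit, "kd_fit")) as_report(fit) else lapply(fit, as_report)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
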