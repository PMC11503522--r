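#' Assemble a pipeline run configuration
#'
#' A run configuration drives [run_pipeline()]. It can be built in code or
#' loaded from a YAML file with the same block structure.
#'
#' @param mode One of `"simulate"`, `"analyze"`, `"fit"`, `"fret"`,
#'   `"full"`.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer master seed; stage seeds derive from it.
#' @param binding List: `kd` (true ladder, uM; simulate/full), `n_sites`,
#'   `p_total` (uM), `l_totals` (uM), `base_mass` (Da), `ligand_mass` (Da),
#'   `n_ions`, `n_replicates`, `n_starts`.
#' @param deconv List of [deconv_config()] arguments.
#' @param sim List: `mz_range`, `mz_step`, `peak_fwhm`, `z_center`,
#'   `z_sigma`.
#' @param inputs List of input paths: `titration` (fit mode), `spectra`
#'   (analyze mode: CSV with columns `path`, `l_total_uM`, `replicate`),
#'   `plate` (fret mode).
#' @param verbose Emit progress messages to standard error.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("full", "simulate", "analyze", "fit", "fret"),
                       out_dir = "lipidnms-run", seed = 1,
                       binding = list(), deconv = list(), sim = list(),
                       inputs = list(), verbose = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(seed), length(seed) == 1, seed == round(seed))
  b_def <- list(kd = c(1, 2, 5), n_sites = NULL, p_total = 1,
                l_totals = c(0, 1, 2.5, 5, 10, 15, 20, 25),
                base_mass = 99600, ligand_mass = 750,
                n_ions = 2000, n_replicates = 3, n_starts = 10)
  s_def <- list(mz_range = c(2000, 20000), mz_step = 0.25, peak_fwhm = 0.85,
                z_center = 14, z_sigma = 1.2)
  binding <- utils::modifyList(b_def, binding)
  sim <- utils::modifyList(s_def, sim)
  if (is.null(binding$n_sites)) binding$n_sites <- length(binding$kd)
  structure(list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
                 binding = binding, deconv = deconv, sim = sim,
                 inputs = inputs, verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror the [run_config()]
#'   arguments.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

pipeline_log <- function(config, ...) {
  if (config$verbose) message("[lipidnms] ", ...)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the analysis pipeline
#'
#' Executes the stage sequence of the configured mode and writes its
#' outputs plus a JSON run manifest (config hash, seed, package version,
#' per-file entries) into `out_dir`. Identical configuration and seed
#' reproduce identical outputs.
#'
#' Modes:
#' \describe{
#'   \item{simulate}{Simulate titration spectra of a lipid-binding complex
#'     and write them as two-column text plus the ground-truth titration
#'     CSV.}
#'   \item{analyze}{Deconvolve listed spectra, assign lipid stoichiometries
#'     and write the mole-fraction titration CSV and a Zavg table.}
#'   \item{fit}{Fit per-site dissociation constants to a titration CSV
#'     (per replicate) and write the JSON fit report and replicate
#'     summary.}
#'   \item{fret}{Correct and normalize a FRET plate CSV.}
#'   \item{full}{simulate, analyze and fit chained in memory: spectra are
#'     simulated from the configured true Kd ladder at every titration
#'     point, deconvolved, converted to mole fractions and refitted.}
#' }
#'
#' @param config A [run_config()] or path to a YAML config file.
#' @return A list with the mode's principal results (invisible elements
#'   vary by mode: `titration`, `fits`, `summary`, `zavg`, `plate`,
#'   `manifest_path`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  result <- list()
  b <- config$binding

  make_system <- function(l_total) binding_system(b$kd, b$p_total, l_total)
  dcfg <- do.call(deconv_config, config$deconv)
  cm <- charge_model(config$sim$z_center, config$sim$z_sigma)

  simulate_point <- function(l_total, rep_i) {
    species <- simulate_lipid_ensemble(make_system(l_total),
                                       b$base_mass, b$ligand_mass)
    simulate_spectrum(species, cm,
                      mz_range = config$sim$mz_range,
                      mz_step = config$sim$mz_step,
                      peak_fwhm = config$sim$peak_fwhm,
                      noise = "ion_count", n_ions = b$n_ions,
                      seed = derive_seed(config$seed,
                                         rep_i * 1000 + which(b$l_totals == l_total)))
  }

  analyze_spectra <- function(spec_tbl) {
    # spec_tbl: tibble with columns spectrum (list), l_total_uM, replicate
    rows <- purrr::pmap(spec_tbl, function(spectrum, l_total_uM, replicate) {
      zc <- deconvolve(spectrum, dcfg)
      asg <- assign_species(zc, b$base_mass, b$ligand_mass, b$n_sites)
      f <- stats::setNames(as.list(asg$mole_fraction), paste0("f", asg$n_lipids))
      tibble::as_tibble(c(list(replicate = replicate, l_total_uM = l_total_uM,
                               zavg = average_charge(zc)), f))
    })
    dplyr::bind_rows(rows)
  }

  if (config$mode %in% c("simulate", "full")) {
    pipeline_log(config, "simulating ", length(b$l_totals), " titration points x ",
                 b$n_replicates, " replicates")
    grid <- tidyr::expand_grid(replicate = seq_len(b$n_replicates),
                               l_total_uM = b$l_totals)
    spectra <- stage("simulate", purrr::map2(
      grid$l_total_uM, grid$replicate, simulate_point))
    if (config$mode == "simulate") {
      paths <- file.path(config$out_dir,
                         sprintf("spectrum_rep%d_L%g.txt",
                                 grid$replicate, grid$l_total_uM))
      purrr::walk2(spectra, paths, write_spectrum)
      truth <- simulate_titration(b$kd, b$p_total, b$l_totals, n_ions = Inf,
                                  n_replicates = 1, seed = config$seed)
      tpath <- file.path(config$out_dir, "titration_true.csv")
      write_titration(truth, tpath)
      index <- dplyr::mutate(grid, path = basename(paths))
      ipath <- file.path(config$out_dir, "spectra.csv")
      readr::write_csv(index, ipath)
      outputs <- c(paths, tpath, ipath)
      result$spectra_index <- index
    } else {
      spec_tbl <- dplyr::mutate(grid, spectrum = spectra)[,
        c("spectrum", "l_total_uM", "replicate")]
    }
  }

  if (config$mode == "analyze") {
    idx_path <- config$inputs$spectra
    if (is.null(idx_path)) stop("analyze mode requires `inputs$spectra`", call. = FALSE)
    idx <- stage("read", readr::read_csv(idx_path, show_col_types = FALSE))
    if (nrow(idx) == 0) stop("stage `read` failed: no spectra listed", call. = FALSE)
    spec_tbl <- tibble::tibble(
      spectrum = purrr::map(file.path(dirname(idx_path), idx$path), read_spectrum),
      l_total_uM = idx$l_total_uM, replicate = idx$replicate)
  }

  if (config$mode %in% c("analyze", "full")) {
    pipeline_log(config, "deconvolving ", nrow(spec_tbl), " spectra")
    tit <- stage("deconvolve", analyze_spectra(spec_tbl))
    zavg <- tit[c("replicate", "l_total_uM", "zavg")]
    tit$zavg <- NULL
    tpath <- file.path(config$out_dir, "titration.csv")
    zpath <- file.path(config$out_dir, "zavg.csv")
    write_titration(tit, tpath)
    readr::write_csv(zavg, zpath)
    outputs <- c(outputs, tpath, zpath)
    result$titration <- tit
    result$zavg <- zavg
  }

  if (config$mode == "fit") {
    tp <- config$inputs$titration
    if (is.null(tp)) stop("fit mode requires `inputs$titration`", call. = FALSE)
    result$titration <- stage("read", read_titration(tp))
  }

  if (config$mode %in% c("fit", "full")) {
    pipeline_log(config, "fitting sequential Kd ladder")
    fits <- stage("fit", {
      reps <- split(result$titration, result$titration$replicate)
      lapply(seq_along(reps), function(i)
        fit_sequential_kds(reps[[i]], p_total = b$p_total,
                           seed = derive_seed(config$seed, i),
                           n_starts = b$n_starts))
    })
    summ <- replicate_summary(fits)
    fpath <- file.path(config$out_dir, "kd_fit.json")
    spath <- file.path(config$out_dir, "kd_summary.csv")
    write_fit_report(fits, fpath)
    readr::write_csv(summ, spath)
    outputs <- c(outputs, fpath, spath)
    result$fits <- fits
    result$summary <- summ
    if (config$mode == "full") result$kd_true <- b$kd
  }

  if (config$mode == "fret") {
    pp <- config$inputs$plate
    if (is.null(pp)) stop("fret mode requires `inputs$plate`", call. = FALSE)
    plate <- stage("read", readr::read_csv(pp, show_col_types = FALSE))
    res <- stage("fret", analyze_plate(plate))
    ppath <- file.path(config$out_dir, "fret_corrected.csv")
    readr::write_csv(res, ppath)
    outputs <- c(outputs, ppath)
    result$plate <- res
  }

  manifest <- list(
    package = "lipidnms",
    version = as.character(utils::packageVersion("lipidnms")),
    mode = config$mode, seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    outputs = lapply(basename(outputs), function(f) list(file = f)))
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  result$manifest_path <- mpath
  pipeline_log(config, "done; outputs in ", config$out_dir)
  invisible(result)
}
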