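#' Configuration for an end-to-end error analysis
#'
#' Bundles the inputs and options for [run_analysis()].  Inputs may be file
#' paths (Touchstone `.sNp` for the S-matrix, `ptxsar-vop-json` for the VOP
#' set) or in-memory objects; referenced files must exist when the
#' configuration is built.
#'
#' @param smatrix An [smatrix()] or a path to a Touchstone file.
#' @param vops A [vop_set()] or a path to a VOP container; may be `NULL`
#'   when `analysis` needs no VOPs (`"power_error"`, `"reflected_power"`).
#' @param directivity_db Numeric vector of coupler directivities in dB; each
#'   value yields its own sweep.
#' @param n_phase_steps Phase grid size over \eqn{[0, 2\pi)} (default 360).
#' @param attenuation Linear cable attenuation factor (default 1).
#' @param analysis One of `"sar_error"`, `"power_error"`,
#'   `"reflected_power"`, `"all"`.
#' @param out_dir Output directory (created if missing).
#' @param seed Optional integer recorded in the summary (the analysis itself
#'   is deterministic).
#' @param percent_convention `"of_actual"` (\eqn{(1-1/r)\cdot 100}, default)
#'   or `"of_measured"` (\eqn{(r-1)\cdot 100}); selects the headline
#'   `percent` column, both conventions are always present in the CSV.
#' @param plots Write error-vs-phase and reflected-power-spectrum plot files?
#' @param frequency_hz Optional frequency passed to [read_touchstone()].
#' @return A `"run_config"` list.
#' @seealso [run_analysis()], [read_run_config()]
#' @export
run_config <- function(smatrix, vops = NULL, directivity_db = 25,
                       n_phase_steps = 360L, attenuation = 1,
                       analysis = c("sar_error", "power_error",
                                    "reflected_power", "all"),
                       out_dir = ".", seed = NULL,
                       percent_convention = c("of_actual", "of_measured"),
                       plots = FALSE, frequency_hz = NULL) {
  analysis <- match.arg(analysis)
  percent_convention <- match.arg(percent_convention)
  stopifnot(is.numeric(directivity_db), all(directivity_db > 0),
            n_phase_steps >= 1, attenuation >= 1)
  for (input in list(smatrix, vops)) {
    if (is.character(input) && !file.exists(input)) {
      abort(sprintf("Input file '%s' does not exist.", input),
            class = "ptxsar_bad_input")
    }
  }
  if (is.null(vops) && analysis %in% c("sar_error", "all")) {
    abort("`vops` is required for a SAR error analysis.",
          class = "ptxsar_bad_input")
  }
  structure(list(smatrix = smatrix, vops = vops,
                 directivity_db = directivity_db,
                 n_phase_steps = as.integer(n_phase_steps),
                 attenuation = attenuation, analysis = analysis,
                 out_dir = out_dir, seed = seed,
                 percent_convention = percent_convention, plots = plots,
                 frequency_hz = frequency_hz),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [run_config()]; relative input
#' paths are resolved against the YAML file's directory.
#'
#' @param path Path to a YAML file.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.character(p) && !file.exists(p) && file.exists(file.path(base, p)))
      file.path(base, p) else p
  }
  run_config(
    smatrix = resolve(raw$smatrix),
    vops = resolve(raw$vops),
    directivity_db = raw$directivity_db %||% 25,
    n_phase_steps = raw$n_phase_steps %||% 360L,
    attenuation = raw$attenuation %||% 1,
    analysis = raw$analysis %||% "sar_error",
    out_dir = raw$out_dir %||% ".",
    seed = raw$seed,
    percent_convention = raw$percent_convention %||% "of_actual",
    plots = isTRUE(raw$plots),
    frequency_hz = raw$frequency_hz)
}

input_digest <- function(input) {
  if (is.character(input)) {
    unname(tools::md5sum(input))
  } else {
    tf <- tempfile()
    on.exit(unlink(tf))
    saveRDS(input, tf)           # canonical binary form of in-memory input
    unname(tools::md5sum(tf))
  }
}

#' Run a complete directional-coupler error analysis
#'
#' Loads the inputs, runs the selected analyses for every requested
#' directivity, and writes a report bundle to the output directory:
#' per-phase CSV files (`sweep_<analysis>_<dB>dB.csv` with phase, ratio and
#' both percent conventions), a `summary.json` with the peak errors, solver
#' statuses, software version and input digests, a reflected-power spectrum
#' CSV, and (optionally) plot files.  A solver failure or an unbounded
#' worst case aborts with a diagnostic naming the phase point.
#'
#' @param config A [run_config()].
#' @return The report bundle, invisibly: a list with `sar_sweeps`,
#'   `power_sweeps` (named by directivity), `spectrum`, `summary`.
#' @examples
#' cfg <- run_config(smatrix = synth_smatrix(2, 0.2, 0.05, seed = 1),
#'                   vops = synth_vops(2, 2, rank = 2, seed = 2),
#'                   directivity_db = 25, n_phase_steps = 12,
#'                   analysis = "all", out_dir = tempfile("ptxsar"))
#' bundle <- run_analysis(cfg)
#' bundle$summary$peaks
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  S <- if (is.character(config$smatrix)) {
    read_touchstone(config$smatrix, frequency_hz = config$frequency_hz)
  } else as_smatrix(config$smatrix)
  vops <- NULL
  if (!is.null(config$vops)) {
    vops <- if (is.character(config$vops)) read_vops(config$vops) else
      as_vop_set(config$vops)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  do_sar <- config$analysis %in% c("sar_error", "all")
  do_power <- config$analysis %in% c("power_error", "all")
  do_spec <- config$analysis %in% c("reflected_power", "all")

  headline <- function(r) {
    if (config$percent_convention == "of_actual") (1 - 1 / r) * 100
    else (r - 1) * 100
  }
  sar_sweeps <- list()
  power_sweeps <- list()
  peaks <- list()
  for (db in config$directivity_db) {
    key <- sprintf("%gdB", db)
    if (do_sar) {
      sw <- phase_sweep(vops, S, db, n_steps = config$n_phase_steps,
                        attenuation = config$attenuation)
      sar_sweeps[[key]] <- sw
      out <- dplyr::mutate(tidy(sw), percent = headline(.data$ratio),
                           .after = "ratio")
      readr::write_csv(out, file.path(config$out_dir,
                                      sprintf("sweep_sar_%s.csv", key)))
      peaks[[length(peaks) + 1]] <- tibble(
        analysis = "sar_error", directivity_db = db,
        peak_ratio = sw$peak_ratio,
        peak_percent = headline(sw$peak_ratio),
        peak_phase_rad = sw$peak_phase_rad,
        max_certificate_gap = max(sw$sweep$certificate_gap))
    }
    if (do_power) {
      sw <- power_error_sweep(S, db, n_steps = config$n_phase_steps,
                              attenuation = config$attenuation)
      power_sweeps[[key]] <- sw
      out <- dplyr::mutate(tidy(sw), percent = headline(.data$ratio),
                           .after = "ratio")
      readr::write_csv(out, file.path(config$out_dir,
                                      sprintf("sweep_power_%s.csv", key)))
      peaks[[length(peaks) + 1]] <- tibble(
        analysis = "power_error", directivity_db = db,
        peak_ratio = sw$peak_ratio,
        peak_percent = headline(sw$peak_ratio),
        peak_phase_rad = sw$peak_phase_rad,
        max_certificate_gap = 0)
    }
  }
  spectrum <- NULL
  if (do_spec) {
    spectrum <- reflected_power_spectrum(S)
    readr::write_csv(tidy(spectrum),
                     file.path(config$out_dir, "reflected_power_spectrum.csv"))
  }
  peaks <- dplyr::bind_rows(peaks)
  summary <- list(
    package = "ptxsar",
    version = as.character(packageVersion("ptxsar")),
    analysis = config$analysis,
    n_phase_steps = config$n_phase_steps,
    directivity_db = config$directivity_db,
    attenuation = config$attenuation,
    percent_convention = config$percent_convention,
    seed = config$seed,
    n_channels = S$n_channels,
    max_reflected_power = max_shs_eigenvalue(S$values),
    input_digests = list(
      smatrix = input_digest(config$smatrix),
      vops = if (is.null(config$vops)) NULL else input_digest(config$vops)),
    peaks = peaks,
    generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null")
  if (isTRUE(config$plots)) {
    for (key in names(sar_sweeps)) {
      ggplot2::ggsave(file.path(config$out_dir,
                                sprintf("sweep_sar_%s.png", key)),
                      autoplot(sar_sweeps[[key]]), width = 7, height = 4,
                      dpi = 150)
    }
    for (key in names(power_sweeps)) {
      ggplot2::ggsave(file.path(config$out_dir,
                                sprintf("sweep_power_%s.png", key)),
                      autoplot(power_sweeps[[key]]), width = 7, height = 4,
                      dpi = 150)
    }
    if (!is.null(spectrum)) {
      ggplot2::ggsave(file.path(config$out_dir,
                                "reflected_power_spectrum.png"),
                      autoplot(spectrum), width = 5, height = 4, dpi = 150)
    }
  }
  invisible(list(sar_sweeps = sar_sweeps, power_sweeps = power_sweeps,
                 spectrum = spectrum, summary = summary))
}
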