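#' Run the end-to-end calibration workflow
#'
#' File-to-file orchestration of [calibrate_trap()]: reads a trajectory and
#' its metadata sidecar, resolves the physical environment (explicit
#' viscosity, or the built-in water reference at the given temperature),
#' runs the calibration and writes a structured-text (YAML) report holding
#' the package version, the fully resolved configuration, the seed, and every
#' intermediate quantity with units.
#'
#' @param config a named list (or path to a YAML file) with elements:
#'   `input` (trajectory CSV; sidecar defaults to `<input>.yml`),
#'   `report` (output report path; default `<input>.report.yml`),
#'   `temperature_k`, `bead_radius_m`, and either `viscosity_pa_s` or
#'   `solvent: water`; optional `block`, `window`, `band`, `bins`,
#'   `pca`, `spike_half_window`, `spike_criterion`, `seed`. Values present
#'   in the trajectory sidecar are used as defaults.
#' @return The `trap_calibration` object, invisibly, with the report path in
#'   attribute `"report"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$input))
    stop_trapcal("config is missing 'input' (trajectory file path)", "config_error")
  tr <- read_trajectory(config$input)
  meta <- attr(tr, "metadata")
  get <- function(name, default = NULL) {
    if (!is.null(config[[name]])) config[[name]]
    else if (!is.null(meta[[name]])) meta[[name]]
    else default
  }
  temperature <- get("temperature_k")
  if (is.null(temperature))
    stop_trapcal("missing parameter 'temperature_k'", "config_error")
  radius <- get("bead_radius_m")
  if (is.null(radius))
    stop_trapcal("missing parameter 'bead_radius_m'", "config_error")
  eta <- get("viscosity_pa_s")
  if (is.null(eta)) {
    solvent <- get("solvent")
    if (is.null(solvent))
      stop_trapcal("missing parameter 'viscosity_pa_s' (or 'solvent: water')",
                   "config_error")
    if (!identical(tolower(solvent), "water"))
      stop_trapcal(sprintf("unknown solvent '%s': supply 'viscosity_pa_s'", solvent),
                   "config_error")
    eta <- water_viscosity(temperature)
  }
  env <- trap_environment(temperature, eta, radius)
  cal <- calibrate_trap(
    tr, env,
    block = get("block", 1),
    pre_blocked = get("blocked_by", 1),
    window = get("window", "auto"),
    pca = get("pca", TRUE),
    band = if (!is.null(config$band)) as.numeric(config$band),
    spike_half_window = get("spike_half_window", 20),
    spike_criterion = get("spike_criterion", 5),
    bins = get("bins", 100))

  report <- get("report", paste0(config$input, ".report.yml"))
  tab <- axis_table(cal)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    p <- cal$per_axis[[tab$axis[i]]]
    list(axis = tab$axis[i],
         corner_frequency_hz = tab$corner_frequency_hz[i],
         kappa_n_per_m = tab$kappa_n_per_m[i],
         kappa_pn_per_um = tab$kappa_pn_per_um[i],
         sigma_m_m = p$sigma_m,
         sigma_psd = p$sigma_psd,
         delta = tab$delta_nm_per_unit[i],
         delta_units = paste0("nm/", cal$settings$signal_units),
         fit_residual = p$fit$residual,
         fit_band_hz = p$fit$band)
  })
  out <- list(
    tool = "trapcal",
    version = as.character(utils::packageVersion("trapcal")),
    seed = get("seed"),
    input = config$input,
    environment = list(temperature_k = env$temperature,
                       viscosity_pa_s = env$viscosity,
                       bead_radius_m = env$bead_radius,
                       gamma0_kg_per_s = env$gamma0),
    config = c(cal$settings,
               list(rotation_angle_deg = if (!is.null(cal$rotation))
                 cal$rotation$angle * 180 / pi)),
    results = rows)
  yaml::write_yaml(out, report, precision = 12)
  attr(cal, "report") <- report
  invisible(cal)
}
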