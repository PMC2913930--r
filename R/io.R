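#' Read and write trajectories as CSV
#'
#' UTF-8, comma-separated, header row, `.` decimal; times in hours,
#' concentrations in nM (deterministic) or molecule counts (stochastic).
#' The reader restores the trajectory class so every file the package
#' writes is parseable by its own readers.
#'
#' @param traj A `p53_trajectory` or `p53_ssa_trajectory`.
#' @param file Path to write to / read from.
#' @return `write_trajectory_csv` returns `file` invisibly;
#'   `read_trajectory_csv` returns the trajectory data frame.
#' @export
write_trajectory_csv <- function(traj, file) {
  stopifnot(is.data.frame(traj))
  utils::write.csv(as.data.frame(traj), file, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(file) {
  df <- utils::read.csv(file, fileEncoding = "UTF-8")
  cls <- if ("n_p" %in% names(df)) "p53_ssa_trajectory" else "p53_trajectory"
  structure(df, class = c(cls, "data.frame"))
}

#' Read and write stress scenarios as YAML
#'
#' A scenario file holds `name`, a `fold_changes` map and a `sign_pattern`
#' map; [read_scenario()] validates the result through
#' [stress_scenario()].
#'
#' @param scenario A [stress_scenario()].
#' @param file Path to write to / read from.
#' @return `write_scenario` returns `file` invisibly; `read_scenario`
#'   returns the scenario.
#' @export
write_scenario <- function(scenario, file) {
  stopifnot(inherits(scenario, "p53_scenario"))
  yaml::write_yaml(list(name = scenario$name,
                        fold_changes = as.list(scenario$fold_changes),
                        sign_pattern = as.list(scenario$sign_pattern)),
                   file, precision = 15L)
  invisible(file)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(file) {
  raw <- yaml::read_yaml(file)
  if (is.null(raw$name) || is.null(raw$fold_changes))
    stop("scenario file must define 'name' and 'fold_changes'", call. = FALSE)
  stress_scenario(raw$name, unlist(raw$fold_changes),
                  sign_pattern = if (!is.null(raw$sign_pattern))
                    unlist(raw$sign_pattern) else NULL)
}

#' Run manifest
#'
#' Every command-line run emits one manifest recording the tool version,
#' parameter set, scenario, solver settings, seeds, timestamp and output
#' file inventory, sufficient to bit-reproduce deterministic outputs.
#'
#' @param command Subcommand name.
#' @param params Parameter set used.
#' @param scenario Scenario used, or `NULL`.
#' @param solver List of solver settings.
#' @param seed Seed, or `NULL` for deterministic commands.
#' @param outputs Character vector of files written.
#' @param extra Optional named list of additional entries.
#' @return A list of class `p53_manifest`.
#' @export
run_manifest <- function(command, params, scenario = NULL, solver = list(),
                         seed = NULL, outputs = character(0),
                         extra = list()) {
  m <- c(list(
    tool = "p53loop",
    version = as.character(utils::packageVersion("p53loop")),
    command = command,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = params[c(.rate_names, "hill", "variant")],
    scenario = if (!is.null(scenario))
      list(name = scenario$name,
           fold_changes = as.list(scenario$fold_changes)) else NULL,
    solver = solver,
    seed = seed,
    outputs = as.list(outputs)), extra)
  structure(m, class = "p53_manifest")
}

#' @rdname run_manifest
#' @param manifest A manifest.
#' @param file Path of the JSON file to write.
#' @export
write_manifest <- function(manifest, file) {
  jsonlite::write_json(unclass(manifest), file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(file)
}

#' Canned deterministic fixtures for tests and examples
#'
#' @return A list with `defaults` (the default parameter set),
#'   `gamma2_oscillator` (defaults with the Mdm2 removal rate doubled, past
#'   the oscillation onset), `dna_damage` (the packaged calibrated
#'   scenario), and `sinusoid` (a synthetic trajectory
#'   `100 + 50 sin(2 pi t / 6)` nM over 60 h, period 6 h, used to exercise
#'   the oscillation metrics against closed-form values).
#' @examples
#' fx <- fixtures()
#' fx$gamma2_oscillator$gamma    # 0.4
#' @export
fixtures <- function() {
  tt <- seq(0, 60, by = 0.01)
  x <- 100 + 50 * sin(2 * pi * tt / 6)
  sinus <- structure(
    data.frame(time_h = tt, p_nM = x, mm_nM = 0 * tt, m_nM = 0 * tt,
               c_nM = 0 * tt, total_p53_nM = x),
    class = c("p53_trajectory", "data.frame"))
  list(defaults = p53_parameters(),
       gamma2_oscillator = set_parameters(p53_parameters(), gamma = 0.4),
       dna_damage = builtin_scenarios()$dna_damage,
       sinusoid = sinus)
}
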