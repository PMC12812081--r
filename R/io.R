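#' Scenario presets
#'
#' Named parameter sets for the worked examples: `fig2a` (identical
#' encounter rates, several values of the mean rate), `fig2b` (exponentially
#' distributed rates, i.e. Gamma shape 1), `fig3a`/`fig3b`/`fig3c` (Gamma
#' rates with shape 100/10/1 and rate 1000/100/10, equal mean 0.1), and the
#' dynamic problems `fig4a` (three-phase regime) and `fig4b` (two-phase
#' regime). The quasi-static presets fix the combination `K u n / m = 1e4`;
#' only that product enters the schedule, and it is decomposed here as
#' `n = 1000, m = 1, u = 1, K = 10`. The dynamic presets do not determine
#' the peripheral decay rate `u`; it is a required user input.
#'
#' @return a named list of preset parameter lists.
#' @export
scenario_presets <- function() {
  quasi <- list(n = 1000, m = 1, u = 1, K = 10) # K u n / m = 1e4
  list(
    fig2a = c(quasi, list(kind = "degenerate",
                          mean_rates = c(0.05, 0.1, 0.2), # illustrative defaults
                          T = 50)),
    fig2b = c(quasi, list(kind = "gamma", shape = 1, rate_param = 10, T = 50)),
    fig3a = c(quasi, list(kind = "gamma", shape = 100, rate_param = 1000, T = 50)),
    fig3b = c(quasi, list(kind = "gamma", shape = 10, rate_param = 100, T = 50)),
    fig3c = c(quasi, list(kind = "gamma", shape = 1, rate_param = 10, T = 50)),
    fig4a = list(kind = "degenerate", n = 1000, mean_rate = 0.275,
                 m = 1, K = 0.001, h_max = 3, T = 10, u = NA_real_),
    fig4b = list(kind = "degenerate", n = 1000, mean_rate = 0.2751,
                 m = 1, K = 0.001, h_max = 0.1, T = 10, u = NA_real_)
  )
}

.config_keys <- c("scenario", "out_dir", "seed", "overrides",
                  "kind", "n", "mean_rate", "mean_rates", "shape", "rate_param",
                  "log_mean", "log_var", "rates",
                  "K", "m", "u", "h_max", "T", "C", "N0")

#' Load and validate a scenario configuration
#'
#' Reads a JSON mapping with either a `scenario` preset name or explicit
#' parameters, applies overrides, rejects unknown keys, and prepares a
#' provenance manifest (fully resolved parameters, seed and package
#' version) that [write_outputs()] echoes next to every result.
#'
#' @param path path to a JSON config file, or a named list.
#' @return an object of class `scenario_config` with elements `params`
#'   (fully resolved), `seed`, `out_dir` and `manifest`.
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else path
  if (!is.list(cfg) || length(cfg) == 0L)
    stop("config is empty: provide a 'scenario' preset name or explicit parameters")
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))

  params <- list()
  if (!is.null(cfg$scenario)) {
    presets <- scenario_presets()
    if (!cfg$scenario %in% names(presets))
      stop("unknown scenario '", cfg$scenario, "'; available: ",
           paste(names(presets), collapse = ", "))
    params <- presets[[cfg$scenario]]
  }
  direct <- cfg[setdiff(names(cfg), c("scenario", "out_dir", "seed", "overrides"))]
  params[names(direct)] <- direct
  if (!is.null(cfg$overrides)) {
    unknown <- setdiff(names(cfg$overrides), .config_keys)
    if (length(unknown))
      stop("unknown override keys: ", paste(unknown, collapse = ", "))
    params[names(cfg$overrides)] <- cfg$overrides
  }
  if (is.null(cfg$scenario) && is.null(params$kind))
    stop("config must name a 'scenario' preset or give an explicit model 'kind'")
  if (!is.null(params$u) && is.na(params$u))
    stop("required field 'u' (peripheral clone decay rate) is missing: ",
         "this scenario does not determine it")

  manifest <- list(
    scenario = cfg$scenario,
    resolved_params = params,
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("thymodel")))
  structure(list(params = params, seed = cfg$seed,
                 out_dir = cfg$out_dir, manifest = manifest),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario config", if (!is.null(x$manifest$scenario))
    paste0("(preset '", x$manifest$scenario, "')"), "\n")
  utils::str(x$params, give.attr = FALSE)
  invisible(x)
}

config_model <- function(config) {
  p <- config$params
  args <- p[intersect(names(p), c("kind", "n", "mean_rate", "shape", "rate_param",
                                  "log_mean", "log_var", "rates"))]
  do.call(encounter_model, args)
}

config_problem <- function(config) {
  p <- config$params
  cp <- cost_params(p$K, p$m, p$u)
  control_problem(cp, config_model(config), T = p$T, h_max = p$h_max,
                  C = if (is.null(p$C)) 0 else p$C,
                  N0 = p$N0)
}

#' Write deterministic result files for a run
#'
#' Serializes results with a stable column order: trajectories as CSV
#' (`t,N,lambda,h,psi`), schedules and certificates as JSON, plus a
#' `manifest.json` echoing the resolved configuration. Two runs with
#' identical config and seed produce byte-identical files.
#'
#' @param results a named list; recognized elements are `trajectory`
#'   (a [integrate_trajectory()] result), `schedule` (a phase schedule),
#'   `certificate` (a [pmp_certificate()]), `table` (any data.frame, e.g.
#'   from [quasistatic_schedule()]), and `summary` (any list, written as
#'   JSON).
#' @param config a [load_config()] result with a non-`NULL` `out_dir`.
#' @return character vector of the paths written, invisibly.
#' @export
write_outputs <- function(results, config) {
  stopifnot(inherits(config, "scenario_config"))
  dir <- config$out_dir
  if (is.null(dir)) stop("config has no 'out_dir'")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  wjson <- function(x, file) {
    path <- file.path(dir, file)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", na = "null")
    path
  }
  if (!is.null(results$trajectory)) {
    tr <- results$trajectory
    df <- data.frame(t = tr$ages, N = tr$N, lambda = tr$lam, h = tr$h, psi = tr$psi)
    path <- file.path(dir, "trajectory.csv")
    utils::write.csv(df, path, row.names = FALSE)
    written <- c(written, path)
  }
  if (!is.null(results$schedule)) {
    s <- results$schedule
    written <- c(written, wjson(list(structure = s$structure, t1 = s$t1, t2 = s$t2,
                                     t3 = s$t3, T = s$T, h_max = s$h_max,
                                     phi = results$phi), "schedule.json"))
  }
  if (!is.null(results$certificate)) {
    cert <- unclass(results$certificate)
    written <- c(written, wjson(cert, "certificate.json"))
  }
  if (!is.null(results$table)) {
    path <- file.path(dir, "schedule_table.csv")
    utils::write.csv(results$table, path, row.names = FALSE)
    written <- c(written, path)
  }
  if (!is.null(results$summary)) {
    written <- c(written, wjson(results$summary, "summary.json"))
  }
  written <- c(written, wjson(config$manifest, "manifest.json"))
  invisible(written)
}

#' Rebuild a phase schedule from its JSON serialization
#'
#' @param path path to a `schedule.json` written by [write_outputs()].
#' @param problem the [control_problem()] the schedule belongs to.
#' @return a `phase_schedule`.
#' @export
read_schedule_json <- function(path, problem) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  null2na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  t1 <- null2na(s$t1); t2 <- null2na(s$t2); t3 <- null2na(s$t3)
  Tmax <- problem$T
  if (identical(s$structure, "three_phase")) {
    pieces <- list(
      control_piece(0, t1, problem$h_max, "max"),
      control_piece(t1, t2, function(t) singular_control(t, problem, check = FALSE),
                    "singular"),
      control_piece(t2, Tmax, 0, "zero"))
    new_phase_schedule("three_phase", problem, t1 = t1, t2 = t2, pieces = pieces)
  } else {
    pieces <- if (t3 <= 0) list(control_piece(0, Tmax, 0, "zero"))
              else if (t3 >= Tmax) list(control_piece(0, Tmax, problem$h_max, "max"))
              else list(control_piece(0, t3, problem$h_max, "max"),
                        control_piece(t3, Tmax, 0, "zero"))
    new_phase_schedule("two_phase", problem, t3 = t3, pieces = pieces)
  }
}
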