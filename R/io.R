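# Config loading and CSV trajectory round-trips.

.config_known <- list(
  top = c("scenario", "params", "seed", "horizon", "n_replicates", "out",
          "onset", "stationary", "intervention", "equilibria"),
  params = c("d", "b", "q", "p", "S_plus", "h", "k"),
  onset = c("E0", "dE", "E_end", "lam0", "dlam", "lam_end"),
  stationary = c("E", "lambda", "C0", "S0"),
  intervention = c("duration_weeks", "p_treat", "lam_treat", "S_plus_base",
                   "lam_base", "E_base", "eval_week", "success_threshold"),
  equilibria = c("E_min", "E_max", "step")
)

.check_keys <- function(block, known, where) {
  unknown <- setdiff(names(block), known)
  if (length(unknown))
    stop("config validation error: unknown key '", unknown[1],
         "' in ", where, call. = FALSE)
}

#' Load and validate a run configuration
#'
#' Reads a YAML file describing one run: a `scenario` selector (one of
#' `onset`, `stationary`, `intervention`, `equilibria`), an optional `params`
#' block overriding the default model parameters, an optional
#' scenario-specific block, plus `seed`, `horizon`, `n_replicates` and `out`.
#' Unknown keys are rejected by name (fail fast), every model-parameter
#' invariant — including the boundedness requirement `b q < 1` — is checked
#' at load time, and parse failures are reported distinctly from validation
#' failures.
#'
#' @param path path to the YAML config file
#' @return a list of class `run_config` with fully resolved defaults
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config parse error: file not found: ", path, call. = FALSE)
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("config parse error in '", path, "': ", conditionMessage(e),
         call. = FALSE))
  if (!is.list(cfg))
    stop("config parse error: '", path, "' does not contain a mapping",
         call. = FALSE)
  .check_keys(cfg, .config_known$top, "top level")
  if (is.null(cfg$scenario))
    stop("config validation error: missing key 'scenario'", call. = FALSE)
  if (!cfg$scenario %in% c("onset", "stationary", "intervention", "equilibria"))
    stop("config validation error: key 'scenario' must be one of ",
         "onset, stationary, intervention, equilibria", call. = FALSE)

  pblock <- cfg$params
  if (!is.null(pblock)) .check_keys(pblock, .config_known$params, "'params' block")
  pdef <- default_params()
  pargs <- utils::modifyList(unclass(pdef)[.config_known$params],
                             if (is.null(pblock)) list() else pblock)
  params <- tryCatch(do.call(model_params, pargs), error = function(e)
    stop("config validation error in 'params': ", conditionMessage(e),
         call. = FALSE))

  for (blk in c("onset", "stationary", "intervention", "equilibria")) {
    if (!is.null(cfg[[blk]])) {
      if (blk != cfg$scenario)
        stop("config validation error: block '", blk,
             "' does not match scenario '", cfg$scenario, "'", call. = FALSE)
      .check_keys(cfg[[blk]], .config_known[[blk]],
                  paste0("'", blk, "' block"))
    }
  }

  scen_args <- if (is.null(cfg[[cfg$scenario]])) list() else cfg[[cfg$scenario]]
  scenario_spec <- tryCatch(switch(cfg$scenario,
    onset = do.call(onset_schedule, scen_args),
    intervention = do.call(intervention_protocol, scen_args),
    stationary = utils::modifyList(list(E = 0.1525, lambda = 1,
                                        C0 = 0, S0 = params$S_plus), scen_args),
    equilibria = utils::modifyList(list(E_min = -0.6, E_max = 0.35,
                                        step = 0.005), scen_args)
  ), error = function(e)
    stop("config validation error in '", cfg$scenario, "': ",
         conditionMessage(e), call. = FALSE))

  structure(list(scenario = cfg$scenario, params = params,
                 scenario_spec = scenario_spec,
                 seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
                 horizon = if (is.null(cfg$horizon)) NULL else as.integer(cfg$horizon),
                 n_replicates = if (is.null(cfg$n_replicates)) 50L
                                else as.integer(cfg$n_replicates),
                 out = cfg$out),
            class = "run_config")
}

#' Write a trajectory to CSV
#'
#' Columns `t,C,S,E,lambda,R,A,V`, one row per week, written at full
#' floating-point precision (17 significant digits) so that
#' [read_trajectory()] restores numerically identical records.
#'
#' @param trajectory a `craving_trajectory` (or any data frame with the
#'   trajectory columns)
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(trajectory, path) {
  cols <- c("t", "C", "S", "E", "lambda", "R", "A", "V")
  if (!all(cols %in% names(trajectory)))
    stop("not a trajectory: missing columns ",
         paste(setdiff(cols, names(trajectory)), collapse = ", "),
         call. = FALSE)
  df <- trajectory[cols]
  out <- data.frame(t = df$t, R = df$R)
  for (nm in setdiff(cols, c("t", "R"))) out[[nm]] <- sprintf("%.17g", df[[nm]])
  out <- out[cols]
  tryCatch(utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
           error = function(e)
             stop("failed to write trajectory to '", path, "': ",
                  conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV file path
#' @return a `craving_trajectory` data frame
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path))
    stop("trajectory file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  df$t <- as.integer(df$t); df$R <- as.integer(df$R)
  for (nm in c("C", "S", "E", "lambda", "A", "V")) df[[nm]] <- as.double(df[[nm]])
  structure(df, class = c("craving_trajectory", "data.frame"))
}

#' Write a branch diagram to CSV
#'
#' Columns `E, C_star, S_star, regime, stable, eig1, eig2`.
#'
#' @param diagram a `branch_diagram` from [sweep_branches()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_branches <- function(diagram, path) {
  df <- diagram$branches[c("E", "C_star", "S_star", "regime",
                           "stable", "eig1", "eig2")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
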