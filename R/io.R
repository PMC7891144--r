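# Configuration files, trajectory/summary writers, CLI plumbing.

#' Default run configuration
#'
#' A run configuration is a plain named list, serialized as YAML, that
#' fully specifies an experiment: parameter overrides (Table values are
#' the defaults; only overrides are listed), light schedule, perturbations,
#' solver and entrainment settings, output formats and a recorded random
#' seed (the model is deterministic; the seed is stored for provenance
#' only).
#'
#' @return Named list with components `parameters`, `schedule`,
#'   `perturbations`, `solver`, `entrain`, `outputs`, `seed`.
#' @export
default_run_config <- function() {
  list(
    parameters = list(),
    schedule = list(mode = "LD", xi = 2 / 3, dd_level = 1),
    perturbations = list(),
    solver = list(method = "lsoda", rtol = 1e-8, atol = 1e-10, dt = 0.05),
    entrain = list(
      burn_in_days = 40, max_days = 90, cycle_tol = 1e-4, keep_cycles = 3
    ),
    outputs = list(formats = c("tidy_csv", "wide_csv", "json")),
    seed = 1
  )
}

#' Read and validate a run configuration
#'
#' @param path YAML file.
#' @return Validated configuration list (unspecified fields filled with
#'   defaults).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' Write a run configuration
#'
#' @param config configuration list.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  config <- validate_run_config(config)
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

validate_run_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a named list", call. = FALSE)
  known <- names(default_run_config())
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
      "; valid sections: ", paste(known, collapse = ", "),
      call. = FALSE
    )
  }
  def <- default_run_config()
  merged <- def
  for (nm in names(cfg)) {
    # perturbations is an unnamed list of specs: replace, never merge
    if (nm == "perturbations" || !is.list(def[[nm]])) {
      merged[[nm]] <- cfg[[nm]]
    } else {
      merged[[nm]] <- utils::modifyList(def[[nm]], cfg[[nm]])
    }
  }
  cfg <- merged
  # parameter overrides are validated by clock_params (lists valid names)
  do.call(clock_params, cfg$parameters)
  if (!cfg$schedule$mode %in% c("LD", "DD", "custom")) {
    stop("schedule$mode must be LD, DD or custom", call. = FALSE)
  }
  for (p in cfg$perturbations) {
    if (is.null(p$kind) ||
      !p$kind %in% c("cry_deficiency", "agonist_injection", "custom_scale")) {
      stop(
        "perturbation kind must be one of cry_deficiency, ",
        "agonist_injection, custom_scale",
        call. = FALSE
      )
    }
    if (!is.null(p$magnitude) && p$magnitude < 0) {
      stop("perturbation magnitude must be >= 0", call. = FALSE)
    }
    if (identical(p$kind, "agonist_injection")) {
      zt <- p$injection_time_ZT %||% 0
      if (zt < 0 || zt >= 24) {
        stop("injection_time_ZT must lie in [0, 24)", call. = FALSE)
      }
    }
    if (identical(p$kind, "custom_scale") && is.null(p$parameter)) {
      stop("custom_scale perturbation needs a 'parameter' field",
        call. = FALSE
      )
    }
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_params <- function(cfg) {
  params <- do.call(clock_params, cfg$parameters)
  for (p in cfg$perturbations) {
    if (identical(p$kind, "cry_deficiency")) {
      params <- cry_deficiency(params, p$magnitude %||% 0.95)
    } else if (identical(p$kind, "custom_scale")) {
      ov <- list(params[[p$parameter]] * (p$magnitude %||% 1))
      names(ov) <- p$parameter
      params <- do.call(
        clock_params,
        utils::modifyList(as.list(unclass(params)), ov)
      )
    }
  }
  params
}

config_schedule <- function(cfg) {
  s <- cfg$schedule
  bp <- if (!is.null(s$breakpoints)) {
    as.data.frame(lapply(s$breakpoints, unlist))
  }
  light_schedule(s$mode, xi = s$xi %||% 2 / 3,
    dd_level = s$dd_level %||% 1, breakpoints = bp
  )
}

# numbers written with enough digits to round-trip exactly
fmt_full <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 17, format = "g"))
}

#' Write a trajectory as CSV
#'
#' Tidy format has columns `time_hr, variable, value_nM`; wide format one
#' column per state variable. Numbers are written with 17 significant
#' digits so that reading the file back reproduces the doubles exactly.
#'
#' @param trajectory a `clock_trajectory`.
#' @param path output file.
#' @param format `"tidy"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path,
                                 format = c("tidy", "wide")) {
  format <- match.arg(format)
  df <- if (format == "tidy") {
    tidy_trajectory(trajectory)
  } else {
    as.data.frame(trajectory)
  }
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_full)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wide-format trajectory CSV
#'
#' Reconstructs the numeric time grid and state matrix written by
#' [write_trajectory_csv()] (wide format). Metadata (parameters, schedule,
#' solver) lives in the JSON sidecar and is not restored here.
#'
#' @param path CSV file.
#' @return List with `time` and `state` (matrix).
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_hr" %in% names(df)) {
    stop("not a wide trajectory CSV (no time_hr column)", call. = FALSE)
  }
  list(
    time = df$time_hr,
    state = as.matrix(df[setdiff(names(df), "time_hr")])
  )
}

#' Write a rhythm summary or expression profile
#'
#' @param x a [rhythm_summary()] data frame (JSON) or
#'   [expression_profiles()] data frame (CSV, columns `ZT_hr, ETH, EMAO`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rhythm_summary <- function(x, path) {
  jsonlite::write_json(x, path, dataframe = "rows", digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_rhythm_summary
#' @export
write_expression_profile <- function(x, path) {
  df <- as.data.frame(x)
  df[] <- lapply(df, fmt_full)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

run_metadata <- function(cfg, trajectory, extra = list()) {
  c(
    list(
      package_version = as.character(utils::packageVersion("circadopa")),
      config = cfg,
      solver = trajectory$solver,
      burn_in_hours = trajectory$burn_in_hours,
      achieved_residual = trajectory$achieved_residual %||% NA,
      residual_history = trajectory$residual_history %||% NA
    ),
    extra
  )
}

write_outputs <- function(trajectory, cfg, out_dir, stem, extra = list()) {
  fm <- cfg$outputs$formats
  paths <- character(0)
  if ("tidy_csv" %in% fm) {
    p <- file.path(out_dir, paste0(stem, "_tidy.csv"))
    write_trajectory_csv(trajectory, p, "tidy")
    paths <- c(paths, p)
  }
  if ("wide_csv" %in% fm) {
    p <- file.path(out_dir, paste0(stem, "_wide.csv"))
    write_trajectory_csv(trajectory, p, "wide")
    paths <- c(paths, p)
  }
  if ("json" %in% fm) {
    p <- file.path(out_dir, paste0(stem, "_meta.json"))
    jsonlite::write_json(
      run_metadata(cfg, trajectory, extra), p,
      auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
    )
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Command-line interface
#'
#' Entry point behind the `inst/cli/circadopa.R` script. Subcommands:
#' \describe{
#'   \item{simulate}{integrate from the default start over `--days` days.}
#'   \item{entrain}{entrain to the configured schedule and write the final
#'     cycles, rhythm summary and TH/MAO expression profile.}
#'   \item{agonist}{run the agonist injection experiment configured under
#'     `perturbations` and write treated/control trajectories plus the
#'     windowed phase-shift table.}
#'   \item{perturb}{apply the configured parameter perturbations (e.g. CRY
#'     deficiency) and entrain.}
#'   \item{summarize}{recompute the rhythm summary from a wide trajectory
#'     CSV given with `--trajectory`.}
#' }
#' Every subcommand takes `--config <yaml>` (optional; defaults are the
#' reference setup) and `--out-dir <dir>`. Solver diagnostics and the
#' entrainment residual history go to the JSON sidecar and to stderr.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return Exit status, invisibly (0 on success).
#' @export
circadopa_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch(
    {
      cli_dispatch(args)
      0L
    },
    error = function(e) {
      message("error: ", conditionMessage(e))
      1L
    }
  )
  invisible(status)
}

cli_opt <- function(args, name, default = NULL) {
  i <- which(args == name)
  if (!length(i)) {
    return(default)
  }
  if (i[1] == length(args)) stop(name, " needs a value", call. = FALSE)
  args[i[1] + 1]
}

cli_dispatch <- function(args) {
  if (!length(args)) {
    stop(
      "usage: circadopa.R <simulate|entrain|agonist|perturb|summarize> ",
      "[--config cfg.yaml] [--out-dir dir] [--days n] [--trajectory csv]",
      call. = FALSE
    )
  }
  cmd <- args[1]
  cfg <- if (!is.null(cp <- cli_opt(args, "--config"))) {
    read_run_config(cp)
  } else {
    default_run_config()
  }
  out_dir <- cli_opt(args, "--out-dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  params <- config_params(cfg)
  schedule <- config_schedule(cfg)
  sv <- cfg$solver
  en <- cfg$entrain

  entrain_cfg <- function(p) {
    entrain_clock(p, schedule,
      burn_in_days = en$burn_in_days, max_days = en$max_days,
      cycle_tol = en$cycle_tol, keep_cycles = en$keep_cycles,
      dt = sv$dt, rtol = sv$rtol, atol = sv$atol, method = sv$method
    )
  }

  if (cmd == "simulate") {
    days <- as.numeric(cli_opt(args, "--days", "10"))
    tr <- simulate_clock(params, schedule,
      t_span = c(0, 24 * days),
      dt = sv$dt, rtol = sv$rtol, atol = sv$atol, method = sv$method
    )
    write_outputs(tr, cfg, out_dir, "trajectory")
  } else if (cmd %in% c("entrain", "perturb")) {
    ent <- entrain_cfg(params)
    message(sprintf(
      "entrained in %d days, cycle residual %.3g",
      ent$days_run, ent$achieved_residual
    ))
    write_outputs(ent, cfg, out_dir, "entrained")
    write_rhythm_summary(
      rhythm_summary(ent), file.path(out_dir, "rhythm_summary.json")
    )
    write_expression_profile(
      expression_profiles(ent),
      file.path(out_dir, "expression_profile.csv")
    )
  } else if (cmd == "agonist") {
    inj <- NULL
    for (p in cfg$perturbations) {
      if (identical(p$kind, "agonist_injection")) inj <- p
    }
    if (is.null(inj)) {
      inj <- list(injection_time_ZT = 0, magnitude = 2,
        dose_mode = "multiple_of_REV_peak"
      )
    }
    ent <- entrain_cfg(params)
    dose <- if (identical(inj$dose_mode, "absolute")) {
      inj$magnitude
    } else {
      NULL
    }
    exp <- agonist_experiment(
      params, schedule,
      injection_ZT = inj$injection_time_ZT %||% 0,
      dose_multiplier = inj$magnitude %||% 2, dose = dose,
      post_days = inj$post_days %||% 8, entrained = ent, dt = sv$dt
    )
    write_outputs(exp$treated, cfg, out_dir, "treated",
      extra = list(dose_nM = exp$dose, injection_ZT = exp$injection_ZT)
    )
    write_outputs(exp$control, cfg, out_dir, "control")
    ps <- phase_shift(exp$treated, exp$control)
    write_rhythm_summary(ps, file.path(out_dir, "phase_shift.json"))
  } else if (cmd == "summarize") {
    tp <- cli_opt(args, "--trajectory")
    if (is.null(tp)) stop("summarize needs --trajectory", call. = FALSE)
    raw <- read_trajectory_csv(tp)
    tr <- new_trajectory(
      raw$time, raw$state, params, schedule, cfg$solver
    )
    write_rhythm_summary(
      rhythm_summary(tr), file.path(out_dir, "rhythm_summary.json")
    )
  } else {
    stop("unknown subcommand '", cmd, "'", call. = FALSE)
  }
  invisible(NULL)
}
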