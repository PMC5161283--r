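experiment_kinds <- c("switch-prob", "switch-grid", "invasion", "evolve",
                      "therapy", "sweep")

#' Load and validate an experiment configuration
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON configuration describing one
#' experiment, validates it and fills in defaults (`gmax = 60`,
#' `environment wA = 2.0, wB = 1.01`, therapy defaults as in
#' [treatment_simulation()]). The `switch` block may be a bare kind name or a
#' map with `kind`, `gmax`, `bias`; the `environment` block takes either
#' `{wA, wB}` or `{dA, fA, dB, fB}` (mixing forms is rejected by
#' [env_spec()]).
#'
#' @param path path to a config file.
#' @return object of class `experiment_config`: validated list with the
#'   resolved `switch_model`, `env`, and experiment parameters.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_config(raw, source = path)
}

validate_config <- function(raw, source = "<list>") {
  if (is.null(raw$experiment))
    stop("config field 'experiment' is required (", source, ")")
  if (!raw$experiment %in% experiment_kinds)
    stop("config field 'experiment' must be one of: ",
         paste(experiment_kinds, collapse = ", "))

  sw <- raw$switch
  if (is.null(sw)) sw <- list(kind = "DC")
  if (is.character(sw)) sw <- list(kind = sw)
  if (is.null(sw$kind)) stop("config field 'switch.kind' is required")
  sw$gmax <- if (is.null(sw$gmax)) 60L else as.integer(sw$gmax)
  if (length(sw$bias) == 0) sw$bias <- NULL
  kinds <- as.character(sw$kind)

  envb <- raw$environment
  env <- if (is.null(envb)) env_spec()
  else if (!is.null(envb$dA) || !is.null(envb$fA) ||
           !is.null(envb$dB) || !is.null(envb$fB)) {
    if (!is.null(envb$wA) || !is.null(envb$wB))
      stop("config field 'environment' mixes (wA, wB) with (d, f) values")
    env_spec(dA = envb$dA, fA = envb$fA, dB = envb$dB, fB = envb$fB)
  } else
    env_spec(wA = if (is.null(envb$wA)) 2.0 else envb$wA,
             wB = if (is.null(envb$wB)) 1.01 else envb$wB)

  regime <- raw$regime
  regime <- if (is.null(regime)) drug_regime("cytotoxic")
  else if (is.character(regime)) drug_regime(regime)
  else drug_regime("custom", dA = regime$dA, fA = regime$fA,
                   dB = regime$dB, fB = regime$fB)

  default <- function(field, value)
    if (is.null(raw[[field]])) value else raw[[field]]
  cfg <- list(
    experiment = raw$experiment,
    switch_kinds = kinds,
    gmax = sw$gmax,
    bias = sw$bias,            # NULL means the calibrated default
    env = env,
    regime = regime,
    x0 = if (is.null(raw$x0)) NULL else as.integer(raw$x0),
    seed = as.integer(default("seed", 1L)),
    replicates = as.integer(default("replicates", 200L)),
    event_cap = as.numeric(default("event_cap", 1e6)),
    holiday = as.numeric(default("holiday", c(0, 3000, 5000, 50000, 1e5))),
    N0 = as.numeric(default("N0", 1e10)),
    horizon = as.numeric(default("horizon", 20000)),
    success_threshold = as.numeric(default("success_threshold", 240)))
  class(cfg) <- "experiment_config"
  cfg
}

#' Save an experiment configuration
#'
#' Writes a config in a form [load_config()] reads back to an equivalent
#' object (round-trip identity over the resolved fields).
#'
#' @param config an `experiment_config`.
#' @param path output path (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  raw <- list(
    experiment = config$experiment,
    switch = Filter(Negate(is.null),
                    list(kind = config$switch_kinds, gmax = config$gmax,
                         bias = config$bias)),
    environment = if (!is.null(config$env$dA))
      config$env[c("dA", "fA", "dB", "fB")]
    else config$env[c("wA", "wB")],
    regime = if (config$regime$name == "custom")
      unclass(config$regime)[c("dA", "fA", "dB", "fB")]
    else config$regime$name,
    x0 = config$x0, seed = config$seed, replicates = config$replicates,
    event_cap = config$event_cap, holiday = config$holiday, N0 = config$N0,
    horizon = config$horizon, success_threshold = config$success_threshold)
  raw <- Filter(Negate(is.null), raw)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(raw, path)
  else
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(path)
}

config_switch <- function(config, kind = config$switch_kinds[1]) {
  if (is.null(config$bias))
    make_switch(kind, gmax = config$gmax)
  else
    make_switch(kind, gmax = config$gmax, bias = config$bias)
}

#' Run a configured experiment
#'
#' Dispatches on `config$experiment`, writes tabular outputs (CSV) and a
#' summary (JSON) under `out_dir`, plus a `manifest.json` recording the
#' config echo, package version, per-output checksums, seed and wall time so
#' that any output is reproducible from its manifest.
#'
#' @param config an `experiment_config` (or path to one).
#' @param out_dir output directory (created if needed).
#' @return named list of the objects written, invisibly.
#' @export
run_experiment <- function(config, out_dir) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()["elapsed"]
  outputs <- list()
  write_csv <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    outputs[[name]] <<- df
  }

  if (config$experiment == "switch-prob") {
    for (kind in config$switch_kinds)
      write_csv(switch_prob_table(config_switch(config, kind)),
                sprintf("switch_prob_%s.csv", kind))
  } else if (config$experiment == "switch-grid") {
    for (kind in config$switch_kinds)
      write_csv(switch_prob_grid(config_switch(config, kind)),
                sprintf("switch_grid_%s.csv", kind))
  } else if (config$experiment == "invasion") {
    write_csv(invasion_grid(env = config$env), "invasion_grid.csv")
  } else if (config$experiment == "evolve") {
    for (kind in config$switch_kinds) {
      sw <- config_switch(config, kind)
      x0 <- if (is.null(config$x0)) closest_to_half(sw) else config$x0
      runs <- lapply(seq_len(config$replicates), function(k) {
        tr <- sswm_trajectory(sw, x0, env = config$env,
                              seed = derive_seed(config$seed, k),
                              event_cap = config$event_cap)
        list(loss = data.frame(replicate = k, seed = derive_seed(config$seed, k),
                               loss_time = tr$loss_time,
                               censored = tr$censored),
             rec = cbind(replicate = k, tr$records))
      })
      write_csv(do.call(rbind, lapply(runs, `[[`, "loss")),
                sprintf("loss_times_%s.csv", kind))
      write_csv(do.call(rbind, lapply(runs, `[[`, "rec")),
                sprintf("trajectories_%s.csv", kind))
      expected <- expected_loss_time(sw, x0, config$env)
      jsonlite::write_json(
        list(switch = kind, x0 = x0, expected_loss_time = expected),
        file.path(out_dir, sprintf("expected_loss_%s.json", kind)),
        auto_unbox = TRUE, digits = NA)
    }
  } else if (config$experiment %in% c("therapy", "sweep")) {
    regimes <- if (config$experiment == "sweep")
      c("cytotoxic", "cytostatic", "mixed") else config$regime$name
    for (kind in config$switch_kinds) {
      sw <- config_switch(config, kind)
      x0 <- if (is.null(config$x0)) closest_to_half(sw) else config$x0
      for (rg in regimes) {
        reg <- if (inherits(config$regime, "drug_regime") &&
                   rg == config$regime$name) config$regime
               else drug_regime(rg)
        res <- holiday_sweep(sw, x0, T_list = config$holiday, regime = reg,
                             env = config$env, N0 = config$N0,
                             horizon = config$horizon,
                             replicates = config$replicates,
                             success_threshold = config$success_threshold,
                             seed = derive_seed(config$seed,
                                                match(rg, regimes) * 1000L))
        write_csv(res, sprintf("holiday_%s_%s.csv", kind, rg))
      }
    }
  }

  manifest <- list(
    config = jsonlite::fromJSON(jsonlite::toJSON(
      save_config_list(config), auto_unbox = TRUE, digits = NA)),
    package_version = as.character(utils::packageVersion("hedgesim")),
    seed = config$seed,
    outputs = as.list(tools::md5sum(
      list.files(out_dir, pattern = "\\.(csv|json)$", full.names = TRUE))),
    wall_time_seconds = unname(proc.time()["elapsed"] - t0))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outputs)
}

# config as a plain list (the echo stored in manifests)
save_config_list <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  jsonlite::fromJSON(tmp, simplifyVector = TRUE)
}

#' Canonical ready-to-run experiment configs
#'
#' Writes a suite of configuration files encoding the package's reference
#' experiments: expected-loss-time runs for each switch, the full
#' switching-probability tables, the invasion-probability grid, and
#' treatment-holiday sweeps (cytotoxic, cytostatic and mixed regimes) at
#' desk-scale replicate counts.
#'
#' @param dir directory to write the configs into.
#' @param seed master seed recorded in every config.
#' @return character vector of the paths written.
#' @export
fixture_suite <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  add <- function(name, raw) {
    p <- file.path(dir, paste0(name, ".yaml"))
    yaml::write_yaml(raw, p)
    paths <<- c(paths, p)
  }
  for (kind in c("DC", "DCx", "DCy"))
    add(paste0(tolower(kind), "_loss"),
        list(experiment = "evolve", switch = kind, seed = seed,
             replicates = 200))
  add("am_loss", list(experiment = "evolve", switch = "AM", x0 = 30,
                      seed = seed, replicates = 3, event_cap = 1e5))
  add("switch_tables", list(experiment = "switch-prob",
                            switch = list(kind = c("DC", "DCx", "DCy", "AM",
                                                   "DCdup")),
                            seed = seed))
  add("fig_invasion_grid", list(experiment = "invasion", seed = seed))
  add("holiday_sweep",
      list(experiment = "sweep",
           switch = list(kind = c("DC", "DCx", "DCy", "AM")),
           seed = seed, replicates = 200))
  paths
}
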