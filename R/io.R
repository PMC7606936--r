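# Configuration files, result serialisation and fixture generation.

CONFIG_KEYS <- c("scenario", "tau_multiplier", "node_scales", "n_cells",
                 "duration", "dt", "seed", "n_replicates", "heterogeneity_cv",
                 "parameters")

#' Load a run configuration from YAML
#'
#' Reads a YAML configuration, fills defaults (normal scenario, 500 cells,
#' 20 days, calibrated default parameters) and validates it. Top-level keys:
#' `scenario`, `tau_multiplier`, `node_scales` (named map), `n_cells`,
#' `duration`, `dt`, `seed`, `n_replicates`, `heterogeneity_cv`, and
#' `parameters` (a map of flattened parameter names, see [param_table()], to
#' override values). Unknown keys are rejected with the offending key path.
#'
#' @param path Path to a YAML file. An empty file yields the full defaults.
#' @param base Base `network_parameters` the overrides are applied to.
#' @return A list with elements `config` ([scenario_config()]) and
#'   `parameters` (`network_parameters`).
#' @export
load_config <- function(path, base = default_parameters()) {
  if (!file.exists(path)) stop("configuration error: file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop("configuration error: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  params <- base
  for (nm in names(raw$parameters)) {
    params <- tryCatch(set_param(params, nm, raw$parameters[[nm]]),
                       error = function(e) {
                         stop("configuration error at parameters.", nm, ": ",
                              conditionMessage(e), call. = FALSE)
                       })
  }
  validate_parameters(params)
  args <- raw[setdiff(names(raw), "parameters")]
  names(args)[names(args) == "scenario"] <- "scenario"
  if (!is.null(args$node_scales)) args$node_scales <- unlist(args$node_scales)
  cfg <- do.call(scenario_config, args)
  list(config = cfg, parameters = params)
}

#' Write or read a parameter set as YAML
#'
#' `write_parameters()` serialises a `network_parameters` object to YAML;
#' `load_parameters()` reads one back. The package ships its calibrated
#' defaults at `system.file("extdata", "default_parameters.yaml",
#' package = "agevuln")`.
#'
#' @param params A `network_parameters` object.
#' @param path File path.
#' @return `load_parameters()` returns a `network_parameters` object;
#'   `write_parameters()` returns `path` invisibly.
#' @export
write_parameters <- function(params, path) {
  # named numeric vectors (weight maps) must become named lists to keep their
  # names through YAML
  prep <- function(x) {
    if (is.list(x)) return(lapply(x, prep))
    if (is.numeric(x) && length(x) > 1 && !is.null(names(x))) return(as.list(x))
    x
  }
  yaml::write_yaml(prep(unclass(params)), path, precision = 9)
  invisible(path)
}

#' @rdname write_parameters
#' @export
load_parameters <- function(path) {
  raw <- yaml::read_yaml(path)
  # named weight maps come back as lists; restore numeric vectors
  fix <- function(x) {
    if (is.list(x) && length(x) > 0 && all(vapply(x, is.numeric, logical(1))) &&
        all(vapply(x, length, integer(1)) == 1) && !is.null(names(x)) &&
        all(names(x) %in% c(NODE_NAMES))) {
      return(unlist(x))
    }
    if (is.list(x)) return(lapply(x, fix))
    x
  }
  p <- structure(lapply(raw, fix), class = "network_parameters")
  validate_parameters(p)
  p
}

#' Write a results directory
#'
#' Serialises a `population_trajectory` into a directory of plain-text files:
#' `population_means.csv`, `phenotypes.csv`, `survival.csv`, `deaths.csv`,
#' a YAML echo of the configuration, and a JSON run manifest (command label,
#' seed, package version, timestamps, file list). Floating point values are
#' written with 9 significant digits for regression stability.
#'
#' @param traj A `population_trajectory`.
#' @param dir Output directory (created if needed).
#' @param command Label recorded in the manifest.
#' @return The manifest, invisibly.
#' @export
write_results <- function(traj, dir, command = "run") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  fmt <- function(df) {
    df[] <- lapply(df, function(x) if (is.double(x)) signif(x, 9) else x)
    df
  }
  files <- c(population_means = "population_means.csv",
             phenotypes = "phenotypes.csv", survival = "survival.csv",
             deaths = "deaths.csv", config = "config.yaml",
             manifest = "manifest.json")
  utils::write.csv(fmt(traj$means), file.path(dir, files["population_means"]),
                   row.names = FALSE)
  utils::write.csv(fmt(phenotype_fractions(traj)), file.path(dir, files["phenotypes"]),
                   row.names = FALSE)
  utils::write.csv(fmt(survival_curve(traj)), file.path(dir, files["survival"]),
                   row.names = FALSE)
  utils::write.csv(fmt(traj$deaths), file.path(dir, files["deaths"]),
                   row.names = FALSE)
  cfg <- traj$config
  yaml::write_yaml(list(scenario = cfg$scenario_name,
                        tau_multiplier = cfg$tau_multiplier,
                        node_scales = as.list(cfg$node_scales),
                        n_cells = cfg$n_cells, duration = cfg$duration,
                        dt = cfg$dt, seed = cfg$seed,
                        n_replicates = cfg$n_replicates,
                        heterogeneity_cv = cfg$heterogeneity_cv),
                   file.path(dir, files["config"]))
  manifest <- list(command = command, config = files[["config"]],
                   seed = traj$seed,
                   package_version = as.character(utils::packageVersion("agevuln")),
                   started = started,
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   outputs = unname(files))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(dir, files["manifest"]),
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  }
  invisible(manifest)
}

#' Deterministic miniature population snapshot
#'
#' Generates a small frozen population (a short default-parameter run) for
#' regression tests: per-cell molecular state, pool counts and phenotype.
#' Identical seeds give identical snapshots.
#'
#' @param n_cells Number of cells, at most 100.
#' @param seed Integer seed.
#' @param duration Days simulated before the snapshot (default 2).
#' @return Tibble, one row per cell (the trajectory's final state).
#' @export
make_fixture_population <- function(n_cells = 20, seed = 1L, duration = 2) {
  stopifnot(n_cells <= 100)
  cfg <- scenario_config(n_cells = n_cells, duration = duration, seed = seed,
                         dt = 0.02, n_replicates = 1)
  run_simulation(cfg, record_every = 0.5)$final_state
}
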