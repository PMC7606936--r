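#' @importFrom stats rnorm rbinom runif setNames var
#' @importFrom utils modifyList
NULL

# Canonical node ordering used everywhere (state columns, signatures, exports).
NODE_NAMES <- c(
  "uprmt_hsp60", "uprer_bip", "uprer_pperk", "skn1", "daf16",
  "sod2", "bec1", "mtor", "pink1"
)

# Field-standard marker labels for the same nodes, used in reports and figures.
NODE_LABELS <- c(
  uprmt_hsp60 = "hsp-60", uprer_bip = "BiP", uprer_pperk = "p-PERK",
  skn1 = "skn-1", daf16 = "daf-16", sod2 = "sod-2", bec1 = "bec-1",
  mtor = "mTOR", pink1 = "pink-1"
)

PHENOTYPE_LEVELS <- c(
  "RESILIENT", "MT_COMPROMISED", "ER_COMPROMISED",
  "DUAL_COMPROMISED", "VULNERABLE", "DEAD"
)

#' Node names of the molecular signature
#'
#' @param labels If `TRUE`, return the marker labels (hsp-60, BiP, ...) instead
#'   of the machine-readable node names.
#' @return Character vector of the nine signature nodes.
#' @export
signature_nodes <- function(labels = FALSE) {
  if (labels) unname(NODE_LABELS) else NODE_NAMES
}

#' Default network parameterisation
#'
#' Returns the calibrated default parameter set for the aging stress-response
#' network: production and clearance rates for reactive oxygen species (ROS)
#' and tau load, Hill input terms, self-feedback terms and age-dependent
#' capacity decline for the nine response nodes, mitochondrion pool rates, and
#' the phenotype/death constants. All rates are per simulated day; activities
#' are normalised response fractions in `[0, 1]`.
#'
#' The mitochondrial and ER unfolded protein response nodes (`uprmt_hsp60`,
#' `uprer_bip`) carry positive self-feedback with Hill coefficient >= 2 plus
#' chronic repression of their capacity by ROS (and tau for the ER branch), so
#' the steady-state activity versus clamped ROS folds into two stable branches
#' (bistability with hysteresis).
#'
#' @return A `network_parameters` object (nested named list).
#' @seealso [apply_scenario()], [param_table()], [set_param()]
#' @export
default_parameters <- function() {
  p <- list(
    ros = list(
      basal_production = 0.008,   # rate/day at first day of adulthood
      age_production   = 0.038,   # rate/day^2, spontaneous age-dependent rise
      mito_coupling    = 0.35,    # rate/day per unit damaged mitochondrial fraction
      tau_coupling     = 0.02,    # rate/day per unit tau load
      clearance_basal  = 1.10,    # conc/day, saturable basal elimination capacity
      clearance_K      = 0.25,    # half-saturation of basal elimination
      clearance_weights = c(sod2 = 0.15, skn1 = 0.09, daf16 = 0.09)
    ),
    tau = list(
      production_basal    = 0.220,  # load/day
      scenario_multiplier = 1.0,    # 2.0 in the tau-exacerbated scenario
      ros_amplification   = 0.45,   # fold boost of aggregation at saturating ROS
      ros_K = 0.35, ros_n = 2,
      clearance_basal   = 0.33,     # /day
      clearance_weights = c(bec1 = 0.04, uprer_bip = 0.04)
    ),
    nodes = list(
      uprmt_hsp60 = list(
        basal_drive = 0.35,
        input_weight = 0.15, input_K = 0.30, input_n = 2,  # damaged mito fraction
        self_feedback_weight = 0.65, self_feedback_K = 0.60, self_feedback_n = 6,
        ros_repression_K = 0.75, ros_repression_n = 6,
        tau_repression_K = 1.35, tau_repression_n = 6,
        capacity_decline_rate = 0.005, relaxation_time = 0.5, expression_scale = 1.0
      ),
      uprer_bip = list(
        basal_drive = 0.35,
        input_weight = 0.13, input_K = 0.50, input_n = 2,  # tau load (acute ER stress)
        self_feedback_weight = 0.65, self_feedback_K = 0.60, self_feedback_n = 6,
        ros_repression_K = 0.66, ros_repression_n = 6,
        tau_repression_K = 0.87, tau_repression_n = 20,
        capacity_decline_rate = 0.005, relaxation_time = 0.5, expression_scale = 1.0
      ),
      uprer_pperk = list(
        basal_drive = 0.40,
        input_weight = 0.30, input_K = 0.50, input_n = 2,  # tau load, shared ER input
        ros_repression_K = 0.66, ros_repression_n = 6,
        tau_repression_K = 0.87, tau_repression_n = 20,
        capacity_decline_rate = 0.010, relaxation_time = 2.0, expression_scale = 1.0
      ),
      skn1 = list(
        basal_drive = 0.25,
        input_weight = 0.75, input_K = 0.30, input_n = 2,  # ROS
        capacity_decline_rate = 0.010, relaxation_time = 0.5, expression_scale = 1.0
      ),
      daf16 = list(
        basal_drive = 0.25,
        input_weight = 0.75, input_K = 0.35, input_n = 2,  # ROS
        capacity_decline_rate = 0.010, relaxation_time = 0.5, expression_scale = 1.0
      ),
      sod2 = list(
        basal_drive = 0.30,
        skn1_weight = 0.60, daf16_weight = 0.60,
        capacity_decline_rate = 0.010, relaxation_time = 0.5, expression_scale = 1.0
      ),
      bec1 = list(
        basal_drive = 0.30,
        skn1_weight = 0.50, daf16_weight = 0.50,
        mtor_repression_K = 0.60, mtor_repression_n = 2,
        capacity_decline_rate = 0.020, relaxation_time = 0.5, expression_scale = 1.0
      ),
      mtor = list(
        basal_drive = 0.70,
        capacity_decline_rate = 0.030, relaxation_time = 0.5, expression_scale = 1.0
      ),
      pink1 = list(
        basal_drive = 0.25,
        skn1_weight = 0.60, daf16_weight = 0.60,
        capacity_decline_rate = 0.020, relaxation_time = 0.5, expression_scale = 1.0
      )
    ),
    mito = list(
      damage_rate = 0.24, damage_K = 0.45, damage_n = 2,
      uprmt_protection = 0.45,      # damage hazard reduction by UPR^mt activity
      uprer_damage_coupling = 1.20, # damage hazard boost when UPR^ER is lost
      mitophagy_rate = 1.50,
      biogenesis_decline_rate = 0.05,
      capacity = 100
    ),
    phenotype = list(
      activity_cutoff = 0.50,  # UPR activity below this flags a compromised branch
      ros_threshold = 0.38,    # oxidative insult gate for the vulnerable state
      tau_threshold = 0.60,    # proteotoxic insult gate for the vulnerable state
      death_hazard = 1.00     # /day once vulnerable
    )
  )
  structure(p, class = "network_parameters")
}

# Flattened-name metadata -----------------------------------------------------

# Leaves that are structural: never sampled per agent, never scanned in the
# one-at-a-time sensitivity analysis.
STRUCTURAL_PATTERNS <- c(
  "expression_scale$", "scenario_multiplier$", "^mito\\.capacity$"
)
# Scanned but not sampled per agent: Hill exponents and classification
# constants (structural), and the proteotoxic stressor program, which is an
# imposed population-wide insult (a scenario protocol), not per-cell machinery.
UNSAMPLED_PATTERNS <- c(
  "(_n|\\.ros_n|\\.input_n|repression_n|feedback_n)$",
  "^phenotype\\.(activity_cutoff|ros_threshold|tau_threshold)$",
  "^tau\\.(production_basal|ros_amplification|ros_K|clearance_basal)$"
)

flatten_params <- function(p, prefix = NULL) {
  out <- list()
  for (nm in names(p)) {
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    v <- p[[nm]]
    if (is.list(v)) {
      out <- c(out, flatten_params(v, key))
    } else if (length(v) > 1) {
      out <- c(out, as.list(setNames(as.numeric(v), paste(key, names(v), sep = "."))))
    } else {
      out[[key]] <- as.numeric(v)
    }
  }
  out
}

matches_any <- function(x, patterns) {
  Reduce(`|`, lapply(patterns, grepl, x = x), rep(FALSE, length(x)))
}

#' Tabulate all scalar parameters
#'
#' Flattens a [network_parameters][default_parameters] object into a tibble of
#' dot-separated names and values, flagging which parameters receive per-agent
#' heterogeneity (`sampled`) and which enter the one-at-a-time sensitivity scan
#' (`scanned`). Structural constants (Hill exponents, expression scales, the
#' scenario multiplier, the pool capacity, classification thresholds) are
#' excluded from per-agent sampling.
#'
#' @param params A `network_parameters` object.
#' @return A tibble with columns `parameter`, `value`, `sampled`, `scanned`.
#' @export
param_table <- function(params) {
  fl <- flatten_params(unclass(params))
  nm <- names(fl)
  structural <- matches_any(nm, STRUCTURAL_PATTERNS)
  tibble::tibble(
    parameter = nm,
    value = unlist(fl, use.names = FALSE),
    sampled = !structural & !matches_any(nm, UNSAMPLED_PATTERNS),
    scanned = !structural
  )
}

#' Get or set one parameter by its flattened name
#'
#' @param params A `network_parameters` object.
#' @param name Dot-separated parameter name as listed by [param_table()],
#'   e.g. `"ros.age_production"` or `"nodes.skn1.input_K"`.
#' @param value Replacement value (for `set_param`).
#' @return `get_param` returns a numeric scalar; `set_param` returns a modified
#'   copy of `params` (the input is never mutated).
#' @export
get_param <- function(params, name) {
  fl <- flatten_params(unclass(params))
  if (!name %in% names(fl)) {
    stop("unknown parameter: ", name, call. = FALSE)
  }
  fl[[name]]
}

#' @rdname get_param
#' @export
set_param <- function(params, name, value) {
  path <- strsplit(name, ".", fixed = TRUE)[[1]]
  p <- unclass(params)
  node <- p
  for (i in seq_along(path)) {
    part <- path[[i]]
    if (is.list(node)) {
      if (!part %in% names(node)) stop("unknown parameter: ", name, call. = FALSE)
      node <- node[[part]]
    } else {
      # named numeric vector leaf (e.g. clearance weights)
      if (i != length(path) || !part %in% names(node)) {
        stop("unknown parameter: ", name, call. = FALSE)
      }
    }
  }
  assign_path <- function(x, path, value) {
    if (length(path) == 1) {
      if (is.list(x)) x[[path]] <- value else x[path] <- value
      return(x)
    }
    x[[path[[1]]]] <- assign_path(x[[path[[1]]]], path[-1], value)
    x
  }
  structure(assign_path(p, path, value), class = "network_parameters")
}

#' Validate a parameter set
#'
#' Checks the structural invariants of the network parameterisation: strictly
#' positive rates, Hill constants and relaxation times; Hill coefficients
#' `n >= 1`; non-negative expression scales; and self-feedback Hill coefficient
#' `n >= 2` for the two bistable unfolded-protein-response nodes.
#'
#' @param params A `network_parameters` object.
#' @return `params`, invisibly, if valid; otherwise an error.
#' @export
validate_parameters <- function(params) {
  tab <- param_table(params)
  if (any(!is.finite(tab$value))) {
    stop("invalid parameter(s), non-finite: ",
         paste(tab$parameter[!is.finite(tab$value)], collapse = ", "), call. = FALSE)
  }
  # productions, couplings, weights, declines, hazards and thresholds may be
  # zero (switched off); K values, clearance floors, relaxation times, rates of
  # the saturable machinery and the pool capacity must be strictly positive.
  zero_ok <- grepl(
    "(weight|weights|coupling|amplification|production|decline|hazard|threshold|multiplier|scale)",
    tab$parameter)
  strict <- !zero_ok
  if (any(strict & tab$value <= 0)) {
    stop("invalid parameter(s), must be strictly positive: ",
         paste(tab$parameter[strict & tab$value <= 0], collapse = ", "), call. = FALSE)
  }
  if (any(zero_ok & tab$value < 0)) {
    stop("invalid parameter(s), must be non-negative: ",
         paste(tab$parameter[zero_ok & tab$value < 0], collapse = ", "), call. = FALSE)
  }
  ns <- tab[grepl("(_n)$", tab$parameter), ]
  if (any(ns$value < 1)) {
    stop("invalid parameter(s): Hill coefficients must be >= 1: ",
         paste(ns$parameter[ns$value < 1], collapse = ", "), call. = FALSE)
  }
  for (node in c("uprmt_hsp60", "uprer_bip")) {
    if (params$nodes[[node]]$self_feedback_n < 2) {
      stop("invalid parameter: nodes.", node, ".self_feedback_n must be >= 2 ",
           "(bistability requirement)", call. = FALSE)
    }
  }
  scales <- vapply(params$nodes, function(x) x$expression_scale, numeric(1))
  if (any(scales < 0)) {
    stop("invalid parameter: expression_scale must be >= 0", call. = FALSE)
  }
  invisible(params)
}

# Scenario configuration -------------------------------------------------------

#' Scenario and run configuration
#'
#' Bundles the perturbation (tau multiplier, per-node expression scales) with
#' the run settings (population size, duration, step size, seed, replicates,
#' per-agent heterogeneity).
#'
#' @param scenario Name of a preset scenario (see [scenario_presets()]), or
#'   `"custom"`.
#' @param tau_multiplier Multiplier on the tau aggregation rate (1 = normal
#'   aging; 2 = the tau-exacerbated scenario's 100% increase). Defaults to the
#'   preset's value.
#' @param node_scales Named numeric vector of expression scales applied
#'   multiplicatively per node (e.g. `c(skn1 = 0.10)` for partial ablation).
#' @param n_cells Number of cell agents (>= 1).
#' @param duration Simulated days (default 20, the upper end of wild-type
#'   nematode lifespan; day 0 is the first day of adulthood).
#' @param dt Integration step in days, `0 < dt <= 0.1`.
#' @param seed Integer seed; every stochastic element of a run derives from it.
#' @param n_replicates Replicate count used by [run_replicates()].
#' @param heterogeneity_cv Coefficient of variation of per-agent parameter
#'   lognormal-like scatter (truncated Gaussian factors), default 0.10.
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(scenario = "normal",
                            tau_multiplier = NULL,
                            node_scales = NULL,
                            n_cells = 500,
                            duration = 20,
                            dt = 0.01,
                            seed = 1L,
                            n_replicates = 10,
                            heterogeneity_cv = 0.10) {
  presets <- scenario_presets()
  if (!scenario %in% c(names(presets), "custom")) {
    stop("configuration error: unknown scenario '", scenario, "'; available: ",
         paste(c(names(presets), "custom"), collapse = ", "), call. = FALSE)
  }
  preset <- if (scenario %in% names(presets)) presets[[scenario]] else
    list(tau_multiplier = 1, node_scales = numeric(0))
  cfg <- structure(list(
    scenario_name = scenario,
    tau_multiplier = if (is.null(tau_multiplier)) preset$tau_multiplier else tau_multiplier,
    node_scales = if (is.null(node_scales)) preset$node_scales else node_scales,
    n_cells = as.integer(n_cells),
    duration = duration,
    dt = dt,
    seed = as.integer(seed),
    n_replicates = as.integer(n_replicates),
    heterogeneity_cv = heterogeneity_cv
  ), class = "scenario_config")
  validate_config(cfg)
}

validate_config <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$n_cells < 1) stop("configuration error: n_cells must be >= 1", call. = FALSE)
  if (config$duration < 0) stop("configuration error: duration must be >= 0", call. = FALSE)
  if (!(config$dt > 0 && config$dt <= 0.1)) {
    stop("configuration error: dt must satisfy 0 < dt <= 0.1 day", call. = FALSE)
  }
  if (config$n_replicates < 1) stop("configuration error: n_replicates must be >= 1", call. = FALSE)
  if (config$heterogeneity_cv < 0) {
    stop("configuration error: heterogeneity_cv must be >= 0", call. = FALSE)
  }
  unknown <- setdiff(names(config$node_scales), NODE_NAMES)
  if (length(unknown) > 0) {
    stop("configuration error: unknown node(s) in node_scales: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(config$node_scales < 0)) {
    stop("configuration error: node_scales must be >= 0", call. = FALSE)
  }
  invisible(config)
}

#' Preset perturbation scenarios
#'
#' `"normal"` is unperturbed aging. `"tau"` doubles the tau aggregation rate
#' (a 100% increase). `"skn1-ablation"` and `"skn1-oe"` scale skn-1 expression
#' to 10% and 150%. The four deficiency scenarios used for survival comparisons
#' reduce the named response to 10% expression.
#'
#' @return Named list of `list(tau_multiplier, node_scales)` presets.
#' @export
scenario_presets <- function() {
  list(
    "normal"        = list(tau_multiplier = 1, node_scales = numeric(0)),
    "tau"           = list(tau_multiplier = 2, node_scales = numeric(0)),
    "skn1-ablation" = list(tau_multiplier = 1, node_scales = c(skn1 = 0.10)),
    "skn1-oe"       = list(tau_multiplier = 1, node_scales = c(skn1 = 1.50)),
    "skn1-def"      = list(tau_multiplier = 1, node_scales = c(skn1 = 0.10)),
    "daf16-def"     = list(tau_multiplier = 1, node_scales = c(daf16 = 0.10)),
    "uprmt-def"     = list(tau_multiplier = 1, node_scales = c(uprmt_hsp60 = 0.10)),
    "uprer-def"     = list(tau_multiplier = 1,
                           node_scales = c(uprer_bip = 0.10, uprer_pperk = 0.10))
  )
}

#' Apply a scenario to a parameter set
#'
#' Returns a copy of `base` with the scenario's tau multiplier set and each
#' named node's `expression_scale` multiplied by the corresponding scale. The
#' input is never modified.
#'
#' @param base A `network_parameters` object.
#' @param scenario A `scenario_config` object.
#' @return A modified `network_parameters` copy.
#' @export
apply_scenario <- function(base, scenario) {
  validate_config(scenario)
  p <- base
  p$tau$scenario_multiplier <- scenario$tau_multiplier
  for (node in names(scenario$node_scales)) {
    if (!node %in% NODE_NAMES) {
      stop("configuration error: unknown node '", node, "' in node_scales", call. = FALSE)
    }
    p$nodes[[node]]$expression_scale <-
      p$nodes[[node]]$expression_scale * scenario$node_scales[[node]]
  }
  p
}

# Per-agent heterogeneity ------------------------------------------------------

trunc_gauss_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  z <- pmin(3, pmax(-3, rnorm(n)))
  pmax(1 + cv * z, 1e-6)
}

#' Sample a heterogeneous agent parameterisation
#'
#' Multiplies every positive kinetic rate, Hill constant, weight, decline rate
#' and relaxation time by an independent Gaussian factor (mean 1, sd `cv`,
#' truncated to `[1 - 3 cv, 1 + 3 cv]`, floored at a small positive value).
#' Structural fields (Hill coefficients, expression scales, topology,
#' classification thresholds) are unchanged. This emulates natural biological
#' stochasticity across the cell population.
#'
#' @param base A `network_parameters` object.
#' @param cv Coefficient of variation, `cv >= 0`. A warning is issued for
#'   `cv >= 1/3` where truncation distorts the distribution.
#' @return A `network_parameters` copy with perturbed values.
#' @export
sample_agent_params <- function(base, cv) {
  if (cv < 0) stop("invalid parameter: cv must be >= 0", call. = FALSE)
  if (cv >= 1 / 3) {
    warning("cv >= 1/3: truncation to [1-3cv, 1+3cv] distorts the sampling distribution")
  }
  if (cv == 0) return(base)
  tab <- param_table(base)
  p <- base
  for (nm in tab$parameter[tab$sampled]) {
    p <- set_param(p, nm, get_param(p, nm) * trunc_gauss_factors(1, cv))
  }
  p
}

# Vectorised population sampling used by the engine: returns the same nested
# structure with each sampled leaf expanded to a length-n vector.
sample_population_params <- function(base, n, cv) {
  tab <- param_table(base)
  expand <- function(x, path) {
    key <- paste(path, collapse = ".")
    if (is.list(x)) {
      for (nm in names(x)) x[[nm]] <- expand(x[[nm]], c(path, nm))
      return(x)
    }
    if (length(x) > 1) {
      out <- lapply(names(x), function(nm) {
        full <- paste(c(path, nm), collapse = ".")
        if (full %in% tab$parameter && tab$sampled[tab$parameter == full] && cv > 0) {
          x[[nm]] * trunc_gauss_factors(n, cv)
        } else rep(as.numeric(x[[nm]]), n)
      })
      names(out) <- names(x)
      return(out)
    }
    if (key %in% tab$parameter && tab$sampled[tab$parameter == key] && cv > 0) {
      as.numeric(x) * trunc_gauss_factors(n, cv)
    } else x
  }
  structure(expand(unclass(base), character(0)), class = "network_parameters")
}

# Topology export ---------------------------------------------------------------

#' Network topology as an edge list
#'
#' The regulatory couplings of the aging response network, one row per edge,
#' with the Hill constant and coefficient where the coupling is saturable
#' (linear couplings report `NA`).
#'
#' @param params A `network_parameters` object (values fill the K/n columns).
#' @return A tibble with columns `source`, `target`, `sign`, `K`, `n`.
#' @export
network_edges <- function(params = default_parameters()) {
  nd <- params$nodes
  tibble::tribble(
    ~source, ~target, ~sign, ~K, ~n,
    "age", "ros", "+", NA, NA,
    "mito_damaged_fraction", "ros", "+", NA, NA,
    "tau", "ros", "+", NA, NA,
    "sod2", "ros", "-", NA, NA,
    "skn1", "ros", "-", NA, NA,
    "daf16", "ros", "-", NA, NA,
    "ros", "tau", "+", params$tau$ros_K, params$tau$ros_n,
    "bec1", "tau", "-", NA, NA,
    "uprer_bip", "tau", "-", NA, NA,
    "ros", "skn1", "+", nd$skn1$input_K, nd$skn1$input_n,
    "ros", "daf16", "+", nd$daf16$input_K, nd$daf16$input_n,
    "skn1", "sod2", "+", NA, NA,
    "daf16", "sod2", "+", NA, NA,
    "skn1", "bec1", "+", NA, NA,
    "daf16", "bec1", "+", NA, NA,
    "mtor", "bec1", "-", nd$bec1$mtor_repression_K, nd$bec1$mtor_repression_n,
    "skn1", "pink1", "+", NA, NA,
    "daf16", "pink1", "+", NA, NA,
    "mito_damaged_fraction", "uprmt_hsp60", "+", nd$uprmt_hsp60$input_K, nd$uprmt_hsp60$input_n,
    "uprmt_hsp60", "uprmt_hsp60", "+", nd$uprmt_hsp60$self_feedback_K, nd$uprmt_hsp60$self_feedback_n,
    "ros", "uprmt_hsp60", "-", nd$uprmt_hsp60$ros_repression_K, nd$uprmt_hsp60$ros_repression_n,
    "tau", "uprmt_hsp60", "-", nd$uprmt_hsp60$tau_repression_K, nd$uprmt_hsp60$tau_repression_n,
    "tau", "uprer_bip", "+", nd$uprer_bip$input_K, nd$uprer_bip$input_n,
    "uprer_bip", "uprer_bip", "+", nd$uprer_bip$self_feedback_K, nd$uprer_bip$self_feedback_n,
    "ros", "uprer_bip", "-", nd$uprer_bip$ros_repression_K, nd$uprer_bip$ros_repression_n,
    "tau", "uprer_bip", "-", nd$uprer_bip$tau_repression_K, nd$uprer_bip$tau_repression_n,
    "tau", "uprer_pperk", "+", nd$uprer_pperk$input_K, nd$uprer_pperk$input_n,
    "ros", "uprer_pperk", "-", nd$uprer_pperk$ros_repression_K, nd$uprer_pperk$ros_repression_n,
    "tau", "uprer_pperk", "-", nd$uprer_pperk$tau_repression_K, nd$uprer_pperk$tau_repression_n,
    "ros", "mito_damage", "+", params$mito$damage_K, params$mito$damage_n,
    "pink1", "mitophagy", "+", NA, NA,
    "bec1", "mitophagy", "+", NA, NA
  )
}

#' @export
print.network_parameters <- function(x, ...) {
  tab <- param_table(x)
  cat("<network_parameters> ", nrow(tab), " scalar parameters, ",
      length(x$nodes), " response nodes\n", sep = "")
  cat("  tau scenario multiplier: ", x$tau$scenario_multiplier, "\n", sep = "")
  scales <- vapply(x$nodes, function(n) n$expression_scale, numeric(1))
  off <- scales[abs(scales - 1) > 1e-12]
  if (length(off) > 0) {
    cat("  expression scales: ",
        paste(names(off), signif(off, 3), sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> ", x$scenario_name,
      ": ", x$n_cells, " cells, ", x$duration, " days, dt=", x$dt,
      ", seed=", x$seed, ", replicates=", x$n_replicates,
      ", cv=", x$heterogeneity_cv, "\n", sep = "")
  invisible(x)
}
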