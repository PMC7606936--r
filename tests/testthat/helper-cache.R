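# Shared fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# parameter set with every stressor production switched off: the network sits
# at its basal fixed point forever
no_stress_params <- function() {
  p <- default_parameters()
  for (nm in c("ros.basal_production", "ros.age_production", "ros.mito_coupling",
               "ros.tau_coupling", "tau.production_basal", "mito.damage_rate")) {
    p <- set_param(p, nm, if (nm == "mito.damage_rate") 1e-9 else 0)
  }
  p
}

# a short default-parameter run with dense per-cell records
small_tracked_run <- function() {
  cached("small_tracked_run", {
    cfg <- scenario_config("normal", n_cells = 80, duration = 20, dt = 0.02,
                           seed = 42)
    run_simulation(cfg, cell_record_every = 0.2)
  })
}

# medium tau-scenario run used by phenotype/survival checks
small_tau_run <- function() {
  cached("small_tau_run", {
    cfg <- scenario_config("tau", n_cells = 80, duration = 20, dt = 0.02,
                           seed = 43)
    run_simulation(cfg)
  })
}

default_sweep_grid <- function() seq(0.10, 0.90, by = 0.04)

hysteresis_default <- function() {
  cached("hysteresis_default",
         hysteresis_gap(default_parameters(), default_sweep_grid()))
}

hysteresis_no_feedback <- function() {
  cached("hysteresis_no_feedback", {
    p0 <- default_parameters()
    p0 <- set_param(p0, "nodes.uprmt_hsp60.self_feedback_weight", 0)
    p0 <- set_param(p0, "nodes.uprer_bip.self_feedback_weight", 0)
    hysteresis_gap(p0, default_sweep_grid())
  })
}
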