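# Population co-simulation: fixed-step RK4 for the continuous molecular network
# with operator splitting (per step: ODE substep, then stochastic mitochondrial
# and death substep, then phenotype re-classification). State is held as
# matrices/vectors across cells so the whole population advances at once; a
# single seeded generator makes runs bitwise reproducible.

# shared low-level binomial transition for mitochondrion pools; the damage
# hazard is reduced by UPR^mt activity (mitochondrial proteostasis) and raised
# by loss of UPR^ER activity (ER dysregulation drives mitochondrial deficits)
mito_transition <- function(H, D, ros, pink1, bec1, bio, dt, m,
                            uprmt = 1, uprer = 1) {
  n <- length(H)
  modulation <- (1 - m$uprmt_protection * uprmt) *
    (1 + m$uprer_damage_coupling * (1 - uprer))
  p_dam <- 1 - exp(-m$damage_rate * modulation *
                     hill(ros, m$damage_K, m$damage_n) * dt)
  p_rem <- 1 - exp(-m$mitophagy_rate * pink1 * bec1 * dt)
  damaged <- rbinom(n, H, rep_len(p_dam, n))
  removed <- rbinom(n, D, rep_len(p_rem, n))
  refilled <- rbinom(n, removed, rep_len(pmin(1, pmax(0, bio)), n))
  list(H = H - damaged + refilled, D = D + damaged - removed)
}

classify_codes <- function(code, mt, er, insult) {
  new <- rep.int(1L, length(code))
  new[mt & !er] <- 2L
  new[!mt & er] <- 3L
  new[mt & er] <- 4L
  new[mt & er & insult] <- 5L
  sticky <- code >= 5L
  new[sticky] <- code[sticky]
  new
}

#' Run one population simulation
#'
#' Initialises `n_cells` agents (heterogeneous parameters, basal molecular
#' state on the upper response branch, full healthy mitochondrion pools, all
#' `RESILIENT`), then advances the coupled system over the configured duration:
#' per step, an RK4 substep of the molecular network, a stochastic
#' mitochondrial damage/mitophagy/biogenesis substep, phenotype
#' re-classification, and rate-dependent death of vulnerable cells. Fully
#' reproducible from `config$seed`.
#'
#' @param config A [scenario_config()].
#' @param params Base `network_parameters` (the scenario in `config` is applied
#'   on top of it).
#' @param record_every Days between population summary records (default 0.1).
#' @param cell_record_every Days between thinned per-cell records, or `Inf`
#'   (default) to record cells only at the final time.
#' @return A `population_trajectory` object: a list with tibbles
#'   `means` (population averages over living cells), `phenotypes`
#'   (time x state counts), `deaths` (`cell`, `time`), `final_state`
#'   (one row per cell), optionally `cells` (thinned per-cell series), plus
#'   `config` and `seed`.
#' @examples
#' cfg <- scenario_config(n_cells = 20, duration = 2, seed = 1)
#' traj <- run_simulation(cfg)
#' glance(traj)
#' @export
run_simulation <- function(config, params = default_parameters(),
                           record_every = 0.1, cell_record_every = Inf) {
  validate_config(config)
  validate_parameters(params)
  eff <- apply_scenario(params, config)
  n <- config$n_cells
  dt <- config$dt
  set.seed(config$seed)

  pop <- sample_population_params(eff, n, config$heterogeneity_cv)

  # initial state: activities and ROS settled at age 0 with tau = 0, healthy pools
  A <- matrix(0.9, nrow = n, ncol = 9, dimnames = list(NULL, NODE_NAMES))
  ros <- rep(0, n)
  tau <- rep(0, n)
  for (i in seq_len(300)) {
    s <- rk4_step(ros, tau, A, 0, rep(0, n), pop, 0.05, freeze_time = TRUE)
    ros <- s$ros; A <- s$A
  }
  capacity <- as.integer(rep_len(eff$mito$capacity, n))
  H <- capacity
  D <- integer(n)
  # at simulation startup every cell agent carries the fully resilient
  # phenotype; classification begins with the first step
  code <- rep.int(1L, n)
  alive <- rep(TRUE, n)

  n_steps <- max(0L, as.integer(round(config$duration / dt)))
  rec_stride <- max(1L, as.integer(round(record_every / dt)))
  cell_stride <- if (is.finite(cell_record_every)) {
    max(1L, as.integer(round(cell_record_every / dt)))
  } else NA_integer_
  rec_steps <- unique(c(0L, seq_len(n_steps)[seq_len(n_steps) %% rec_stride == 0L], n_steps))
  n_rec <- length(rec_steps)

  mean_cols <- c("ros", "tau", NODE_NAMES, "damaged_fraction")
  means <- matrix(NA_real_, n_rec, length(mean_cols) + 2,
                  dimnames = list(NULL, c("time", mean_cols, "n_alive")))
  phen_counts <- matrix(0L, n_rec, 6, dimnames = list(NULL, PHENOTYPE_LEVELS))
  deaths_cell <- integer(0)
  deaths_time <- numeric(0)
  cells_rec <- list()

  fd <- function() ifelse(H + D > 0L, D / pmax(1L, H + D), 1)

  record_cells <- function(t) {
    tibble::tibble(
      cell = seq_len(n), time = t, phenotype = PHENOTYPE_LEVELS[code],
      alive = alive, ros = ros, tau = tau,
      tibble::as_tibble(as.data.frame(A)),
      n_healthy = H, n_damaged = D, damaged_fraction = fd()
    )
  }

  ri <- 1L
  record <- function(step) {
    t <- step * dt
    live <- alive
    f <- fd()
    if (any(live)) {
      means[ri, ] <<- c(t, colMeans(cbind(ros, tau, A, f)[live, , drop = FALSE]),
                        sum(live))
    } else {
      means[ri, ] <<- c(t, rep(NA_real_, length(mean_cols)), 0)
    }
    phen_counts[ri, ] <<- tabulate(code, 6L)
    ri <<- ri + 1L
  }
  record(0L)
  if (!is.na(cell_stride)) cells_rec[["0"]] <- record_cells(0)

  thresholds <- eff$phenotype
  hazards <- if (length(pop$phenotype$death_hazard) == n) pop$phenotype$death_hazard
             else rep_len(pop$phenotype$death_hazard, n)

  for (step in seq_len(n_steps)) {
    t0 <- (step - 1L) * dt
    f0 <- fd()
    s <- rk4_step(ros, tau, A, t0, f0, pop, dt)
    ros <- s$ros; tau <- s$tau; A <- s$A
    bio <- exp(-pop$mito$biogenesis_decline_rate * t0)
    mt <- mito_transition(H, D, ros, A[, "pink1"], A[, "bec1"], bio, dt, pop$mito,
                          uprmt = A[, "uprmt_hsp60"], uprer = A[, "uprer_bip"])
    H <- mt$H; D <- mt$D
    insult <- ros > thresholds$ros_threshold & tau > thresholds$tau_threshold
    code <- classify_codes(code, A[, "uprmt_hsp60"] < thresholds$activity_cutoff,
                           A[, "uprer_bip"] < thresholds$activity_cutoff, insult)
    at_risk <- alive & code == 5L
    if (any(at_risk)) {
      dies <- at_risk
      dies[at_risk] <- runif(sum(at_risk)) < 1 - exp(-hazards[at_risk] * dt)
      if (any(dies)) {
        code[dies] <- 6L
        alive[dies] <- FALSE
        deaths_cell <- c(deaths_cell, which(dies))
        deaths_time <- c(deaths_time, rep(step * dt, sum(dies)))
      }
    }
    if (step %in% rec_steps && step != 0L) record(step)
    if (!is.na(cell_stride) && step %% cell_stride == 0L) {
      cells_rec[[as.character(step)]] <- record_cells(step * dt)
    }
  }

  structure(list(
    means = tibble::as_tibble(as.data.frame(means)),
    phenotypes = dplyr::bind_cols(
      tibble::tibble(time = rec_steps * dt),
      tibble::as_tibble(as.data.frame(phen_counts))
    ),
    deaths = tibble::tibble(cell = deaths_cell, time = deaths_time),
    final_state = record_cells(n_steps * dt),
    cells = if (length(cells_rec) > 0) dplyr::bind_rows(cells_rec) else NULL,
    config = config,
    seed = config$seed
  ), class = "population_trajectory")
}

#' Run replicate simulations and aggregate
#'
#' Runs one simulation per seed and aggregates population means, phenotype
#' fractions and survival by time point (mean, standard deviation, replicate
#' count), together with one end-of-run summary row per replicate.
#'
#' @param config A [scenario_config()]; `config$n_replicates` sets the default
#'   number of seeds.
#' @param params Base `network_parameters`.
#' @param seeds Integer seeds, one per replicate; defaults to
#'   `config$seed + 0:(n_replicates - 1)`. Duplicates trigger a warning.
#' @return A `replicate_summary` object with tibbles `means`, `phenotypes`,
#'   `survival` (aggregated over replicates) and `replicates` (per-replicate
#'   [glance()] rows).
#' @export
run_replicates <- function(config, params = default_parameters(), seeds = NULL) {
  validate_config(config)
  if (is.null(seeds)) seeds <- config$seed + seq_len(config$n_replicates) - 1L
  if (length(seeds) == 0) stop("seeds must be nonempty", call. = FALSE)
  if (anyDuplicated(seeds)) warning("duplicate seeds supplied; replicates will repeat")

  runs <- purrr::map(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    run_simulation(cfg, params)
  })

  means_long <- purrr::imap_dfr(runs, function(r, i) {
    dplyr::mutate(tidyr::pivot_longer(r$means, -"time",
                                      names_to = "variable", values_to = "value"),
                  replicate = i)
  })
  means_agg <- dplyr::summarise(
    dplyr::group_by(means_long, .data$time, .data$variable),
    mean = mean(.data$value), sd = stats::sd(.data$value),
    n_replicates = dplyr::n(), .groups = "drop"
  )

  phen_long <- purrr::imap_dfr(runs, function(r, i) {
    dplyr::mutate(phenotype_fractions(r), replicate = i)
  })
  phen_agg <- dplyr::summarise(
    dplyr::group_by(phen_long, .data$time, .data$state),
    mean = mean(.data$fraction), sd = stats::sd(.data$fraction),
    n_replicates = dplyr::n(), .groups = "drop"
  )

  surv_long <- purrr::imap_dfr(runs, function(r, i) {
    dplyr::mutate(survival_curve(r), replicate = i)
  })
  surv_agg <- dplyr::summarise(
    dplyr::group_by(surv_long, .data$time),
    mean = mean(.data$surviving_pct), sd = stats::sd(.data$surviving_pct),
    n_replicates = dplyr::n(), .groups = "drop"
  )

  structure(list(
    means = means_agg,
    phenotypes = phen_agg,
    survival = surv_agg,
    replicates = purrr::imap_dfr(runs, function(r, i) {
      dplyr::mutate(glance(r), replicate = i, .before = 1)
    }),
    config = config,
    seeds = as.integer(seeds)
  ), class = "replicate_summary")
}

#' @export
print.population_trajectory <- function(x, ...) {
  g <- glance(x)
  cat("<population_trajectory> scenario '", x$config$scenario_name, "': ",
      g$n_cells, " cells over ", g$duration, " days (seed ", x$seed, ")\n",
      "  survival ", round(g$survival_end, 1), "%, UPR^mt<0.5: ",
      round(g$pct_uprmt_low, 1), "%, UPR^ER<0.5: ", round(g$pct_uprer_low, 1),
      "%, first vulnerable day: ",
      ifelse(is.na(g$first_vulnerable_day), "none", g$first_vulnerable_day),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat("<replicate_summary> scenario '", x$config$scenario_name, "': ",
      length(x$seeds), " replicates of ", x$config$n_cells, " cells\n", sep = "")
  s_end <- dplyr::filter(x$survival, .data$time == max(.data$time))
  cat("  end-of-run survival ", round(s_end$mean, 1), "% (sd ",
      round(s_end$sd, 2), ")\n", sep = "")
  invisible(x)
}
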