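# Steady-state dose-response and hysteresis analysis of the response
# activities under clamped ROS. The activity subsystem is integrated with ROS
# held fixed and the slow variables (age, tau load, mitochondrial damaged
# fraction) frozen at reference values, until the largest activity rate falls
# below tolerance.

#' Reference conditions for clamped-ROS analysis
#'
#' The slow variables frozen during steady-state analysis: age (capacity
#' decline), tau load, and mitochondrial damaged fraction. The defaults (age 0,
#' no tau, 5% damage) probe the intrinsic dose-response of the response
#' network against oxidative load alone.
#'
#' @param age,tau,damaged_fraction Frozen values.
#' @return Named list.
#' @export
clamp_reference <- function(age = 0, tau = 0, damaged_fraction = 0.05) {
  list(age = age, tau = tau, damaged_fraction = damaged_fraction)
}

#' Steady state of the response activities under clamped ROS
#'
#' Integrates the nine-activity subsystem with ROS held at `ros_clamp` (age,
#' tau and damaged fraction frozen at `reference`) until
#' `max |dA/dt| < tol` or the step limit is reached. On non-convergence the
#' partial result is returned with `converged = FALSE`; no error is thrown.
#'
#' @param params A `network_parameters` object.
#' @param ros_clamp Clamped ROS level, `>= 0`.
#' @param init Optional initial activities: named numeric vector over
#'   [signature_nodes()] (defaults to the unstressed basal state).
#' @param reference See [clamp_reference()].
#' @param tol Convergence tolerance on the maximum activity rate (default
#'   1e-8 per day).
#' @param dt Integration step (default 0.005 day).
#' @param max_steps Step limit (default 1e6).
#' @return A one-row tibble with `ros_clamp`, the nine steady activities and
#'   `converged`.
#' @export
clamped_ros_steady_state <- function(params, ros_clamp, init = NULL,
                                     reference = clamp_reference(),
                                     tol = 1e-8, dt = 0.005, max_steps = 1e6) {
  if (ros_clamp < 0) stop("invalid input: ros_clamp must be >= 0", call. = FALSE)
  A <- if (is.null(init)) {
    as.matrix(basal_state(params, t = reference$age, tau = reference$tau,
                          damaged_fraction = reference$damaged_fraction)[, NODE_NAMES])
  } else {
    stopifnot(all(NODE_NAMES %in% names(init)))
    matrix(as.numeric(init[NODE_NAMES]), nrow = 1,
           dimnames = list(NULL, NODE_NAMES))
  }
  converged <- FALSE
  check_every <- 50L
  for (step in seq_len(max_steps)) {
    r <- network_rhs(ros_clamp, reference$tau, A, reference$age,
                     reference$damaged_fraction, params)
    A <- clamp01(A + dt * r$A)  # relaxation subsystem: forward Euler is exact enough
    if (step %% check_every == 0L && max(abs(r$A)) < tol) {
      converged <- TRUE
      break
    }
  }
  dplyr::bind_cols(
    tibble::tibble(ros_clamp = ros_clamp),
    tibble::as_tibble(as.data.frame(A)),
    tibble::tibble(converged = converged)
  )
}

#' Dose-response continuation sweep over clamped ROS
#'
#' Continuation sweep of steady-state activities along an ordered grid of ROS
#' clamps: each grid point's steady state seeds the next, so the sweep follows
#' one stable branch until it disappears. `direction = "up"` starts from the
#' unstressed basal state at the lowest clamp; `direction = "down"` traverses
#' the reversed grid starting from the high-ROS steady state. Comparing the
#' two branches exposes the bistable window and hysteresis of the
#' unfolded-protein-response activities.
#'
#' @param params A `network_parameters` object.
#' @param ros_grid Strictly monotone increasing vector of clamp levels.
#' @param direction `"up"` or `"down"`.
#' @inheritParams clamped_ros_steady_state
#' @return A `branch_table`: tibble with columns `ros_clamp`, `direction`,
#'   `node`, `activity`, `converged`, ordered by sweep position.
#' @export
dose_response_sweep <- function(params, ros_grid, direction = c("up", "down"),
                                reference = clamp_reference(),
                                tol = 1e-8, dt = 0.005, max_steps = 1e6) {
  direction <- match.arg(direction)
  if (length(ros_grid) == 0) stop("invalid input: ros_grid is empty", call. = FALSE)
  if (length(ros_grid) > 1 && any(diff(ros_grid) <= 0)) {
    stop("invalid input: ros_grid must be strictly increasing", call. = FALSE)
  }
  grid <- if (direction == "up") ros_grid else rev(ros_grid)
  init <- NULL
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    ss <- clamped_ros_steady_state(params, grid[i], init = init,
                                   reference = reference, tol = tol, dt = dt,
                                   max_steps = max_steps)
    rows[[i]] <- ss
    init <- unlist(ss[, NODE_NAMES])
  }
  wide <- dplyr::bind_rows(rows)
  long <- tidyr::pivot_longer(wide, dplyr::all_of(NODE_NAMES),
                              names_to = "node", values_to = "activity")
  out <- dplyr::mutate(long, direction = direction,
                       .after = "ros_clamp")[, c("ros_clamp", "direction",
                                                 "node", "activity", "converged")]
  structure(out, class = c("branch_table", class(out)))
}

#' Hysteresis gap between sweep branches
#'
#' Runs the up and down sweeps and reports, per node, the largest absolute
#' activity difference between the two branches across the grid.
#'
#' @inheritParams dose_response_sweep
#' @param nodes Nodes to report (default the two bistable UPR branches).
#' @return Tibble with columns `node`, `gap`, `ros_at_gap`.
#' @export
hysteresis_gap <- function(params, ros_grid,
                           nodes = c("uprmt_hsp60", "uprer_bip"),
                           reference = clamp_reference(), tol = 1e-8,
                           dt = 0.005, max_steps = 1e6) {
  up <- dose_response_sweep(params, ros_grid, "up", reference, tol, dt, max_steps)
  down <- dose_response_sweep(params, ros_grid, "down", reference, tol, dt, max_steps)
  both <- dplyr::inner_join(
    dplyr::rename(tibble::as_tibble(up)[, c("ros_clamp", "node", "activity")], up = "activity"),
    dplyr::rename(tibble::as_tibble(down)[, c("ros_clamp", "node", "activity")], down = "activity"),
    by = c("ros_clamp", "node")
  )
  both <- dplyr::filter(both, .data$node %in% nodes)
  both$diff <- abs(both$up - both$down)
  dplyr::summarise(dplyr::group_by(both, .data$node),
                   gap = max(.data$diff),
                   ros_at_gap = .data$ros_clamp[which.max(.data$diff)],
                   .groups = "drop")
}

#' Late-life ROS removal experiment
#'
#' Reproduces the dashed-line scenario of the dose-response analysis: age a
#' representative cell deterministically to `removal_day`, multiply its ROS by
#' `removal_fraction`, and relax the response activities to steady state at the
#' reduced clamp. With the calibrated defaults the unfolded-protein responses
#' do not recover their upper branch: the cell settles on the collapsed branch,
#' the irreversible bifurcation into the vulnerable regime.
#'
#' The removal fraction is a configurable default (0.5), not a
#' literature-derived constant.
#'
#' @param params A `network_parameters` object.
#' @param removal_day Day at which ROS is reduced (default 18).
#' @param removal_fraction Multiplier applied to ROS (default 0.5).
#' @param dt Integration step for the aging phase.
#' @return A list with `before` (one-row tibble of the aged state), `after`
#'   (steady state at the reduced clamp) and `recovered` (logical per UPR node:
#'   did activity return above the 0.5 cutoff?).
#' @export
ros_removal_experiment <- function(params, removal_day = 18,
                                   removal_fraction = 0.5, dt = 0.01) {
  # deterministic single-cell aging with expected mitochondrial damage dynamics
  A <- matrix(0.9, nrow = 1, ncol = 9, dimnames = list(NULL, NODE_NAMES))
  ros <- 0; tau <- 0; f <- 0
  for (i in seq_len(300)) {
    s <- rk4_step(ros, tau, A, 0, 0, params, 0.05)
    ros <- s$ros; A <- s$A
  }
  m <- params$mito
  n_steps <- as.integer(round(removal_day / dt))
  for (step in seq_len(n_steps)) {
    t0 <- (step - 1) * dt
    s <- rk4_step(ros, tau, A, t0, f, params, dt)
    ros <- s$ros; tau <- s$tau; A <- s$A
    # expected-value damage dynamics in place of the stochastic pool
    h_dam <- m$damage_rate * hill(ros, m$damage_K, m$damage_n)
    h_rem <- m$mitophagy_rate * A[, "pink1"] * A[, "bec1"]
    f <- pmin(1, pmax(0, f + dt * (h_dam * (1 - f) - h_rem * f)))
  }
  before <- dplyr::bind_cols(
    tibble::tibble(time = removal_day, ros = ros, tau = tau),
    tibble::as_tibble(as.data.frame(A)), tibble::tibble(damaged_fraction = f)
  )
  after <- clamped_ros_steady_state(
    params, ros * removal_fraction,
    init = unlist(before[, NODE_NAMES]),
    reference = clamp_reference(age = removal_day, tau = tau, damaged_fraction = f)
  )
  cutoff <- params$phenotype$activity_cutoff
  list(
    before = before,
    after = after,
    recovered = c(uprmt_hsp60 = after$uprmt_hsp60 >= cutoff,
                  uprer_bip = after$uprer_bip >= cutoff)
  )
}
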