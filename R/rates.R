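# Right-hand side of the molecular network.
#
# Vectorised over cells: `ros`, `tau` and each activity column are length-n
# vectors; parameter leaves are scalars or length-n vectors (per-agent
# heterogeneity). Every activity obeys the relaxation form
#   dA/dt = (clamp01(drive * capacity * expression_scale) - A) / relaxation_time
# so activities cannot leave [0, 1]. Age-dependent capacity declines
# exponentially, and chronic oxidative/proteotoxic load represses the capacity
# of the unfolded-protein-response branches (the substrate of the bistable
# collapse seen in the dose-response analysis).

clamp01 <- function(x) {
  # preserves matrix shape (pmin/pmax with a leading scalar would drop dims)
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# `A` is an n x 9 matrix with columns NODE_NAMES; returns list(ros, tau, A).
network_rhs <- function(ros, tau, A, t, damaged_fraction, params) {
  nd <- params$nodes
  rw <- params$ros$clearance_weights
  tw <- params$tau$clearance_weights

  a_uprmt <- A[, 1L]; a_bip <- A[, 2L]; a_pperk <- A[, 3L]
  a_skn1 <- A[, 4L]; a_daf16 <- A[, 5L]; a_sod2 <- A[, 6L]
  a_bec1 <- A[, 7L]; a_mtor <- A[, 8L]; a_pink1 <- A[, 9L]

  # basal elimination is saturable (enzymatic detoxification); the
  # activity-weighted antioxidant channel is linear in ROS
  d_ros <- params$ros$basal_production + params$ros$age_production * t +
    params$ros$mito_coupling * damaged_fraction + params$ros$tau_coupling * tau -
    params$ros$clearance_basal * ros / (params$ros$clearance_K + ros) -
    ros * (rw[["sod2"]] * a_sod2 + rw[["skn1"]] * a_skn1 + rw[["daf16"]] * a_daf16)

  d_tau <- params$tau$production_basal * params$tau$scenario_multiplier *
    (1 + params$tau$ros_amplification * hill(ros, params$tau$ros_K, params$tau$ros_n)) -
    tau * (params$tau$clearance_basal + tw[["bec1"]] * a_bec1 + tw[["uprer_bip"]] * a_bip)

  cap <- function(node, chronic = FALSE) {
    n <- nd[[node]]
    k <- exp(-n$capacity_decline_rate * t) * n$expression_scale
    if (chronic) {
      k <- k * hill(ros, n$ros_repression_K, n$ros_repression_n, "repression") *
        hill(tau, n$tau_repression_K, n$tau_repression_n, "repression")
      # chronic overload of the mitochondrial response by accumulated damage
      if (!is.null(n$mito_repression_K)) {
        k <- k * hill(damaged_fraction, n$mito_repression_K,
                      n$mito_repression_n, "repression")
      }
    }
    k
  }

  drives <- cbind(
    uprmt_hsp60 = pmin(1, nd$uprmt_hsp60$basal_drive +
      nd$uprmt_hsp60$input_weight *
        hill(damaged_fraction, nd$uprmt_hsp60$input_K, nd$uprmt_hsp60$input_n) +
      nd$uprmt_hsp60$self_feedback_weight *
        hill(a_uprmt, nd$uprmt_hsp60$self_feedback_K, nd$uprmt_hsp60$self_feedback_n)),
    uprer_bip = pmin(1, nd$uprer_bip$basal_drive +
      nd$uprer_bip$input_weight * hill(tau, nd$uprer_bip$input_K, nd$uprer_bip$input_n) +
      nd$uprer_bip$self_feedback_weight *
        hill(a_bip, nd$uprer_bip$self_feedback_K, nd$uprer_bip$self_feedback_n)),
    uprer_pperk = pmin(1, nd$uprer_pperk$basal_drive +
      nd$uprer_pperk$input_weight *
        hill(tau, nd$uprer_pperk$input_K, nd$uprer_pperk$input_n)),
    skn1 = nd$skn1$basal_drive + (1 - nd$skn1$basal_drive) *
      hill(ros, nd$skn1$input_K, nd$skn1$input_n),
    daf16 = nd$daf16$basal_drive + (1 - nd$daf16$basal_drive) *
      hill(ros, nd$daf16$input_K, nd$daf16$input_n),
    sod2 = nd$sod2$basal_drive + (1 - nd$sod2$basal_drive) *
      pmin(1, nd$sod2$skn1_weight * a_skn1 + nd$sod2$daf16_weight * a_daf16),
    bec1 = (nd$bec1$basal_drive + (1 - nd$bec1$basal_drive) *
      pmin(1, nd$bec1$skn1_weight * a_skn1 + nd$bec1$daf16_weight * a_daf16)) *
      hill(a_mtor, nd$bec1$mtor_repression_K, nd$bec1$mtor_repression_n, "repression"),
    mtor = nd$mtor$basal_drive + 0 * a_mtor,
    pink1 = nd$pink1$basal_drive + (1 - nd$pink1$basal_drive) *
      pmin(1, nd$pink1$skn1_weight * a_skn1 + nd$pink1$daf16_weight * a_daf16)
  )

  caps <- cbind(
    cap("uprmt_hsp60", chronic = TRUE),
    cap("uprer_bip", chronic = TRUE),
    cap("uprer_pperk", chronic = TRUE),
    cap("skn1"), cap("daf16"), cap("sod2"), cap("bec1"), cap("mtor"), cap("pink1")
  )

  relax <- cbind(
    nd$uprmt_hsp60$relaxation_time, nd$uprer_bip$relaxation_time,
    nd$uprer_pperk$relaxation_time, nd$skn1$relaxation_time,
    nd$daf16$relaxation_time, nd$sod2$relaxation_time,
    nd$bec1$relaxation_time, nd$mtor$relaxation_time, nd$pink1$relaxation_time
  )
  if (nrow(relax) == 1 && nrow(A) > 1) {
    relax <- relax[rep(1L, nrow(A)), , drop = FALSE]
  }

  dA <- (clamp01(drives * caps) - A) / relax
  colnames(dA) <- NODE_NAMES
  list(ros = d_ros, tau = d_tau, A = dA)
}

#' Instantaneous rates of the molecular network
#'
#' Evaluates the full deterministic right-hand side for one cell: d/dt of ROS,
#' tau load, and each of the nine node activities. Each activity derivative has
#' the relaxation form `(target - activity) / relaxation_time` with the target
#' clamped to `[0, 1]`, so activities cannot leave the unit interval.
#'
#' @param state A list or one-row data frame with elements `ros`, `tau`, `age`
#'   and the nine node activities (see [signature_nodes()]), e.g. as returned
#'   by [basal_state()].
#' @param params A `network_parameters` object.
#' @param damaged_fraction Damaged fraction of the cell's mitochondrion pool.
#' @return A tibble with columns `variable` and `rate` (11 rows).
#' @export
node_rates <- function(state, params, damaged_fraction = 0) {
  state <- as.list(state)
  stopifnot(all(c("ros", "tau", "age", NODE_NAMES) %in% names(state)))
  if (state$ros < 0 || state$tau < 0) {
    stop("invalid state: ros and tau must be non-negative", call. = FALSE)
  }
  A <- matrix(unlist(state[NODE_NAMES]), nrow = 1,
              dimnames = list(NULL, NODE_NAMES))
  r <- network_rhs(state$ros, state$tau, A, state$age, damaged_fraction, params)
  tibble::tibble(
    variable = c("ros", "tau", NODE_NAMES),
    rate = c(r$ros, r$tau, as.numeric(r$A))
  )
}

# One fixed RK4 step of the deterministic subsystem (operator-splitting ODE
# substep). `damaged_fraction` is held constant across the step. With
# `freeze_time = TRUE` all stage evaluations use age `t` (used when settling
# to a fixed point at frozen age).
rk4_step <- function(ros, tau, A, t, damaged_fraction, params, dt,
                     freeze_time = FALSE) {
  f <- function(ros, tau, A, t_stage) {
    network_rhs(ros, tau, A, if (freeze_time) t else t_stage, damaged_fraction,
                params)
  }
  k1 <- f(ros, tau, A, t)
  k2 <- f(ros + dt / 2 * k1$ros, tau + dt / 2 * k1$tau, A + dt / 2 * k1$A, t + dt / 2)
  k3 <- f(ros + dt / 2 * k2$ros, tau + dt / 2 * k2$tau, A + dt / 2 * k2$A, t + dt / 2)
  k4 <- f(ros + dt * k3$ros, tau + dt * k3$tau, A + dt * k3$A, t + dt)
  list(
    ros = pmax(0, ros + dt / 6 * (k1$ros + 2 * k2$ros + 2 * k3$ros + k4$ros)),
    tau = pmax(0, tau + dt / 6 * (k1$tau + 2 * k2$tau + 2 * k3$tau + k4$tau)),
    A = clamp01(A + dt / 6 * (k1$A + 2 * k2$A + 2 * k3$A + k4$A))
  )
}

#' Basal molecular state
#'
#' The basal state of a cell at age `t`: ROS at its fast production/clearance
#' balance and every activity settled on its (upper-branch) steady state, with
#' the slowly accumulating tau load held at `tau` (0 on the first day of
#' adulthood). Computed by relaxation from a high-activity start with age
#' frozen. When all stressor productions are zero this is a true fixed point
#' of the network.
#'
#' @param params A `network_parameters` object.
#' @param t Age (days) at which capacities are evaluated, default 0.
#' @param tau Tau load held fixed during settling, default 0.
#' @param damaged_fraction Mitochondrial damaged fraction held during the
#'   settling integration, default 0.
#' @param settle_days,dt Length and step of the relaxation integration.
#' @return A one-row tibble with `ros`, `tau`, `age` and the nine activities.
#' @export
basal_state <- function(params, t = 0, tau = 0, damaged_fraction = 0,
                        settle_days = 40, dt = 0.02) {
  A <- matrix(0.9, nrow = 1, ncol = 9, dimnames = list(NULL, NODE_NAMES))
  ros <- 0
  for (i in seq_len(ceiling(settle_days / dt))) {
    s <- rk4_step(ros, tau, A, t, damaged_fraction, params, dt, freeze_time = TRUE)
    ros <- s$ros; A <- s$A
  }
  out <- tibble::as_tibble(as.data.frame(A))
  dplyr::bind_cols(tibble::tibble(ros = ros, tau = tau, age = t), out)
}
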