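#' Create a mitochondrion pool
#'
#' Each cell agent carries a pool of two-state (healthy/damaged) mitochondrion
#' agents. Pools are represented as a tibble with one row per cell so a whole
#' population can be stepped at once.
#'
#' @param n_cells Number of cells (rows).
#' @param capacity Maximum pool size per cell (default 100 mitochondria).
#' @param n_healthy,n_damaged Initial counts (recycled across cells).
#' @return A `mito_pool` tibble with columns `n_healthy`, `n_damaged`,
#'   `capacity`.
#' @export
mito_pool <- function(n_cells = 1, capacity = 100, n_healthy = capacity,
                      n_damaged = 0) {
  pool <- tibble::tibble(
    n_healthy = as.integer(rep_len(n_healthy, n_cells)),
    n_damaged = as.integer(rep_len(n_damaged, n_cells)),
    capacity = as.integer(rep_len(capacity, n_cells))
  )
  if (any(pool$n_healthy < 0 | pool$n_damaged < 0 | pool$capacity <= 0)) {
    stop("invalid pool: counts must be non-negative and capacity positive", call. = FALSE)
  }
  if (any(pool$n_healthy + pool$n_damaged > pool$capacity)) {
    stop("invalid pool: n_healthy + n_damaged must not exceed capacity", call. = FALSE)
  }
  structure(pool, class = c("mito_pool", class(pool)))
}

#' Advance mitochondrion pools by one stochastic step
#'
#' Over a step of length `dt`, each healthy mitochondrion is damaged with
#' probability `1 - exp(-k_dam * hill(ros) * dt)` (oxidative damage hazard),
#' each damaged one is removed by mitophagy with probability
#' `1 - exp(-k_mito * pink1 * bec1 * dt)`, and each removed slot is refilled
#' with a healthy organelle with probability `biogenesis_capacity`. Counts are
#' drawn binomially (statistically identical to per-agent event queues for
#' exchangeable organelles). Draws consume the global R random number stream,
#' so a `set.seed()` call upstream makes trajectories bitwise reproducible.
#'
#' @param pool A `mito_pool` tibble (one row per cell).
#' @param ros Cellular ROS level(s), recycled across rows.
#' @param pink1,bec1 Mitophagy-driving activities in `[0, 1]`.
#' @param biogenesis_capacity Probability that a cleared slot is refilled;
#'   declines with age as `exp(-biogenesis_decline_rate * t)` in the engine.
#' @param dt Step length in days (`dt = 0` returns the pool unchanged).
#' @param params A `network_parameters` object (rates under `params$mito`).
#' @param uprmt,uprer UPR^mt and UPR^ER activities modulating the damage
#'   hazard: active mitochondrial proteostasis lowers it, loss of ER
#'   proteostasis raises it. Defaults 1 (fully protective).
#' @return The advanced `mito_pool`.
#' @export
step_mitochondria <- function(pool, ros, pink1, bec1, biogenesis_capacity, dt,
                              params = default_parameters(), uprmt = 1, uprer = 1) {
  stopifnot(dt >= 0)
  if (dt == 0) return(pool)
  if (any(pink1 < 0 | pink1 > 1) || any(bec1 < 0 | bec1 > 1)) {
    stop("invalid input: activities must lie in [0, 1]", call. = FALSE)
  }
  out <- mito_transition(pool$n_healthy, pool$n_damaged, ros, pink1, bec1,
                         pmin(1, pmax(0, biogenesis_capacity)), dt, params$mito,
                         uprmt = uprmt, uprer = uprer)
  pool$n_healthy <- out$H
  pool$n_damaged <- out$D
  pool
}

#' Damaged fraction of a pool
#'
#' `n_damaged / (n_healthy + n_damaged)`. An empty pool is defined as fully
#' failed (fraction 1) and reported with a message.
#'
#' @param pool A `mito_pool` tibble.
#' @return Numeric vector of fractions in `[0, 1]`, one per cell.
#' @export
damaged_fraction <- function(pool) {
  total <- pool$n_healthy + pool$n_damaged
  out <- ifelse(total > 0, pool$n_damaged / pmax(1L, total), 1)
  if (any(total == 0)) {
    message(sum(total == 0), " empty mitochondrion pool(s) treated as fully failed")
  }
  out
}
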