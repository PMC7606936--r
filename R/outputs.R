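#' Fold-change molecular signature
#'
#' Divides each node's population-mean activity by its value at the reference
#' time (default day 0, the first day of adulthood), giving the time-resolved
#' molecular signature as fold changes. Mid-life (day 6) and late-life
#' (day 11) fold changes are attached as the `milestones` attribute when those
#' days lie on the time grid.
#'
#' @param traj A `population_trajectory`.
#' @param t_ref Reference time on the recorded grid (default 0).
#' @return A `signature_table`: tibble with columns `node`, `label`, `time`,
#'   `fold_change`; attributes `t_ref` and `milestones`.
#' @export
fold_change_signature <- function(traj, t_ref = 0) {
  m <- traj$means
  i_ref <- which(abs(m$time - t_ref) < 1e-9)
  if (length(i_ref) != 1) {
    stop("t_ref = ", t_ref, " is not on the recorded time grid", call. = FALSE)
  }
  ref <- unlist(m[i_ref, NODE_NAMES])
  if (any(ref == 0)) {
    stop("zero reference value at t_ref for node(s): ",
         paste(NODE_NAMES[ref == 0], collapse = ", "), call. = FALSE)
  }
  long <- tidyr::pivot_longer(m[, c("time", NODE_NAMES)], -"time",
                              names_to = "node", values_to = "activity")
  long$fold_change <- long$activity / ref[long$node]
  out <- tibble::tibble(
    node = long$node,
    label = unname(NODE_LABELS[long$node]),
    time = long$time,
    fold_change = long$fold_change
  )
  milestones <- signature_milestones(out, days = c(mid = 6, late = 11))
  structure(out, t_ref = t_ref, milestones = milestones,
            class = c("signature_table", class(out)))
}

#' Mid- and late-life fold changes
#'
#' Extracts per-node fold changes at the sampling days used for comparison
#' against experimental fold-change tables (mid-life day 6, late-life day 11).
#' Days not on the recorded grid are dropped with a warning.
#'
#' @param signature A `signature_table` from [fold_change_signature()].
#' @param days Named vector of group label -> day.
#' @return Tibble with columns `node`, `label`, `group`, `fold_change`.
#' @export
signature_milestones <- function(signature, days = c(mid = 6, late = 11)) {
  purrr::imap_dfr(days, function(day, group) {
    rows <- signature[abs(signature$time - day) < 1e-9,
                      c("node", "label", "fold_change")]
    if (nrow(rows) == 0) return(NULL)
    dplyr::mutate(rows, group = group, .before = "fold_change")
  })
}

#' Phenotype fractions over time
#'
#' Fractions of the initial population in each phenotype state per recorded
#' time point. All six states (including `DEAD`) sum to 1 at every time.
#'
#' @param traj A `population_trajectory`.
#' @return Tibble with columns `time`, `state`, `fraction`.
#' @export
phenotype_fractions <- function(traj) {
  n0 <- traj$config$n_cells
  long <- tidyr::pivot_longer(traj$phenotypes, -"time",
                              names_to = "state", values_to = "count")
  long$state <- factor(long$state, levels = PHENOTYPE_LEVELS)
  dplyr::arrange(
    tibble::tibble(time = long$time, state = long$state,
                   fraction = long$count / n0),
    .data$time, .data$state
  )
}

#' Percent survival over time
#'
#' `100 * (1 - DEAD fraction)`: starts at 100 and is nonincreasing (death is
#' absorbing).
#'
#' @param traj A `population_trajectory`.
#' @return Tibble with columns `time`, `surviving_pct`.
#' @export
survival_curve <- function(traj) {
  n0 <- traj$config$n_cells
  tibble::tibble(
    time = traj$phenotypes$time,
    surviving_pct = 100 * (1 - traj$phenotypes$DEAD / n0)
  )
}

#' Extrapolate simulated nematode days to human years
#'
#' Direct linear mapping of the simulated nematode lifespan onto a human
#' lifespan: `day * human_years / lifespan_days`. Under the default 20-day ->
#' 100-year map, day 12 corresponds to 60 years and day 19 to 95 years.
#'
#' @param day Simulated day(s), `>= 0`.
#' @param lifespan_days Simulated lifespan (default 20 days).
#' @param human_years Human lifespan (default 100 years).
#' @return Years, same length as `day`.
#' @export
extrapolate_to_human_years <- function(day, lifespan_days = 20, human_years = 100) {
  if (lifespan_days <= 0) stop("lifespan_days must be > 0", call. = FALSE)
  if (any(day < 0)) stop("invalid input: day must be >= 0", call. = FALSE)
  day * human_years / lifespan_days
}

#' Coefficient of determination against experimental fold changes
#'
#' Compares simulated and experimental fold changes per group (mid-life,
#' late-life), matched by node. The default convention follows the ideal 1:1
#' correlation line: `R^2 = 1 - SS_res / SS_tot` with residuals taken from
#' `y = x` (method `"identity"`); method `"ols"` instead uses an ordinary
#' least-squares fit. With zero variance in the experimental values the
#' statistic is undefined and reported as `NA` with `degenerate = TRUE`.
#'
#' @param sim Tibble of simulated fold changes with columns `node`, `group`,
#'   `fold_change` (e.g. from [signature_milestones()]).
#' @param experimental Tibble with the same columns (user-supplied, typically
#'   read from CSV).
#' @param method `"identity"` (default) or `"ols"`.
#' @return Tibble with columns `group`, `method`, `n_pairs`, `r_squared`,
#'   `degenerate`.
#' @export
correlation_r2 <- function(sim, experimental, method = c("identity", "ols")) {
  method <- match.arg(method)
  need <- c("node", "group", "fold_change")
  stopifnot(all(need %in% names(sim)), all(need %in% names(experimental)))
  merged <- dplyr::inner_join(
    dplyr::rename(sim[, need], sim = "fold_change"),
    dplyr::rename(experimental[, need], exp = "fold_change"),
    by = c("node", "group")
  )
  purrr::map_dfr(split(merged, merged$group), function(g) {
    if (nrow(g) < 3) {
      stop("fewer than 3 matched node pairs in group '", g$group[1], "'", call. = FALSE)
    }
    ss_tot <- sum((g$exp - mean(g$exp))^2)
    if (ss_tot == 0) {
      return(tibble::tibble(group = g$group[1], method = method,
                            n_pairs = nrow(g), r_squared = NA_real_,
                            degenerate = TRUE))
    }
    ss_res <- if (method == "identity") {
      sum((g$exp - g$sim)^2)
    } else {
      sum(stats::resid(stats::lm(exp ~ sim, data = g))^2)
    }
    tibble::tibble(group = g$group[1], method = method, n_pairs = nrow(g),
                   r_squared = 1 - ss_res / ss_tot, degenerate = FALSE)
  })
}
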