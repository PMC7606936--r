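#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a population trajectory
#'
#' Long tibble of population-mean variables over time (living cells only).
#'
#' @param x A `population_trajectory`.
#' @param ... Unused.
#' @return Tibble with columns `time`, `variable`, `value`.
#' @export
tidy.population_trajectory <- function(x, ...) {
  tidyr::pivot_longer(x$means, -"time", names_to = "variable", values_to = "value")
}

#' One-row summary of a population trajectory
#'
#' End-of-run population statistics: percent survival, percent of surviving
#' cells with UPR^mt / UPR^ER activity below the 0.5 cutoff, cumulative death
#' percentage, and the first day with a nonzero vulnerable fraction (`NA` if
#' none).
#'
#' @param x A `population_trajectory`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.population_trajectory <- function(x, ...) {
  fs <- x$final_state
  live <- fs[fs$alive, ]
  cutoff <- 0.5
  vul <- x$phenotypes$time[x$phenotypes$VULNERABLE + x$phenotypes$DEAD > 0]
  tibble::tibble(
    scenario = x$config$scenario_name,
    n_cells = x$config$n_cells,
    duration = x$config$duration,
    seed = x$seed,
    survival_end = 100 * mean(fs$alive),
    dead_pct = 100 * mean(!fs$alive),
    pct_uprmt_low = 100 * mean(live$uprmt_hsp60 < cutoff),
    pct_uprer_low = 100 * mean(live$uprer_bip < cutoff),
    first_vulnerable_day = if (length(vul) > 0) min(vul) else NA_real_,
    n_deaths = nrow(x$deaths)
  )
}

#' Tidy a replicate summary
#'
#' @param x A `replicate_summary`.
#' @param ... Unused.
#' @return The aggregated means tibble (`time`, `variable`, `mean`, `sd`,
#'   `n_replicates`).
#' @export
tidy.replicate_summary <- function(x, ...) x$means

#' One-row summary across replicates
#'
#' Replicate means (and standard deviations) of the end-of-run statistics.
#'
#' @param x A `replicate_summary`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.replicate_summary <- function(x, ...) {
  r <- x$replicates
  tibble::tibble(
    scenario = x$config$scenario_name,
    n_replicates = nrow(r),
    n_cells = x$config$n_cells,
    survival_end = mean(r$survival_end), survival_end_sd = stats::sd(r$survival_end),
    dead_pct = mean(r$dead_pct), dead_pct_sd = stats::sd(r$dead_pct),
    pct_uprmt_low = mean(r$pct_uprmt_low),
    pct_uprer_low = mean(r$pct_uprer_low),
    first_vulnerable_day = mean(r$first_vulnerable_day)
  )
}

#' Tidy a sensitivity table
#'
#' @param x An `sc_table`.
#' @param ... Unused.
#' @return Tibble with `parameter`, `timepoint`, `sc`, `category`.
#' @export
tidy.sc_table <- function(x, ...) {
  tibble::as_tibble(x)[, c("parameter", "timepoint", "sc", "category")]
}

#' Category counts of a sensitivity table
#'
#' @param x An `sc_table`.
#' @param ... Unused.
#' @return One-row tibble with counts per significance category.
#' @export
glance.sc_table <- function(x, ...) {
  tibble::tibble(
    n_parameters = length(unique(x$parameter)),
    n_significant = sum(x$category == "significant"),
    n_considered = sum(x$category == "considered"),
    n_negligible = sum(x$category == "negligible")
  )
}
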