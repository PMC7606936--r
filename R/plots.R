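#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_area geom_col
#'   geom_point geom_hline labs facet_wrap scale_y_continuous theme_minimal
#' @importFrom rlang .data
NULL

#' @export
ggplot2::autoplot

#' Plot a population trajectory
#'
#' `type = "phenotypes"` shows the stacked phenotype fractions over time,
#' `type = "survival"` the percent-survival curve, and `type = "means"` the
#' population-mean node activities.
#'
#' @param object A `population_trajectory`.
#' @param type One of `"phenotypes"`, `"survival"`, `"means"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.population_trajectory <- function(object,
                                           type = c("phenotypes", "survival", "means"),
                                           ...) {
  type <- match.arg(type)
  if (type == "phenotypes") {
    pf <- phenotype_fractions(object)
    ggplot(pf, aes(.data$time, .data$fraction, fill = .data$state)) +
      geom_area() +
      labs(x = "age (days)", y = "fraction of initial population",
           fill = "phenotype",
           title = paste0("Phenotype fractions (", object$config$scenario_name, ")")) +
      theme_minimal()
  } else if (type == "survival") {
    sc <- survival_curve(object)
    ggplot(sc, aes(.data$time, .data$surviving_pct)) +
      geom_line() +
      scale_y_continuous(limits = c(0, 100)) +
      labs(x = "age (days)", y = "surviving cells (%)",
           title = paste0("Cell survival (", object$config$scenario_name, ")")) +
      theme_minimal()
  } else {
    long <- tidy(object)
    long <- long[long$variable %in% NODE_NAMES, ]
    long$label <- NODE_LABELS[long$variable]
    ggplot(long, aes(.data$time, .data$value, colour = .data$label)) +
      geom_line() +
      labs(x = "age (days)", y = "mean normalised activity", colour = "node",
           title = "Population-mean response activities") +
      theme_minimal()
  }
}

#' Plot a fold-change signature
#'
#' Node fold changes over time, normalised to the reference day.
#'
#' @param object A `signature_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.signature_table <- function(object, ...) {
  ggplot(object, aes(.data$time, .data$fold_change, colour = .data$label)) +
    geom_line() +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    labs(x = "age (days)", y = paste0("fold change vs day ", attr(object, "t_ref")),
         colour = "node", title = "Molecular response signature") +
    theme_minimal()
}

#' Plot a dose-response branch table
#'
#' Steady-state activity against the ROS clamp, one panel per node, branches
#' coloured by sweep direction; the separation of branches is the hysteresis
#' window.
#'
#' @param object A `branch_table`.
#' @param nodes Nodes to display (default the two bistable UPR branches).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.branch_table <- function(object, nodes = c("uprmt_hsp60", "uprer_bip"), ...) {
  d <- object[object$node %in% nodes, ]
  d$label <- NODE_LABELS[d$node]
  ggplot(d, aes(.data$ros_clamp, .data$activity, colour = .data$direction)) +
    geom_line() + geom_point(size = 0.8) +
    geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    facet_wrap(~label) +
    labs(x = "clamped ROS", y = "steady-state activity", colour = "sweep",
         title = "Dose-response with hysteresis") +
    theme_minimal()
}

#' Plot a sensitivity table
#'
#' Sensitivity coefficients per parameter and timepoint with the significance
#' threshold marked.
#'
#' @param object An `sc_table`.
#' @param top Show only the `top` parameters by maximum `|SC|` (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sc_table <- function(object, top = 15, ...) {
  d <- tibble::as_tibble(object)
  keep <- dplyr::slice_head(
    dplyr::arrange(
      dplyr::summarise(dplyr::group_by(d, .data$parameter),
                       m = max(abs(.data$sc)), .groups = "drop"),
      dplyr::desc(.data$m)),
    n = top)
  d <- d[d$parameter %in% keep$parameter, ]
  d$parameter <- factor(d$parameter, levels = rev(keep$parameter))
  ggplot(d, aes(abs(.data$sc), .data$parameter, fill = factor(.data$timepoint))) +
    geom_col(position = "dodge") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    labs(x = "|SC|", y = NULL, fill = "day",
         title = "Normalised sensitivity coefficients") +
    theme_minimal()
}
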