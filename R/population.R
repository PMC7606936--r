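#' Phenotype levels of the vulnerability state machine
#'
#' Cells move along a lattice of increasing vulnerability:
#' `RESILIENT -> {MT_, ER_}COMPROMISED -> DUAL_COMPROMISED -> VULNERABLE ->
#' DEAD`. The compromised flags are re-evaluated every step (the underlying
#' hysteresis in the dynamics makes reversal rare without hard-coding it),
#' while `VULNERABLE` and `DEAD` are absorbing.
#'
#' @return Character vector of the six states in lattice order.
#' @export
phenotype_levels <- function() PHENOTYPE_LEVELS

#' Classify a cell's phenotype
#'
#' The mitochondria-compromised flag is raised when UPR^mt (hsp-60) activity is
#' below the activity cutoff (0.50), the ER-compromised flag when UPR^ER (BiP)
#' activity is below it. Both flags together give `DUAL_COMPROMISED`; a dual
#' cell whose oxidative and proteotoxic loads both exceed their thresholds
#' enters the absorbing `VULNERABLE` state. `VULNERABLE` and `DEAD` cells are
#' returned unchanged regardless of inputs.
#'
#' @param uprmt,uprer Node activities in `[0, 1]` (vectorised).
#' @param ros,tau Oxidative and proteotoxic loads.
#' @param thresholds List with `activity_cutoff`, `ros_threshold`,
#'   `tau_threshold` (defaults from [default_parameters()]).
#' @param current Current phenotype(s), character; defaults to `"RESILIENT"`.
#' @return Character vector of phenotypes.
#' @export
classify_phenotype <- function(uprmt, uprer, ros, tau,
                               thresholds = default_parameters()$phenotype,
                               current = "RESILIENT") {
  if (any(uprmt < 0 | uprmt > 1) || any(uprer < 0 | uprer > 1)) {
    stop("invalid input: activities must lie in [0, 1]", call. = FALSE)
  }
  n <- max(length(uprmt), length(uprer), length(ros), length(tau), length(current))
  uprmt <- rep_len(uprmt, n); uprer <- rep_len(uprer, n)
  ros <- rep_len(ros, n); tau <- rep_len(tau, n)
  current <- rep_len(current, n)

  mt <- uprmt < thresholds$activity_cutoff
  er <- uprer < thresholds$activity_cutoff
  state <- rep("RESILIENT", n)
  state[mt & !er] <- "MT_COMPROMISED"
  state[!mt & er] <- "ER_COMPROMISED"
  state[mt & er] <- "DUAL_COMPROMISED"
  vulnerable <- mt & er & ros > thresholds$ros_threshold & tau > thresholds$tau_threshold
  state[vulnerable] <- "VULNERABLE"
  sticky <- current %in% c("VULNERABLE", "DEAD")
  state[sticky] <- current[sticky]
  state
}

#' Rate-dependent death event
#'
#' Only cells in the `VULNERABLE` state are at risk: each draws death with
#' probability `1 - exp(-hazard * dt)` per step. All other phenotypes return
#' `FALSE` deterministically. Draws consume the global R random number stream.
#'
#' @param phenotype Character phenotype(s).
#' @param hazard Death hazard (per day), `>= 0`.
#' @param dt Step length in days, `> 0`.
#' @return Logical vector, `TRUE` where the cell died this step.
#' @export
death_event <- function(phenotype, hazard, dt) {
  stopifnot(hazard >= 0, dt > 0)
  at_risk <- phenotype == "VULNERABLE"
  died <- rep(FALSE, length(phenotype))
  if (any(at_risk)) {
    died[at_risk] <- runif(sum(at_risk)) < 1 - exp(-hazard * dt)
  }
  died
}
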