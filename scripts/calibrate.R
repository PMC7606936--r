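#!/usr/bin/env Rscript
# Calibration helper for the population-level default parameterisation.
#
# The shipped defaults in default_parameters() were frozen with this script's
# procedure: a handful of free constants (the chronic repression constants of
# the two UPR branches, the vulnerability thresholds and the death hazard) are
# tuned against five population statistics of the aging cell model:
#
#   1. ~26% of surviving cells below the 0.50 UPR^mt cutoff at day 20
#   2. ~32% below the 0.50 UPR^ER cutoff at day 20
#   3. ~5% cumulative death by day 19 (normal aging)
#   4. first vulnerable cells after day 12 (normal aging)
#   5. ~5% cumulative death by day 14 (tau-exacerbated scenario)
#
# Usage: Rscript scripts/calibrate.R [--n-cells 250] [--seeds 4] [--grid coarse]
# Prints the loss for each candidate and the best parameter set found around
# the current defaults. The defaults themselves are edited in R/, not here.

suppressPackageStartupMessages(library(agevuln))

args <- commandArgs(trailingOnly = TRUE)
get_opt <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
n_cells <- as.integer(get_opt("--n-cells", "250"))
n_seeds <- as.integer(get_opt("--seeds", "4"))

measure <- function(params) {
  at <- function(r, day, col) {
    i <- which.min(abs(r$phenotypes$time - day))
    r$phenotypes[[col]][i]
  }
  rn <- lapply(seq_len(n_seeds), function(s)
    run_simulation(scenario_config("normal", n_cells = n_cells, seed = s), params))
  rt <- lapply(seq_len(n_seeds), function(s)
    run_simulation(scenario_config("tau", n_cells = n_cells, seed = s + 100), params))
  g <- do.call(rbind, lapply(rn, glance))
  c(uprmt_low = mean(g$pct_uprmt_low),
    uprer_low = mean(g$pct_uprer_low),
    dead19 = mean(sapply(rn, at, 19, "DEAD")) / n_cells * 100,
    first_vuln = mean(g$first_vulnerable_day, na.rm = TRUE),
    tau_dead14 = mean(sapply(rt, at, 14, "DEAD")) / n_cells * 100)
}

loss <- function(m) {
  abs(m["uprmt_low"] - 26) / 5 + abs(m["uprer_low"] - 32) / 5 +
    abs(m["dead19"] - 5) / 2 + abs(m["tau_dead14"] - 5) / 2 +
    ifelse(m["first_vuln"] < 12, 10, 0)
}

# local grid around the shipped defaults
knobs <- list(
  "nodes.uprmt_hsp60.ros_repression_K" = c(0.97, 1.00, 1.03),
  "nodes.uprer_bip.ros_repression_K"   = c(0.97, 1.00, 1.03),
  "phenotype.death_hazard"             = c(0.85, 1.00, 1.15)
)

base <- default_parameters()
cat("defaults:\n")
m0 <- measure(base)
print(round(m0, 2)); cat("loss:", round(loss(m0), 3), "\n\n")

grid <- expand.grid(lapply(knobs, identity))
best <- list(loss = loss(m0), params = "defaults")
for (i in seq_len(nrow(grid))) {
  p <- base
  for (k in names(knobs)) p <- set_param(p, k, get_param(base, k) * grid[i, k])
  m <- measure(p)
  l <- loss(m)
  cat(sprintf("[%2d/%d] %s  loss=%.3f\n", i, nrow(grid),
              paste(names(knobs), round(unlist(grid[i, ]), 3),
                    sep = "x", collapse = " "), l))
  if (l < best$loss) best <- list(loss = l, params = grid[i, ], metrics = m)
}
cat("\nbest:\n"); print(best)
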