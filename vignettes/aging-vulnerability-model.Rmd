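---
title: "An agent-based model of age-dependent neuronal vulnerability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of age-dependent neuronal vulnerability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agevuln)
```

# The model

`agevuln` simulates a population of neuron-like cell agents over a 20-day
adult lifespan (day 0 is the first day of adulthood in the nematode frame;
20 days is the upper end of wild-type *C. elegans* lifespan). Each cell
couples three layers:

1. **A continuous molecular network.** Reactive oxygen species (ROS, `R`) are
   the epicentre of spontaneous, age-dependent stress; tau load (`T`)
   accumulates downstream of oxidative signalling; and nine normalised
   stress-response activities `A_i` in [0, 1] track the markers hsp-60
   (UPR^mt), BiP and p-PERK (UPR^ER), skn-1, daf-16, sod-2, bec-1, mTOR and
   pink-1. The deterministic part is

   - `dR/dt = rho0 + rho_age * t + rho_m * f_d + rho_T * T - Vmax * R / (K_M + R) - R * (w_sod2 A_sod2 + w_skn1 A_skn1 + w_daf16 A_daf16)`
   - `dT/dt = sigma * m * (1 + beta * hill(R)) - T * (kappa0 + w_bec1 A_bec1 + w_BiP A_BiP)`
   - `dA_i/dt = (clamp01(drive_i * capacity_i * scale_i) - A_i) / tau_i`

   where `f_d` is the damaged fraction of the cell's mitochondrion pool and
   `m` is the tau scenario multiplier (2 in the tau-exacerbated scenario, the
   assumed 100% increase in aggregation). Every saturable interaction is a
   Hill term; each activity relaxes toward a drive composed of its Fig-style
   wiring (ROS activates skn-1/daf-16; skn-1/daf-16 drive sod-2, bec-1 and
   pink-1; mTOR represses bec-1; mitochondrial damage drives the UPR^mt
   branch; tau drives the ER branch), multiplied by an age-declining capacity
   `exp(-lambda_i t)` and, for the UPR branches, by chronic Hill repression
   from oxidative and proteotoxic load. Because the relaxation target is
   clamped to [0, 1], activities can never leave the unit interval.

2. **A stochastic mitochondrion pool** of up to 100 two-state organelles per
   cell. Per step, healthy organelles are damaged with hazard
   `k_dam * hill(R)`, modulated down by UPR^mt activity (mitochondrial
   proteostasis) and up by loss of UPR^ER activity (ER dysregulation drives
   mitochondrial deficits); damaged organelles are removed by mitophagy with
   hazard `k_mito * A_pink1 * A_bec1`; removed slots refill with an
   age-declining biogenesis probability. Counts are drawn binomially, which
   is statistically identical to per-organelle event queues for exchangeable
   organelles and far cheaper.

3. **A phenotype state machine.** Cells start fully resilient. UPR^mt
   activity below 0.50 raises the mitochondria-compromised flag, UPR^ER (BiP)
   below 0.50 the ER-compromised flag; both flags give the dual-compromised
   state, and a dual cell whose ROS and tau loads both exceed their insult
   thresholds enters the absorbing vulnerable state, from which it dies with
   a constant hazard. Compromised flags are re-evaluated every step
   (reversible); vulnerability and death are absorbing. The hysteresis of the
   UPR dynamics makes spontaneous reversal rare without hard-coding it.

## Bistability and the dose-response analysis

Both UPR branches carry positive self-feedback (Hill coefficient 6) on top of
a basal drive, so the steady-state activity against a *clamped* ROS level
folds: over a window of clamps a high (responsive) and a low (collapsed)
branch coexist, and past the fold only the collapsed branch remains, below
the 0.50 cutoff. `dose_response_sweep()` traces both branches by
continuation; `hysteresis_gap()` quantifies their separation (about 0.5 at
the calibrated defaults; identically zero when the self-feedback weight is
removed). `ros_removal_experiment()` reproduces the late-life rescue attempt:
a cell aged past its fold does not return to the responsive branch when half
its ROS is removed — the collapse is effectively irreversible. At the shipped
defaults the *median* cell is still just above its fold at day 18, so the
demonstration is clearest for cells in the upper range of the population's
oxidative scatter (higher `ros.age_production`).

## Heterogeneity: what is sampled per cell, and what is not

Every positive kinetic rate, Hill constant, coupling weight, capacity decline
rate and relaxation time is multiplied per cell by a Gaussian factor
(mean 1, sd `heterogeneity_cv` = 0.10, truncated at three standard
deviations). Hill exponents, expression scales, the pool capacity and the
classification thresholds are structural. The proteotoxic stressor program
(the tau production rate, its oxidative amplification and the basal clearance
scale) is also excluded from per-cell sampling: it is an imposed,
population-wide insult — the tau scenario applies it as a protocol — while
all *response machinery* stays heterogeneous. Sampling the stressor program
itself would make the tau-exacerbated collapse (every cell ER-compromised
within nine days) and the mild normal-aging distribution (about a third of
cells compromised at day 20) mutually exclusive, because the slowest
tau-accumulators under the doubled program would overlap the fastest normal
accumulators.

## Saturable ROS elimination

The basal elimination channel is Michaelis–Menten, `Vmax * R / (K_M + R)`,
rather than linear. Enzymatic detoxification saturates, and the distinction
matters for the sensitivity analysis: with a linear basal channel the
normalised sensitivity coefficients of both the age-dependent production and
the basal elimination parameters are mathematically capped near one
(elasticities of a linear quasi-steady balance), whereas the model should
show — and with saturable elimination does show — significant control
(|SC| ≥ 1) of both parameters at young (day 5), mid-life (day 10) and old
(day 19) ages.

## Sensitivity analysis

`global_sensitivity_scan()` reduces each static scalar parameter by 5%,
re-runs the population with the same seed (common random numbers), reads the
population-mean cellular ROS at days 5, 10 and 19, and reports
`SC = [(O_pert - O_base)/O_base] / (-0.05)`, i.e. the finite-difference form
of `(dO/dP)(P/O)`; a linear response yields exactly +1 and the sign is fixed
so positive SC means the output moves with the parameter. |SC| ≥ 1 is
*significant*, 0.1–1 *considered*, below that *negligible*. Parameters whose
reduction would violate a structural invariant (a Hill coefficient falling
below 1) are skipped with a message.

## Calibration

Most of the network's constants are fixed by qualitative requirements
(baseline levels, orderings, saturation ranges); a small set of free
constants (the chronic repression constants of the two UPR branches, the
age-decline rates, the insult thresholds and the death hazard) was
calibrated once — by the procedure in `scripts/calibrate.R` — against five
population statistics the model is built to exhibit: ~26% of
surviving cells below the UPR^mt cutoff and ~32% below the UPR^ER cutoff at
day 20; ~5% cumulative loss at day 19 with vulnerability surfacing after
day 12 in normal aging; and ~5% loss by day 14 in the tau scenario with no
resilient cells after day 9. The resulting values are frozen in
`default_parameters()` and shipped as
`inst/extdata/default_parameters.yaml`.

Numerical settings: fixed-step RK4 at `dt = 0.01` day with operator
splitting (deterministic substep, then stochastic mitochondrial and death
events, then re-classification); population summaries recorded every 0.1
day. Halving `dt` changes day-20 means by well under 1%. Steady-state
analyses integrate the activity subsystem to a rate tolerance of 1e-8 with a
step cap of 1e6. All randomness flows from the single configured seed, so
runs are bitwise reproducible; the engine is vectorised across cells, so
results do not depend on any cell iteration order.

## Worked example

```{r example, eval = FALSE}
cfg <- scenario_config("normal", n_cells = 500, duration = 20, seed = 1,
                       n_replicates = 10)
reps <- run_replicates(cfg)
glance(reps)

traj <- run_simulation(cfg)
autoplot(traj, "phenotypes")
autoplot(fold_change_signature(traj))

# mid-/late-life fold changes against an experimental table
sim <- signature_milestones(fold_change_signature(traj))
exper <- readr::read_csv(system.file("extdata",
  "synthetic_experimental_foldchanges.csv", package = "agevuln"))
correlation_r2(sim, exper)
```

The shipped comparison table is *synthetic* (a stand-in illustrating the
`node, group, fold_change` schema); it does not reproduce any published
longitudinal measurements. The coefficient of determination is computed against the
ideal 1:1 line by default (`1 - SS_res/SS_tot` with residuals from `y = x`),
with an ordinary-least-squares variant available, because agreement with the
identity line — not with an arbitrary refit — is what validates normalised
fold changes.

## What the simulations do and do not show

The synthetic populations emulate: heterogeneous aging trajectories,
bimodal end-of-life UPR activity distributions, the ordering of
mitochondrial before ER compromise in normal aging and its reversal under
tau, rate-dependent death, and the sensitivity structure of oxidative
production/elimination. They do not emulate spatial structure, cell–cell
signalling, distinct neuron/astrocyte types, graded tau levels, or any
feature of real expression data beyond the modelled network — so
passing tests show internal consistency with the calibrated behaviour, not
agreement with new experimental measurements.

Known limitations:

* One deficiency-scenario prediction is not reproduced: ablating UPR^mt
  reduces normal-aging survival here by several percentage points, whereas
  knockout worms show no longevity change in unstressed aging. Relatedly, the
  UPR deficiencies' extra mortality under the tau scenario is small in this
  model (the doubled-tau program collapses both UPR branches within
  days in wild type anyway), while the skn-1 and daf-16 deficiencies show the
  expected clear survival cost in both scenarios. With smooth,
  monotone activity collapse and per-cell response thresholds, a fraction of
  cells always crosses the ER cutoff before the mitochondrial one, and
  removing UPR^mt accelerates their dual compromise. Reproducing neutrality
  would require mitochondrial compromise to be an early, common and partly
  transient (flickering) state for most cells, which is incompatible with
  the monotone dose-response collapse this model commits to.
* The insult thresholds and death hazard are calibration constants; only the
  conditional structure (dual compromise plus oxidative and proteotoxic
  insult) is mechanistic.
* The linear 20-day-to-100-year extrapolation (`extrapolate_to_human_years()`)
  is a direct proportionality, provided for orientation only.
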