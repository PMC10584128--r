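---
title: "Modelling and optimizing levodopa intake schedules: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and optimizing levodopa intake schedules: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pdsched builds individualized oral levodopa/carbidopa intake schedules for
Parkinson's disease (PD) patients in four stages: (1) a compartmental
PK/PD simulator generates virtual patients and their medication days;
(2) neural response models learn to predict a patient's day-long symptom
course from the wake state and the dose schedule; (3) evolutionary
optimizers search for schedules that keep the predicted state inside a
target band; (4) a reinforcement-learning agent learns the same dosing
task step by step, so it can adapt within the day. This vignette explains
the models, the design decisions, and what the synthetic experiments do
and do not show.

## The virtual patient

Patient state is measured on the Treatment Response Scale (TRS), a
clinical score from -3 (severe parkinsonian symptoms) through 0 (optimal)
to +3 (severe dyskinesia). The simulator couples a three-compartment
pharmacokinetic model (gut depot `a0`, central `a1`, peripheral `a2`,
amounts in mg) with a first-order effect compartment and a sigmoid-Emax
effect law:

$$a_0' = \mathit{Inf} - k_a a_0,\qquad
  a_1' = \mathit{BIO}\,k_a a_0 - \tfrac{Q+CL}{V_1}a_1 + \tfrac{Q}{V_2}a_2
         + R_{syn},$$
$$a_2' = \tfrac{Q}{V_1}a_1 - \tfrac{Q}{V_2}a_2,\qquad
  c_e' = k_{EO}\!\left(\tfrac{a_1}{V_1} - c_e\right),\qquad
  E = \mathit{BASE} + E_{MAX}\frac{c_e^{\gamma}}{c_e^{\gamma} +
      EC_{50}^{\gamma}}.$$

Twelve constants parameterize a patient; `BASE` and `BASE + EMAX` bound
the attainable TRS values and are kept inside `[-3, 3]`. Units are mg, L,
mg/L and minutes throughout.

**Oral dosing.** Each pill is an instantaneous bolus added to `a0` at its
intake time with the infusion term held at zero — standard first-order
oral absorption. A bolus at time $t$ therefore first affects the recorded
state one grid step later.

**Integration.** Between grid-aligned dose events the system is linear
and time-invariant, so the default simulator steps exactly with the
matrix exponential of the system matrix (`Phi = expm(A*dt)`), which makes
the ~10^4–10^5 trace evaluations inside the optimizers and the RL
environment cheap and exact on the grid. An adaptive `lsoda` integration
restarted at each dose event (tolerances 1e-8/1e-10) is available as
`method = "ode"` and serves as an independent cross-check; the two agree
to better than 1e-6 TRS units in the test suite.

**The packaged population.** The population file
(`inst/extdata/population_default.yaml`) holds means, dispersions, a
correlation matrix and clip bounds for the twelve parameters. Means are
literature-typical oral levodopa values (absorption half-life ~25 min,
central/peripheral volumes 11/27 L, clearance ~31 L/h, effect
equilibration half-life ~17 min, baseline TRS near -2). Dispersions were
calibrated once so that the emulated study reproduces the qualitative
regime reported for cohorts derived from real PD patients: a population
("general") model explains roughly 60–80% of held-out variance while
patient-specific refits become nearly exact. Larger dispersions make the
cohort so heterogeneous that frozen-feature transfer cannot approach a
per-patient fit at any training budget; the packaged values were frozen
before the acceptance experiments and are a configuration file, not code.
`EMAX` draws are additionally clipped to `3 - BASE` so every patient
respects the TRS ceiling.

**Day generation.** A medication day draws its waking length uniformly
from 14–18 h (grid-aligned), 3–7 doses with the first at wake, remaining
intake times on the 10-minute grid with at least 90 minutes between
doses, and sizes uniform on the 5-mg lattice up to 400 mg. Days start
from the endogenous steady state (`a1 = Rsyn V1 / CL`); a 16-h day yields
95 predicted grid states after the initial one. The 50-patient, 3-day
default layout gives 150 day records.

## Patient-response models

Two architectures predict the next TRS state on the 10-minute grid:

* the **history model**, a multilayer perceptron whose input is the `n`
  previous states plus (time-since-dose, size) pairs for the `k` most
  recent doses (`n = 1`, `k = 2` by default, input width `n + 2k`);
* the **impulse model**, an LSTM fed exactly two values per step — the
  previous state and the dose administered at that step — followed by two
  dense layers, with the full medication history carried in the recurrent
  cells.

Variants of both differ in hidden sizes, in predicting the next state
versus its change ("-diff"), and in a `3*tanh` output head that pins
predictions inside the TRS scale ("-tanh"); identifiers such as
`H-128,128-diff` or `I-(8)64,64` name them compactly.

**Rollout training.** Each day is one training sample: the initial state
and the schedule are the inputs and the 95-ish remaining states the
targets. Training always runs closed loop — each predicted state is fed
back as the next step's previous-state input — and the MSE over the whole
predicted day is the loss, with gradients backpropagated through the
entire day including the feedback path (verified against central finite
differences in the test suite). Days are truncated to the shortest
training day for batching; inputs and targets are standardized with
training-split statistics (targets stay raw for tanh heads, and
difference targets are standardized as differences). Optimization is Adam
at 0.001 with global gradient-norm clipping at 5, minibatches of 32 days,
up to 300 epochs, early stopping after 10 epochs without validation
improvement, and best-on-validation checkpointing.

**A subtle input convention.** The per-step dose feature of the impulse
model pairs the dose at a grid time with the previous state, which makes
a dose taken exactly at wake (t = 0) invisible — prediction rows start at
t = 10. Since the generator places the first dose at wake with
probability one, such doses are attributed to the first prediction step.
This mirrors the round-to-grid convention for off-grid intake times and
is dynamically exact: a bolus at `t` first changes the state at
`t + 10`. Without it the entire morning response is unlearnable in
principle.

**Transfer learning.** A new patient contributes 3 observed days: 2 for
training, the third for validation. The general model is retrained with
the same loss at most 100 epochs with patience 25; the history model
retrains every layer, the impulse model freezes the LSTM and retrains
only the dense layers. Transfer uses per-day minibatches (two updates per
epoch). Because rollout training is sensitive to initialization order,
experiment pipelines repeat each fit a few times with different seeds and
keep the best-on-validation run — the repeat-and-select protocol used for
the model-selection tables, scaled down from 10 repetitions to 3–5 to
keep the default experiments within minutes on one CPU.

**Fast inference.** Day-long prediction inside optimizers runs through a
vectorized manual forward pass; a deliberately naive scalar,
layer-by-layer reference implementation is kept solely to verify it
(agreement to 1e-6 per state on random days).

**Metrics.** Model quality is reported as MSE, MAE and
$R^2 = 1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2$, pooled over all
predicted states; MAE is implemented as the mean absolute error.
Paired per-trial losses are compared with the Wilcoxon signed-rank test
at significance 0.05. Repeated-trial tables average after removing trials
beyond 1.5 IQR on validation MSE (the removal rule is not pinned down by
convention, so it is stated here once).

## Schedule optimization

A daily schedule is the first intake time, the inter-dose intervals and
the integer dose sizes. Four optional constraints shrink the decision
space: (1) lattice intake times (10-min step), (2) first dose at wake,
(3) a morning dose plus equal maintenance doses, (4) equal intervals.
The decision vector keeps times first and sizes second; with all four
constraints it is `[dt, d_mor, d_main]` for any dose count. Intervals are
bounded below by 90 minutes and doses lie in `[0, 400]` mg (maintenance
up to 300 mg in the benchmark setting).

Objectives integrate the squared excursion of the state trace by the
trapezoidal rule on the grid (units TRS^2-min): squared deviation from
the optimal state, area outside the target range, and area below a
threshold; a plain dose sum is also available, and the criteria combine
with custom weights. The printed form of the area criteria is read as the
*squared* max, consistent with the squared-deviation criterion; a switch
restores the unsquared reading. Per patient, the threshold is 10% of the
maximum state `BASE + EMAX` and the target range spans 20–40% of it.

**Threshold handling.** During free optimization the below-threshold area
enters as a penalty (weight 10) — counted only after the state first
reaches the threshold following the first dose, because the morning ramp
from the unmedicated baseline is unavoidable and identical across
schedules, and counting it would dilute every comparison. The
exhaustive-search benchmark instead treats the threshold as a hard
feasibility filter with the same onset rule: once risen, never fall
below.

**The benchmark convention.** The comparison method enumerates morning
dose (0–400 mg), maintenance dose (0–300 mg) and interval lattices with
maintenance doses repeating until the day ends, so the dose count follows
from the interval (`fill_day = TRUE`). Ties break toward less total
medication, then shorter intervals. The genetic algorithm (two-point
crossover at 0.5, per-individual mutation at 0.2, per-variable 0.1,
gaussian mutation with sd 10% of range for continuous genes, uniform
lattice resampling for discrete genes, tournament selection, population
at most 200, at most 100 generations) and differential evolution
(rand/1/bin, `F = 0.8`, crossover 0.7) both recover the exhaustive
optimum exactly on coarse grids across random patients.

**Integrality in DE.** The population stays continuous; candidates are
clipped and rounded to the admissible lattice at evaluation time only,
preserving differential diversity on discrete variables, and the best
individual is refined by a final coordinate-descent polish on the lattice
— both behaviors mirror the reference differential-evolution
implementation this field commonly uses.

**Relaxation experiment.** To quantify what constraints 3 and 4 cost,
each patient is optimized twice at the 50-mg step: under constraints
1–4 (benchmark convention) and under constraints 1–2 with free sizes and
intervals. The relaxed run keeps the dose count of the constrained
optimum — so its feasible region is a strict superset — and warm-starts
from it (the constrained solution plus a perturbation cloud seeds the DE
population). The relative decrease of the optimized objective is
guaranteed non-negative by construction; its magnitude (a few to ~15%
per patient on synthetic cohorts) is population-dependent.

## Reinforcement-learning dosing

The dosing environment advances the patient one 10-minute step at a
time. Actions are integers `0..n_max` mapping to doses `a * dose_step`
(so 400 mg at a 25-mg step gives 17 actions); action 0 just advances the
clock, a dosing action auto-advances through the 90-minute lockout
(9 grid steps) accumulating reward. The reward is the negative
area-outside-target-range of the traversed segment, so the episode total
equals the negative whole-day objective exactly. Episodes terminate when
the state exceeds a patient-specific maximum — defaulting to halfway
between the target ceiling and the patient's maximum effect — and
truncate after 110 steps (over 18 h). Because all rewards are
non-positive, ending the day early would otherwise *pay*; termination
therefore charges the remaining day at the termination excursion level,
which removes the overdose-to-exit exploit without touching in-range
behavior.

Observations depend on the backend: the PK/PD backend exposes the
compartment vector; the history backend the `2k + 1` recent-state/dose
summary; the impulse backend the LSTM's internal cells (clipped to
`[-1, 1]`). For the ML backends a dose administered at clock `t` enters
the model at the next prediction row, one grid step of latency that is
inherent to the data convention above.

The PPO trainer (clipped surrogate, GAE 0.95, discount 0.99, 2048-step
buffers, 10 epochs of 64-sample minibatches, Adam 3e-4, running
observation normalization, separate two-hidden-layer actor and critic —
400 neurons per layer for the 5-mg step, 200 for 50 mg) evaluates the
deterministic policy periodically and stops after two checks without
improvement, returning the best snapshot. The default experiment budget
is scaled down (tens of thousands of steps) so a full agent trains in
minutes on one CPU; on a single-dose-solvable toy patient it reaches and
surpasses the best fixed-dose policy found by enumeration.

## What the synthetic experiments show — and what they do not

The generator emulates dense, noise-free TRS observation of patients
whose ground truth *is* the PK/PD model: no sensor noise, no circadian
covariates (meals, activity, sleep quality), no day-to-day parameter
drift, and dose times aligned to the grid. Passing tests therefore
demonstrate that the learning and optimization machinery recovers known
dynamics from realistic amounts of data (3 days per patient), not that
three days of wearable-sensor data suffice for real patients. Conversely,
model mis-specification — real patients not following a three-compartment
model — is invisible here by construction.

Numerical conventions collected in one place: trace grids run
`t = 0, 10, ..., day_length - 10` with the wake state at `t = 0`;
trapezoidal quadrature throughout; ODE tolerances 1e-8/1e-10 when the
adaptive path is used; Adam epsilon 1e-7; gradient clip 5 (0.5 for PPO);
early-stopping counters reset only on strict improvement; exhaustive-tie
break by total dose then interval; all stochastic stages draw their seeds
from a single global seed through a stage-name hash.

Default problem sizes (chosen to keep the full pipeline a few minutes on
one CPU and stated here as the package's defaults): 40 + 10 patients,
3 days each, general training up to 300 epochs with patience 10, 3–5
repeat-and-select restarts, DE budgets of 30–60 individuals for 40–150
generations, PPO budgets of ~30k steps for small action spaces.

Known limitations: a single medication (no dopamine-agonist
interactions); the dose count is never optimized jointly with times and
sizes except through the fill-day convention; the impulse model cannot
represent sub-grid intake times; PPO training, while seeded and
single-threaded, is the one stage whose result depends strongly on its
budget; and all headline numbers inherit the synthetic population, so
they describe the emulated study, not any real cohort.
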