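---
title: "Capacity allocation in a radiology unit: model, solver, and simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capacity allocation in a radiology unit: model, solver, and simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radalloc)
```

## The decision problem

A radiology unit runs a small fleet of CT scanners through a business day
split into `N` regular 15-minute periods, followed by `K` overtime periods
reserved for clearing leftover demand. Three patient streams compete for the
same machines:

* **Outpatients (OP)** are booked days in advance according to an
  appointment schedule, but each booked patient shows up only with an
  individual probability — no-show is the central disturbance the unit
  manages, and the reason it overbooks.
* **Inpatients (IP)** are requested by the wards; at most one request
  arrives per period, with probability `p_ip`.
* **Emergency patients (EP)** arrive with probability `p_ep` per period and
  must be scanned in the very next period — they are never queued.

At the start of each period the scheduler observes the waiting counts and
decides how many patients of each type to start. Unserved inpatients and
outpatients accrue per-period waiting costs; patients pushed past the
regular day are served in overtime at a per-patient premium; and anyone
still unserved when the overtime budget runs out triggers a terminal
penalty. The objective is the minimum expected total cost of one day.

Key structural assumptions: service times are deterministic and equal to one
period (the slow scanner being the exception below); arrivals of the three
streams are mutually independent; shows are independent across booked slots;
no patient leaves the queue within the day; the day opens empty, because
overnight emergencies are handled by dedicated equipment.

## States, actions, and the capacity argument that prunes them

A regular-period state is the triple `(w_ip, w_op, w_ep)` with
`w_ep ∈ {0, 1}`; an overtime state is the pair `(w_ip, w_op)`. Box bounds
are immediate: by period `i` at most `i` inpatient arrivals can have
accumulated, and at most the cumulative schedule of outpatients.

The package's restricted enumeration adds a joint bound on the backlog
`w_ip + w_op`. Each elapsed period with capacity `C_l` serves
`min(C_l, waiting)` patients, of which at most one is an emergency; so
whenever queues are non-trivial at least `C_l − 1` inpatients/outpatients
leave per period. Evaluating that guarantee at its worst case (an emergency
present in every past period) gives, for period `i ≥ 2`,

```
w_ip + w_op ≤ Σ_{l≤i} Ag_l + i − Σ_{l<i} (C_l − 1)
```

with `Ag_l` the outpatients booked for period `l`. The overtime analogue
subtracts, in addition, the overtime capacity already consumed: the bound
can only shrink as overtime periods elapse, which is the monotone form the
package implements. Should cumulative capacity outrun cumulative arrivals,
the regular-period bound degenerates and the enumerator falls back to the
fresh-arrivals box (and, in overtime, to the single empty state); on the
default clinic day this branch is never active, but it is implemented and
tested. On that day the pruning removes 43% of the box states
(93,534 → 52,680), which is what makes plain backward induction practical.

Feasible actions always seat the waiting emergency first and never idle a
slot while someone waits: `a_ip + a_op + a_ep = min(C_i, |z_i|)`. Action
lists are generated in descending `a_ip` order, and the solver's argmin uses
strict improvement, so ties break deterministically toward serving
inpatients — policies are reproducible across runs and platforms.

## Transition model

Inpatient and emergency arrivals are Bernoulli shifts: after serving `a` of
`w` waiting patients, the successor count is `w − a` or `w − a + 1`. The
outpatient component counts shows among the slots booked for the *next*
period: with slot-specific show probabilities it is Poisson-binomial,
computed exactly by convolving one two-point Bernoulli mass per slot
(left-to-right over slots; the floating-point order effect is far below the
`1e-12` normalization tolerance the tests enforce). Nothing is pruned or
truncated: probabilities below machine-noise thresholds are kept, since the
state space is small enough and pruning would bias the expectations. A show
probability of exactly 0 or 1 is tolerated by the kernel (the slot's mass
simply degenerates), although the synthetic generator clips its output to
`[1e-6, 1 − 1e-6]` to keep every outcome representable.

The crossover from the last regular period into overtime is deterministic:
no arrivals occur after hours, and the emergency component is dropped
because the waiting emergency was just served and late emergencies go to
dedicated equipment.

## Costs and their default calibration

All six unit costs are user-settable; the shipped presets derive them from
two public figures, in US$:

| cost | default | derivation |
|------|---------|------------|
| `wc_op` | 1.56 | one hour of average household income (343.87/month over 220 h) |
| `wc_ip` | 0.78 | half of `wc_op` (indirect bed-blocking cost) |
| `pc_op` | 12.48 | one 8-hour workday of income lost |
| `pc_ip` | 24.96 | twice `pc_op` (risk of an extra hospital day) |
| `oc_ip`, `oc_op` | 2.76 | a 15-minute slice of the radiologist's 11.04/h wage |

Derived values are rounded to cents by default (`round_cents = FALSE` keeps
full precision for sensitivity work). The `low`/`high` presets are 0.5× and
1.5× the baseline. Overtime charges per patient *served* in overtime, not
per patient waiting — the formula is linear in the action, not the state.

## Solver numerics

Backward induction stores one dense value array per period, indexed directly
by waiting counts, with `NA` outside the restricted state set. Because the
emergency component of every feasible action clears the waiting emergency,
the expected continuation depends only on the post-action remainders
`(w_ip − a_ip, w_op − a_op)`; the solver therefore pre-computes, once per
period, the continuation matrix by shifting the next period's value array
under the arrival kernels, and every state–action evaluation is a single
lookup. If any positive-probability successor ever lands on an `NA` cell the
sweep stops with an error rather than extending the set silently — this
doubles as a runtime proof that the restricted sets are closed under the
dynamics, and a dedicated test verifies closure exhaustively on a mid-sized
day.

The expected day cost is reported as the average of the period-1 values over
the opening-arrival distribution (Bernoulli IP and EP, Poisson-binomial
period-1 shows from the empty pre-day state); the full `V_1` table is also
retained, since per-state values are what a duty manager consults.

## Benchmark policies and the simulator

Five heuristics bracket practice: P1 draws uniformly without replacement
from the pooled IP+OP queue; P2 prioritizes outpatients (closest to current
practice in many units); P3 prioritizes inpatients; P4 runs IP-priority for
the first half of the day (`ceiling(N/2)` periods) then switches, with
OP-priority in overtime; P5 is P4's mirror image. All of them seat
emergencies first and never idle capacity — they differ only in how the
residual slots are split.

The Monte-Carlo simulator replays whole days: a "day stream" records every
Bernoulli arrival and every slot's show outcome, so the same stream can be
replayed under different policies. Common random numbers are the default in
`compare_policies()` — the comparison of two policies on identical arrival
histories strips arrival noise out of the cost difference — but independent
streams are available (`common_random = FALSE`) since either experimental
convention is defensible. Policy differences are tested with Welch's
unequal-variance two-sample t-test at the 5% level; the equal-variance
variant would be hard to justify given how visibly the cost dispersion
differs across policies. Occupancy is reported as served starts divided by
*all* offered capacity, counting unused overtime slots in the denominator —
the stricter of the two possible conventions, chosen because the overtime
resources are reserved (and paid for) whether or not they are used.

## The synthetic no-show generator

Real show behaviour is patient-specific; operationally one fits a penalized
logistic regression on appointment records (lead time, time of day,
demographics, ...) and feeds the predicted per-slot show probabilities into
the model. Such records cannot be shipped. The `noshow_spec()` module
therefore emulates the *product* of that pipeline: per booked slot it draws
a small synthetic covariate vector (standardized lead time with a negative
coefficient, an afternoon indicator, an age-like score), pushes the linear
predictor through the inverse logit, and returns one probability per slot.
`calibrate_intercept()` bisects the intercept until the Monte-Carlo mean
show probability hits a chosen target within 0.005.

The default target mean used throughout the examples is **0.8** — a 20%
no-show rate, mid-range for public-sector CT clinics with long waiting
lists. This is a modelling choice of the package, not an estimate: the
generator reproduces realistic heterogeneity in the probabilities, not any
particular clinic's case mix. Consequently, simulated dollar figures are
scenario results, not forecasts for a specific unit; what carries over to
real data are the structural findings the tests verify — the optimal policy
dominates the heuristics, spread-out double overbooking beats front-loaded
flight-style overbooking, and a second overtime resource lowers total cost.

## Problem sizes used by the test suite

Exactness is checked where exactness is cheap, and sampling properties where
they are informative:

* the show-count pmf is compared with full `2^Q` subset enumeration up to
  `Q = 12`;
* solver optimality is verified against exhaustive enumeration of *all*
  deterministic Markov policies (with exact outcome-tree expectations) on a
  2-period micro instance, and by hand-computable deterministic trajectories;
* the stochastic orderings (optimal vs. P1–P5, double vs. flight, one
  vs. two overtime resources) run on a 12-period scaled clinic day with the
  same structure as the full problem (mixed fleet, stride-6 overbooking, two
  overtime periods) at 5,000–10,000 simulated days, and solver–simulator
  consistency on a 3-period instance at 20,000 days — sizes chosen so the
  whole suite stays comfortably in desk time while keeping Monte-Carlo
  standard errors small against the effects being checked;
* the full 52,680-state clinic day is solved in seconds and exercised
  end-to-end in the examples.

## Known limitations

* At most one slow (two-period) scanner is supported, and its service
  pattern enters only through the alternating capacity profile — there is no
  mid-exam preemption, and the phase (first start in period 1 by default) is
  a configuration field.
* Overtime is restricted to the fast scanners (capacity 1 or 2 per overtime
  period); a slow scanner spanning two overtime periods is not modelled.
* Arrival probabilities are period-invariant in the shipped presets; the
  internal storage is per-period, so time-varying rates need no refactor,
  but no preset exercises them.
* The one-Bernoulli-arrival-per-period model caps IP/EP arrivals at one per
  15 minutes; bursty emergency demand is outside scope.
* No within-day rescheduling of outpatients and no patient abandonment are
  modelled.
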