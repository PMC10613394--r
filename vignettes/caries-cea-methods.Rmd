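---
title: "Methods: a Markov cohort model for school-based caries prevention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model for school-based caries prevention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cariesCEA)
```

## The decision problem

South African public schools can deliver several mutually exclusive
caries-prevention programmes — APF gel application, fissure sealants,
atraumatic restorative treatment (ART), supervised tooth brushing — or the
state can pursue population-level sugar reduction (taxation, marketing
restrictions). `cariesCEA` evaluates these against doing nothing, from the
public healthcare payer's perspective, using a deterministic Markov cohort
model plus a probabilistic sensitivity analysis (PSA).

## Model structure and assumptions

A closed, expected-value cohort (fractional occupancies, not
microsimulation) of `cohort_size` learners starts caries-free at
`start_age` and is advanced through `n_cycles` annual cycles. States are
*no caries*, *caries*, *treated* and the absorbing *exited*. Within each
cycle the model:

1. applies the age's exit probability to every living state (exit is
   independent of oral-health state and irreversible);
2. moves caries-free survivors into the caries state with the age's caries
   probability, caries cases into treatment with probability
   `1 - prob_untreated`, and treated learners back to caries with
   probability `prob_recurrence`;
3. accrues costs for everyone present at the *start* of the cycle (the
   whole class receives the programme at the start of the school year,
   including those who leave during it) and DMFT for the cycle's incident
   cases;
4. discounts both at `discount_rate`, with cycle 0 undiscounted
   (`1/(1+r)^t`, `t = 0, …, n_cycles−1`). No half-cycle correction is
   applied; annual spreadsheet-style cohort models conventionally omit it
   and nothing in the source material suggests one was used.

Occupancies are asserted to sum to the cohort size at every cycle to
1e−9 relative; a violation is an internal error, never silently repaired.

The annual caries probability is interpreted as *conditional on being
caries-free* (it drives the flow out of the no-caries state). An
unconditional population incidence reading is also defensible; the
conditional reading is the one consistent with a state-transition diagram
in which only caries-free learners can become new cases, and it is isolated
in `transition_step()`/`dmft_increment()` if a user wants to re-wire it.

## How effectiveness acts

Effectiveness is published only as a *percentage reduction in DMFT*. Two
mechanisms are implemented, switched by `effect_mechanism`:

- `"dmft"` (default): the cohort's state dynamics are those of do-nothing
  and the DMFT accrual of incident cases is scaled by `1 − effect`. Averted
  DMFT is then *exactly proportional* to effectiveness. The published
  deterministic results have precisely this proportionality across the APF
  gel, fissure sealant and ART arms (each arm's averted DMFT equals its
  effectiveness times a common do-nothing total), which is why this is the
  default: it is the only mechanism that can reproduce that structure.
- `"flow"`: effectiveness instead multiplies the caries-entry probability
  by `1 − effect`. This changes the state trajectory (protected learners
  remain at risk longer), so averted DMFT is no longer exactly linear in
  effectiveness. It is the more mechanistic reading and is kept one switch
  away.

The sugar-reduction arm is special. Deterministically (under
`sugar_mechanism = "slope"`, the default) it averts
`sugar_slope × sugar_reduction` = 0.0128 × 30 = 0.384 DMFT per living
learner per year, as an absolute offset subtracted from the cycle's DMFT
increment and floored at zero — cohort DMFT cannot go negative. Its
tabulated beta effectiveness (31.89%, SD 0.18) is used only when
effectiveness is explicitly sampled or overridden, i.e. in the PSA, where
all arms — sugar included — run through the standard effect mechanism.
`sugar_mechanism = "effect"` makes the deterministic run use the
percentage too.

## Parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `cohort_size` | 10,000 | learners | closed cohort |
| `start_age`, `exit_age` | 5, 15 | years | 10 annual cycles |
| `discount_rate` | 0.05 | /year | costs and DMFT alike |
| `prob_untreated` | 0.7 | probability | caries cases not reaching care |
| `prob_recurrence` | 0.188 | probability | treated → caries |
| `dmft_growth` | 0.0059 | /year | per-case DMFT accrual growth |
| `sugar_slope` | 0.0128 | DMFT per g/day | linear dose response |
| `sugar_reduction` | 30 | g/day | policy target |
| `screening_cost` | 525.61 | ZAR/learner/year | bundled with clinical arms |
| `wtp` | 38,500 | ZAR per DMFT averted | NMB threshold |

Per-arm annual costs (ZAR/learner/year) and percentage effectiveness, with
their SDs, live in `default_config()` and the bundled
`inst/extdata/table1_default.yaml`. A cost SD that is absent is imputed as
10% of the mean at load time; an explicitly given SD (tooth brushing,
544.29) is never overwritten. Effectiveness is stored on the percent scale
as published and converted to a proportion only inside computations.

## Synthetic age schedules and calibration

The age-dependent inputs — annual caries probability, exit probability and
per-case baseline DMFT — were published only in an unavailable appendix.
`generate_age_schedule()` therefore produces seeded stand-ins:

- caries probability: level 0.2, either exactly flat or ramped from 0.7× to
  1.3× of the level with small seeded jitter, constrained non-decreasing
  (caries experience rises with age) and inside [0, 1]. The 0.2 level is in
  the range implied by the high reported childhood caries prevalence
  (60–70% by mid-childhood).
- exit probability: flat 0.03 per year, a plausible combined rate of
  drop-out, relocation and transfer out of the public system.
- baseline DMFT per incident case: 1.2 at age 5 rising linearly to 1.9 by
  age 14, consistent with national child oral-health survey magnitudes.

`calibrate_schedule()` then fits one scalar multiplier on the exit column
(bisection on a bracketing interval, multiplier tolerance 1e−6, 200
iteration cap, bracket bounded so no probability can exceed 1 — an
unreachable target errors with the achievable range rather than clamping)
so that the implied 10-year screening budget for the cohort matches the
published ZAR43.78 million within 0.5%. That budget is treated as an
*undiscounted* implementation figure: with 5% discounting the 10-year
screening total is bounded above by 525.61 × 10,000 × Σₜ 1.05⁻ᵗ ≈ ZAR42.62
million even with zero exits, so no discounted reading can reach ZAR43.78
million, while the undiscounted reading calibrates comfortably
(`measure = "discounted"` remains available for other targets). An
optional second multiplier on the caries column can match a do-nothing
total-DMFT target the same way.

What the synthetic schedules do **not** emulate: the authors' actual
appendix values, any non-monotone age pattern, grade-specific drop-out
spikes, or correlation between caries risk and drop-out. Consequently
engine-level absolute totals (total costs, total DMFT averted) are *not*
comparable to the published Table of totals — only their structure is.
Reproduction of the published tables is done in fixture mode, which feeds
the printed per-arm totals directly into the CEA layer; tests that pass on
synthetic schedules demonstrate the engine's internal correctness
(conservation, closed forms, oracle equivalence), not agreement with the
unavailable data.

## Deterministic CEA conventions

- Ranking: ascending DMFT averted; ties broken by lower cost first.
- All arms are kept in the ranked table and negative ranked ICERs are
  reported as computed (matching published practice); `frontier = TRUE`
  additionally flags strict dominance (another arm is at least as effective
  and cheaper, or as cheap and more effective, with one strict) and
  extended dominance (off the efficient frontier without being strictly
  dominated).
- The frontier is built greedily from the cheapest arm by repeatedly taking
  the smallest incremental ICER among strictly more effective arms; its
  ICER sequence is non-decreasing by construction, and the
  frontier-walk decision rule provably coincides with the NMB argmax
  (property-tested on randomized instances).
- An ICER between equally effective arms is undefined and raised as a
  typed error carrying the cost difference, never returned as ±Inf.
- Display rounding mirrors the published tables — ICERs versus do-nothing
  to the nearest integer, or two decimals when the magnitude is below 10;
  ranked ICERs to integers; NMB to whole ZAR — while full precision is kept
  internally and in the non-display CSVs.

## Probabilistic sensitivity analysis

Only the quantities with published distributions are sampled: each arm's
annual per-learner cost (gamma, moment-matched as shape = μ²/σ², scale =
σ²/μ) and effectiveness (beta on the proportion scale, ν = m(1−m)/s² − 1,
α = mν, β = (1−m)ν). Schedules and structural probabilities stay fixed. A
beta SD at or above √(m(1−m)) is an error naming the feasible bound — never
silently clipped, since clipping would change the stated uncertainty.
Draws use one random stream per run in arm-major order (all of an arm's
costs, then its effectiveness draws), so every stochastic output is a pure
function of inputs and seed. Default 1000 iterations.

CEACs use the mutually-exclusive convention: at each threshold of the
default grid (ZAR0–40,000 in steps of 500, covering the ZAR500 and
ZAR38,500 discussion points), an arm's probability is the fraction of
iterations in which it attains the highest NMB among all arms including
do-nothing; exact ties share an iteration equally, so curves sum to one at
every threshold. A pairwise-versus-do-nothing variant sits behind
`pairwise = TRUE`.

## Problem sizes and numerical checks in the test-suite

The bundled tests run the full 10-cycle, 10,000-learner model for the
deterministic checks; engine-versus-oracle equivalence uses randomized
miniatures (cohorts ≤ 10, ≤ 3 cycles) against an independent
enumerate-and-sum ledger; distribution moment recovery uses 10⁵ draws
within three Monte-Carlo standard errors; PSA behaviour is exercised at
20–400 iterations with a single 1000-iteration envelope check. All
randomized tests fix their seeds.

## Known limitations

- No QALY/DALY weighting, no societal costs, no treatment-state costs
  (payer cost is programme plus screening only), matching the source
  analysis's payer perspective.
- Expected-value cohort only; no individual-level microsimulation, so no
  stochastic cohort variability.
- No correlation between sampled parameters, and no one-way/tornado
  deterministic sensitivity analysis.
- The sugar arm's published averted-DMFT total is not derivable from the
  stated slope and dose alone; with the default synthetic schedules the
  slope offset exceeds the modelled do-nothing accrual, so the floored
  sugar arm averts everything the comparator accrues. Treat the sugar arm's
  engine-level totals as illustrative.
- The published PSA means/SDs and CEAC probabilities depend on the
  unavailable appendix schedules and are therefore only qualitatively
  comparable (ordering of curves), not numeric targets.
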