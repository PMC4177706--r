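---
title: "Methods: an agent-based model of opinion-leader emergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an agent-based model of opinion-leader emergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olsim)
```

## The model and its assumptions

`olsim` simulates belief dynamics on a single patient care unit. The core
assumption is a normative one: nurses are rational belief revisers.
Confronted with new evidence, an agent weighs the evidence against its own
prior belief and weighs the messenger's credibility against its own; it
adopts what is close enough to believe, asks a credible colleague when it
cannot judge, and ignores the rest. Opinion leadership is not an input —
no agent is labelled "leader" — it *emerges* as the repeated receipt of
advice links by agents that happen to be visible and credible when their
colleagues are uncertain.

Every quantity lives on a 1–100 probability-like scale. The unit mixes
three roles with fixed position-based (unearned) authority: staff nurses
(50), educators (80), one manager (90). Further structural assumptions:

* all agents know each other equally well (a complete acquaintance
  network); advice partners are drawn uniformly from the available pool;
* one announcement per tick, from an agent drawn uniformly at random;
* the announcer neither assesses nor revises its belief on its own
  announcement, and never seeks advice about it;
* assessments are symmetric absolute differences — an agent is as
  suspicious of evidence far *above* its belief as far below, and of an
  announcer much *more* credible than itself as much less.

One tick runs: announce → assess (evidence, announcer credibility) →
uncertainty → availability → advice and reassessment → adoption and belief
revision. In continuous mode `commit_and_reset()` then disconnects links,
replaces prior beliefs with revised beliefs *for revisers only*, and
recomputes visibility then credibility. That ordering matters: credibility
depends on visibility, which depends on the just-committed beliefs.

## Parameters that matter

| parameter | default | units | why this value |
|---|---|---|---|
| `mean_prior_belief`, `mean_earned_authority`, `mean_motives` | 50 | score in [1,100] | midpoint of the scale; the "average unit" |
| `mean_evidence` | 60 | score | evidence mildly above the average belief, so announcements carry news |
| `sd_attributes`, `sd_evidence` | 10 | score | keeps ~95% of draws within ±20 of the mean on a 100-point scale; makes the 20-point tolerances meaningful |
| `credibility_threshold` | 65 | score | an advisor must beat the typical agent (~50) by a wide margin |
| `evidence_tolerance`, `credibility_tolerance` | 20 | score difference | ±2 SD of the attribute draws: disagreement beyond the bulk of natural variation triggers uncertainty |
| `epistemic_visibility_threshold` | 70 | prior belief | accuracy-motivated agents act only on strong beliefs (strict `>`) |
| `pragmatic_visibility_threshold` | 30 | prior belief | interest-motivated agents act readily; only "lower" is dictated, 30 mirrors 70 about the midpoint |
| `visible_earned_weight` / `hidden_earned_weight` | 0.8 / 0.2 | fraction | peers judge visible agents mostly on performance and hidden agents mostly on position |

Attribute draws are Normal(mean, sd) **clipped** to [1, 100] rather than
resampled: clipping is simple, monotone in the mean, and preserves the
ordering of experimental conditions; at the default sd the clipped mass is
negligible except at extreme means.

## What the generator emulates — and what it does not

All inputs are synthetic. The generator emulates a unit whose members
differ smoothly in belief, performance and motivation around
user-controlled means; it does **not** emulate empirically measured
nurses. Real units have correlated attributes (experience drives both
earned authority and belief strength), non-normal and possibly bimodal
motive distributions, incomplete and clustered social networks, and
evidence with content. A green test therefore establishes that the
*mechanism* behaves as posited — visibility tracks beliefs and motives,
availability tracks visibility and the credibility bar, advice flows from
the credible to the uncertain — not that any real unit will show these
magnitudes. The verification experiments are internal-consistency checks,
not empirical validation.

## The verification harness

Two experiments probe the model. The **parameter sweep**
(`build_sweep_design()`, `run_sweep()`) crosses 3×2×2×2×2×2×3 = 288
conditions and runs each as independent single-tick episodes with fresh
initialization (the sweep outputs are per-run counts, so carrying state
across replicates would only blur conditions together). The **time
series** (`run_time_series()`) holds one 106-agent unit fixed for 20
chained ticks and exports per-agent trajectories plus the advice edge
list; `identify_persistent_advisors()` (default: in-links at ≥ 2 distinct
ticks — the notion of *repeated* advice with no stricter cutoff dictated)
names the emergent opinion leaders.

`summarize_sweep()` aggregates replicates to cell min/max/mean;
`run_sign_checks()` fits one OLS per posited relationship **on the cell
means** (n = 288) and compares only coefficient *signs* — magnitudes, R²
and p-values depend on modelling choices no reference pins down, so they
are reported, never asserted. Directions known to be weak are fitted but
not asserted. `fit_availability_logistic()` models whether any advisor
was available from the raw runs; complete separation is reported, not
silently regularized.

## Numerical and design choices

* **Determinism.** Every unit of work (a sweep replicate, a time-series
  tick) seeds R's RNG from `derive_seed(master, labels...)`, a pure
  31-bit string hash. Replicate substreams are hashed from the factor
  *values excluding the credibility threshold*: the threshold affects
  neither initialization nor announcement, so threshold-matched cells
  share identical unit draws and the monotonicity of availability in the
  threshold holds exactly, not just in expectation. Identical master
  seeds give byte-identical CSV/TSV outputs.
* **Boundaries.** Motive split: pragmatic `< 50`, epistemic `≥ 50`.
  Visibility is strict (`b > θ`); availability and adoption are inclusive
  (`c ≥` threshold, assessment `≤` tolerance).
* **Revised assessments.** An advice-induced reassessment counts as
  "revised" only when it moves the assessment *across its tolerance* —
  a changed judgment. Counting any numeric change would mark every
  seeker (continuous draws never tie), collapsing two output variables
  into copies of the sought-advice count and making them useless as
  regressors.
* **Degenerate inputs.** Empty advisor pools are a legitimate outcome
  (uncertain agents simply keep their own assessments); an empty
  *announcer* pool (possible only with `announcer_pool = "available"`)
  is an error. Zero-variance regressors and constant logistic outcomes
  error loudly.
* **Open choices decided.** The announcer is drawn from all agents (the
  restricted pool is available as a config switch); the announcer's
  credibility is taken at announcement time; the motive-to-threshold map
  is two-level rather than continuous; exactly one manager per unit
  (100 staff + 5 educators + 1 manager = the 106-agent reference unit).

## Known limitations

The uncertainty rule (either assessment beyond tolerance) and the adoption
rule (both within tolerance) are exact logical complements. Two
consequences are worth knowing when reading the sign checks:

1. every agent that is *not* uncertain adopts, so the revised-beliefs
   count is approximately (unit size − need-advice count) plus the
   advice-rescued seekers. Holding advice-giving fixed, needing more
   advice therefore *lowers* the revised-beliefs count: the need-advice
   partial coefficient in check G comes out negative, stably.
2. advice replaces a seeker's credibility assessment with |advisor
   credibility − announcer credibility|, and advisors clear a credibility
   bar that typically puts them far from the announcer; advice therefore
   flips the credibility assessment out of tolerance more often than into
   it, and the revised-credibility-assessment count in check F associates
   *negatively* with revised beliefs.

Both directions are structural under the stated rules — they hold with
the opposite sign at p < 1e-3 across independent sweeps — so the
corresponding two acceptance assertions are left failing rather than the
rules being bent to pass them. Other limitations: no affective or
bounded-rationality agent modules, no multi-unit or inter-professional
networks, no empirically parameterized ("hybrid") units, and no graphical
interface — outputs are tables and edge lists by design.
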