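---
title: "An agent-based model of growth-factor competition for heparan-sulfate binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of growth-factor competition for heparan-sulfate binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hscompete)
```

## The biological question

Angiogenesis — the sprouting of new blood vessels — is switched off in
healthy adult tissue and transiently switched on during wound healing. The
regulators of this switch (VEGF, PDGF-B, PF-4, TSP-1 and relatives) are
heparin-binding proteins: they act only while anchored to heparan sulfate
(HS) chains in the extracellular matrix, and their anchoring strengths
differ systematically. Stimulators such as VEGF bind HS weakly, vessel
stabilizers such as PDGF-B bind with intermediate strength, and the
endogenous inhibitors PF-4 and TSP-1 bind most tightly. Elution experiments
show that a rising concentration of a competing solute (or, in tissue, of
HS-cleaving proteases such as heparinase) releases these factors in
affinity order: stimulators first, inhibitors last.

`hscompete` implements a deliberately minimal agent-based model of this
system. Its purpose is a proof of concept: can affinity-ordered detachment
plus competition for a finite pool of binding sites, and nothing else,
reproduce (a) the orderly stimulator-then-stabilizer-then-inhibitor
signaling sequence of normal wound healing, and (b) its failure — inhibitors
out-competed from the matrix — when a tumor-like source keeps injecting
stimulators?

## The model

Space is a `grid_width` × `grid_height` lattice of *microenvironments*
(default 51 × 51 = 2601 patches) with toroidal boundaries. Three kinds of
entities live on it:

* **Microenvironments.** Each patch carries a heparinase level, initialized
  independently uniform on `[0, heparinase_max]` and subject to stochastic
  flux (below). Heparinase is the detachment agent.
* **Cells.** `n_cells` immobile stromal cells at continuous positions, each
  with a fixed number of HS binding sites drawn once from a rounded,
  zero-clamped normal distribution `N(site_mean, site_sd²)`. A site is
  either free or occupied by exactly one factor.
* **Growth factors.** Discrete agents of class LA, MA or HA (low/medium/high
  affinity). A free factor performs a random walk — unit step length, uniform
  heading, positions wrapping on the torus. Class `c` is characterized by
  two parameters: an attachment probability `attach_prob[c]` and a cleavage
  threshold `cleave_threshold[c]`.

Each scheduler step executes six events in fixed order:

1. **Inflow.** `inflow_per_step` new free factors per class appear at
   uniform random positions (all zero in wound-healing mode; the one-shot
   `initial_release` happens at t = 0 instead).
2. **Movement.** Every free factor takes one random-walk step.
3. **Binding.** Every free factor, in a freshly shuffled uniform random
   order, makes at most one attempt: among cells in its patch with a free
   site, one is chosen uniformly; with probability `attach_prob[c]` the
   factor binds, occupying one site. The shuffle removes creation-order
   bias when factors compete for the last sites of a cell.
4. **Cleavage.** Every factor that entered the step bound is detached if
   and only if its patch's heparinase is at or above its class threshold.
   Detachment frees the site; the factor's fate is `cleaved_fate`:
   `degrade` (default — it leaves the system) or `recycle` (it rejoins the
   free pool).
5. **Heparinase flux.** Each patch independently, with probability
   `flux_prob`, changes its heparinase by an amount uniform on
   `[-flux_magnitude, +flux_magnitude]`, clamped to `[0, heparinase_max]`.
6. The step counter advances and per-class bound/free/cleaved counts are
   recorded.

The principal observable is the per-class count of *bound* factors over
time, averaged pointwise over `n_replicates` independent replicates
(replicate `r` is seeded with `seed + r`).

### Why a deterministic threshold for cleavage

The source material specifies an *ordering* of detachment — LA released at
the lowest heparinase concentration, HA only at the highest — but no rates.
A hard threshold (`cleave iff h ≥ θ_c`, with `θ_LA < θ_MA < θ_HA` enforced
at validation) is the minimal reading of that statement; stochasticity in
detachment then enters solely through the heparinase flux, which slowly
drives each patch's level across the thresholds. The strict ordering is the
one quantitative fact the elution data pin down, so it is a hard
validation error, not a warning.

### Cleavage timing within a step

The event list fixes binding before cleavage but does not say whether an
attachment formed in event 3 is already exposed to event 4 of the same
step. This package checks only factors that entered the step bound: a new
attachment is first evaluated on the following step. With the
deterministic threshold rule the alternative would make binding on any
patch at or above a factor's threshold strictly unobservable (bind and
cleave inside one step), collapsing end-of-step occupancy in controlled
single-site experiments to zero and making attachment probability and
cleavage interact in a way the two-parameter class description does not
intend. Under the chosen timing the single-site system is an honest
two-state Markov chain (see "Verification" below).

### Parameter defaults and what they mean

| parameter | default | role |
|---|---|---|
| `grid_width`, `grid_height` | 51 × 51 | lattice size; 2601 microenvironments |
| `n_cells` | 200 | stromal cell count (unspecified in the source; chosen so that cells occupy ~8% of patches and a free factor needs a few tens of steps to find a site, giving well-separated binding and cleavage time scales) |
| `site_mean`, `site_sd` | 5, 2 | per-cell binding sites, i.e. ~1000 sites grid-wide |
| `attach_prob` | 0.5 each | equal for all classes: affinity differences are expressed through detachment only, matching the evidence, which constrains detachment order and nothing else |
| `cleave_threshold` | 0.25 / 0.50 / 0.75 | × `heparinase_max`; evenly spaced strictly ordered thresholds |
| `initial_release` | 300 per class | one-shot release at t = 0 (the staggered platelet release is outside the model); exact source values were unpublished, and the qualitative dynamics are insensitive to this scale |
| `heparinase_max`, `flux_prob`, `flux_magnitude` | 1, 0.2, 0.1 | the per-patch level is a clamped symmetric random walk: "removed and replenished continuously" with a homeostatic (uniform) long-run distribution |
| `cleaved_fate` | `degrade` | a closed system with recycling never loses factors, which cannot produce the observed decay of the LA and MA curves after their peaks; recycling is retained as an option |
| `n_steps` | 500 | long enough for the default wound-healing run to reach its HA-dominated quasi-steady state |
| `n_replicates` | 10 | the replicate count used for the published averaged curves |

All of these are plain config fields (`simulation_config()`, or flat keys
in a YAML/JSON file for `load_config()`), so every scenario can also be run
under user-chosen values.

## Scenarios

`wound_healing` is the baseline: one-shot release, zero inflow. The tumor
presets add per-step inflow on top of the same initial release:

```{r}
list_scenarios()
```

The triples are the published experiment set (panels B–F plus the
supplementary 5LA/1MA/2HA variant); arbitrary custom triples are accepted
through `inflow_per_step`.

## Classifying the outcome

The published distinction between the two regimes is visual. The package
operationalizes it with two declared diagnostics computed from the averaged
bound series:

* **peak order** — the step at which each class's curve attains its maximum
  (ties broken toward the earliest step), and
* **terminal dominance** — mean bound counts over the final `tail_fraction`
  (default 0.2) of the run.

`classify_pattern()` returns `sequential_resolved` when the peaks occur in
affinity order *and* terminal HA is at least `dominance_ratio` (default 1)
times terminal LA + MA; `unresolved_stimulation` when terminal LA + MA
exceeds terminal HA; `no_signal` for identically zero series. Both
diagnostics are always reported alongside the label, because the label is
an operationalization, not a published formula; `tail_fraction` and
`dominance_ratio` are exposed so users can probe the sensitivity of the
verdict.

```{r, fig.width = 6, fig.height = 4}
wh <- run_replicates(simulation_config(n_replicates = 4, seed = 1))
plot(wh)
classify_pattern(wh)
```

In the wound-healing regime the LA curve rises and collapses first (75% of
patches sit at or above its threshold, and degraded factors are not
replaced), MA follows, and HA — cleaved only in the top quarter of the
heparinase range — accumulates and dominates the tail. Under the tumor
presets the continuous LA/MA inflow keeps reoccupying sites as they free
up, so the stimulator curves never resolve and the inhibitors' terminal
share drops.

## Verification strategy

The test suite exercises each event against an independent expectation
rather than against the simulator itself:

* **Movement**: displacement per move has unit length on the torus and
  per-axis empirical mean within 3 standard errors of zero (isotropy).
* **Binding**: 10⁴ independent co-located attempts at `attach_prob = 0.5`
  bind at a rate within 3 standard errors of 0.5.
* **Cleavage**: the set of cleaved classes at any heparinase level is
  nested (HA cleaved ⇒ MA cleaved ⇒ LA cleaved).
* **Flux**: the single-patch time average over 4 × 10⁴ steps is within 3
  batch-means standard errors of `heparinase_max/2` (the clamped symmetric
  walk's stationary mean).
* **Conservation**: at every step, occupied sites = bound factors (globally
  and per cell) and per class bound + free + cleaved = released
  (`degrade`) or bound + free = released (`recycle`).
* **Single-site Markov chain**: on a 1 × 1 lattice with one cell, one site
  and one LA factor, constant heparinase above `θ_LA`, `recycle` fate and
  `attach_prob = p`, end-of-step occupancy is a two-state chain with
  transition matrix `[[1−p, p], [1, 0]]` and stationary bound probability
  `p/(1+p)`. A 5 × 10⁴-step run must land within 3 asymptotic standard
  errors of that value. This is the check that pins the cleavage-timing
  decision above.
* **Scheduler order**: a seeded golden trajectory on a 5 × 5 lattice pins
  the six-event sequence against regressions.
* **Regimes**: 10 averaged default replicates must classify as
  `sequential_resolved` for `wound_healing` and `unresolved_stimulation`
  for presets D and E, with the terminal HA share under inflow strictly
  below the wound-healing share, and verdicts along the inflow ladder
  B → E never reverting from unresolved to resolved.

## What the synthetic conditions do and do not show

Everything here is synthetic: the model's inputs are its parameters, not
measured concentrations. Passing the regime checks shows that the
competition mechanism is *sufficient* to produce both qualitative patterns
under the stated assumptions — it does not calibrate the curves to tissue
data. In particular: absolute counts and time units are arbitrary; NaCl
elution molarity was only ever a proxy for protease activity, so the
thresholds are ordinal, not measured; vessel formation, endothelial cells,
diffusion gradients, platelet activation and pH/hypoxia effects are all
outside the model; and the within-step orderings fixed above are modeling
choices where the source is silent.

## Numerical and degenerate-input notes

* All randomness flows through R's Mersenne–Twister stream, seeded
  `seed + replicate_index` per replicate; identical configurations
  reproduce byte-identical CSV output.
* `n_cells = 0`, all-zero releases, `n_steps = 0` and a 1 × 1 lattice are
  legal and produce the obvious degenerate results (all-zero series,
  length-1 series, single-patch placement), not errors.
* `heparinase_max = 0` disables cleavage entirely: bound counts are then
  non-decreasing.
* Peak ties break toward the earliest step; the replicate summary is the
  pointwise arithmetic mean (not median).
* Binding-site counts are integers; averaged series are fractional.
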