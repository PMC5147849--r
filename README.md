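# hscompete

An agent-based model of angiogenesis regulation as **competition for
heparan-sulfate binding sites**, for systems-biology researchers studying
why normal wound healing resolves while tumor angiogenesis does not.

## The model in brief

Angiogenesis regulators act only while anchored to heparan sulfate (HS) in
the extracellular matrix, and their HS affinities are ordered: stimulators
(VEGF) bind weakest, vessel stabilizers (PDGF-B) intermediately, inhibitors
(PF-4, TSP-1) tightest. Tissue heparinase releases them in that order.

`hscompete` simulates three growth-factor classes — LA, MA, HA for
low/medium/high affinity — as motile agents on a toroidal lattice of
microenvironments (default 51 × 51 = 2601 patches). Immobile stromal cells
carry a finite pool of binding sites (per-cell counts ~ rounded
N(`site_mean`, `site_sd`²)); each patch holds a heparinase level *h* under
clamped symmetric stochastic flux on [0, `heparinase_max`]. Class *c* binds
a free co-located site with probability `attach_prob[c]` and, once bound,
is cleaved when *h* ≥ `cleave_threshold[c]`, with the strict ordering

θ(LA) < θ(MA) < θ(HA)

enforced at validation. Each step runs six events in fixed order: inflow →
movement → binding (shuffled order) → cleavage → heparinase flux → record.
A one-shot release at t = 0 models the platelet burst of wound healing;
per-step inflow of stimulators models a tumor edge. The observable is the
per-class bound count over time, averaged over replicates.

## Worked example

```r
library(hscompete)

cfg <- simulation_config(seed = 1)        # wound-healing defaults
wh  <- run_replicates(cfg)                # 10 replicates, 500 steps each
classify_pattern(wh)
#> <hs_verdict> sequential_resolved
#>   peak steps: LA=51 MA=82 HA=108
#>   terminal shares (tail 20%): LA=0.009 MA=0.256 HA=0.735
#>   terminal means: LA=1.37 MA=37.22 HA=106.84 (dominance ratio 1.00)

tum <- run_replicates(apply_scenario("E", cfg))   # + 5 LA, 1 MA per step
classify_pattern(tum)
#> <hs_verdict> unresolved_stimulation
#>   peak steps: LA=406 MA=487 HA=105
#>   terminal shares (tail 20%): LA=0.253 MA=0.393 HA=0.355
#>   terminal means: LA=67.45 MA=104.74 HA=94.58 (dominance ratio 1.00)
```

Reading the numbers: under wound healing the class peaks occur in affinity
order (steps 51 ≤ 82 ≤ 108) and the high-affinity inhibitors end up holding
73.5% of terminal occupancy — the signal resolves. With continuous
stimulator inflow (preset E) the LA and MA curves never resolve (terminal
LA + MA mean 172 vs HA 95) and the inhibitors' terminal share collapses to
35.5%: they are out-competed from the binding sites.

`plot(wh)` draws the averaged bound curves. `write_output_bundle(wh, dir)`
writes per-replicate and summary CSVs (columns `step, class, bound_count,
free_count, replicate_index`), a config echo, the verdict and a manifest —
enough to reproduce every CSV byte-for-byte.

### Command line

```sh
Rscript exec/hscompete scenarios                     # list the 7 presets
Rscript exec/hscompete run --scenario E --seed 1 --outdir out/
Rscript exec/hscompete classify --summary out/summary.csv
```

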