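---
title: "Modeling plasma-cell affinity maturation by differential division"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling plasma-cell affinity maturation by differential division}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcplasma)
```

## The problem and the model

Serum antibody affinity rises for weeks after immunization, yet export from
the germinal center (GC) into the plasma-cell (PC) pathway is known to be
*affinity-permissive*: precursors (prePCs) span the full affinity range of
the light zone (LZ). `gcplasma` implements one mechanistic resolution of
this apparent paradox: **selection into the PC compartment is permissive,
but subsequent PC clonal expansion is proportional to the amount of T
follicular helper (Tfh) help — read out as a Myc proxy — that each
precursor received in the LZ.** High-affinity precursors capture more
antigen, obtain more help at commitment, and execute more "inertial"
divisions after leaving the GC, without further T-cell input or further
somatic mutation. The PC pool therefore matures in affinity even though
entry into it does not filter on affinity.

The simulator is an agent-based, discrete-time model of a single draining
lymph node:

1. **Capture.** An LZ cell of affinity $a$ captures antigen
   $c(a) = c_\max\, a/(a+K)$ from follicular dendritic cells; the depot
   $c_\max$ holds a plateau and then decays exponentially, so the response
   wanes.
2. **Selection.** A fixed number of Tfh selection slots per step
   (`n_select`) is distributed softly: cell $i$ is selected with
   probability $\min(1,\, S\, w_i / \sum_j w_j)$ with
   $w_i = c_i^{1/\tau}$; the temperature $\tau$ controls how sharply
   capture differences convert into selection differences.
3. **Myc and division budgets.** A selected cell sets
   $\mathrm{myc} = m_0 + k\,c$ and receives a dark-zone (DZ) division
   budget $\mathrm{round}(\beta\,\mathrm{myc})$, spent one division per
   step with somatic mutation; spent cells return to the LZ.
4. **Export.** Each LZ cell exports to the prePC compartment with a fixed
   probability per step, *independent of affinity*. Export is treated as
   the precursor's final help interaction: a fresh capture reading sets its
   Myc, and its PC division budget is
   $\min(\mathrm{cap},\,\mathrm{round}(\beta\,s_{pc}\,s_{il21}\,\mathrm{myc}))$.
   PCs divide without further mutation, up to twice per 12 h step, then
   secrete.
5. **Death and serum.** PC death is a constant, affinity-independent
   hazard. Each live PC adds antibody of dissociation constant
   $k_d = k_{d0}/a$ to a cumulative serum mixture.

### Why Myc is refreshed at export

An alternative bookkeeping would carry the Myc value from the cell's *last
DZ selection* into the export budget. We model the export event itself as a
help interaction instead: prePCs are committed in the light zone while
interacting with Tfh, and their Myc reflects antigen captured at that
moment (the graded antigen-delivery design below reads out exactly this).
The stale-selection variant also fails structurally: most LZ cells are
never re-selected between acquiring an affinity-enhancing mutation and
being exported, so the affinity–division coupling that defines the model
would be one generation out of date, and the PC pool could not overtake the
GC in affinity-mutation frequency. "Inertial" here contrasts with
*post-export* signals, which remain absent: the budget is fixed at export
and spent Tfh-independently.

### Why PC expansion exceeds the DZ burst

Both compartments turn Myc into divisions, but the GC applies its
exponential weighting repeatedly (selection–burst cycles), while each
exported precursor is amplified exactly once. A PC pool whose one-time
amplification equals a single DZ burst is mathematically condemned to lag
the continuously re-selected GC frontier: it is an amplified *average of
past* LZ states competing against the *current* GC state. The package
therefore gives the post-export burst its own scale, `pc_division_scale`
(default 2.0, i.e. the PC budget is twice the DZ budget of an equally
helped cell), and lets PCs cycle faster than the 12 h step
(`pc_divisions_per_step = 2`, matching plasmablast cycle times of ~6 h).
Rapid prePC/PC expansion in GC-adjacent foci, exceeding GC expansion, is
precisely the biology the model exists to represent; with these two
choices the simulated PC pool is reliably more enriched for
affinity-enhancing mutations than the contemporaneous GC, as observed.

## Parameters that matter

| parameter | default | units / meaning |
|---|---|---|
| `step_hours` | 12 | hours per step; founders seeded on day 4 |
| `capture_cmax`, `capture_K` | 4, 2 | antigen-capture saturation |
| `antigen_plateau_steps`, `antigen_halflife_steps` | 20, 8 | depot plateau (to day 14), then decay |
| `myc_m0`, `myc_k` | 0.2, 1 | Myc proxy intercept/slope; `myc_k = 0` is the decoupled control |
| `division_beta` | 1.2 | DZ divisions per unit Myc |
| `pc_division_scale`, `pc_budget_cap` | 2.0, 10 | post-export amplification and its cap |
| `pc_export_prob` | 0.05 | per-LZ-cell export probability per step (affinity-independent) |
| `pc_death_rate` | 0.12 | per-step PC hazard (half-life ~1.7 days, short-lived plasmablasts) |
| `n_select`, `selection_temperature` | 40, 3 | Tfh slots per step; selection softness |
| `mutation_rate` | 0.15 | substitutions per chain per division |
| `site_hotspot_prob` | 0.2 | probability a heavy-chain substitution on the target V is drawn from the designated-site table |
| `mcherry_sigma` | 0.15 | lognormal label noise (initial and measurement) |

The germline pool contains five heavy V analogs; `IGHV1-72*01` is the
designated high-affinity V (baseline affinity 2 vs 0.6–1.2) and carries the
three designated affinity-enhancing replacement sites, analogs of
W33L/K59R/Y99G, with multiplicative factors 8, 2 and 2. Effect sizes are
configuration, not constants. Hotspot targeting (`site_hotspot_prob`)
stands in for the strong sequence-motif bias of somatic hypermutation:
under uniform position/residue targeting a specific replacement arises at
~5×10⁻⁴ per mutation event, and the canonical substitutions would
essentially never be observed at the population sizes simulated; in real
repertoires they recur in most animals within two weeks.

Non-designated substitutions are 30% lethal, 40% deleterious (×0.7) and 30%
neutral — chosen so clone affinity can drift both ways. The fate mix is
unconstrained by data and is exposed in the configuration.

## What the synthetic data emulate — and what they do not

Emulated: clonally related paired IgH+IgL amino-acid sequences descended
from known germlines in fixed coordinates; designated affinity-site
acquisition; GC/prePC/PC compartments; fate labels (GC- and PC-restricted
drivers); division-label dilution with lognormal noise; live/dying status;
per-cell ground-truth mutation logs; cumulative serum as a mixture of
(concentration, kd) species; sequencing depth via per-snapshot subsampling
(`snapshot_sample`).

Not emulated: nucleotide-level hypermutation and its intrinsic motif
spectrum (the simulator works in amino-acid space), insertions/deletions,
V(D)J junction diversification after founding, isotypes, spatial structure,
T-cell dynamics beyond a scalar help signal, bone-marrow homing, and
transcriptomes. Passing tests therefore demonstrate internal consistency of
the mechanism and pipeline, not quantitative agreement with any particular
mouse dataset; the printed frequencies from real experiments are not
reproducible from first principles and are treated as directions, not
targets.

Known limitation: because PC bursts are mutation-free and large, at
realistic sequencing depth the identical GC siblings of a burst are often
unsampled and many PC-heavy genotype nodes classify as PC-only. The robust
form of the node-composition observation — PCs are more concentrated in
mixed nodes than GC cells are, and mixed nodes are the largest — holds
across seeds; the stronger "most PCs in mixed nodes" holds only at full
census and in roughly half the seeds.

## Interventions

`intervention()` schedules: GC/PC fate labeling (tamoxifen analogs),
division-label shut-off (doxycycline), help termination (`ANTI_CD40L`:
selection and GC division stop at the start step; GC/prePC cells are dead
by `start + delay`, default 2 days; PCs retain and spend their budgets),
PC depletion (`TACI_IG`, hazard 1), egress blockade (`FTY720`; egress is an
optional leak, default 0, so retention is the default), and BCR-independent
antigen delivery (`DEC_OVA`, per-cell capture override consumed at that
cell's next help event; dose 0 makes targeted cells unselectable until
consumption, the delivered-antigen analog of competing without cognate
antigen).

## Numerical and statistical choices

* **Determinism.** One master seed; every run is byte-reproducible.
  Experiment presets derive child seeds per animal/arm with a fixed affine
  map kept below 2³¹.
* **Budget quantization.** Deterministic budgets round the mean; the
  Poisson mode removes quantization plateaus and is used where a smooth
  dose–response expectation matters (the graded-delivery preset).
* **Gates.** Quantile gates use outer quartiles with deterministic
  tie-breaking; an all-equal input still partitions and is flagged
  degenerate. Threshold gates recover noise-free division classes exactly.
* **Clone grouping.** Same heavy V and J, equal junction length,
  single-linkage at ≥85% junction amino-acid identity — standard repertoire
  practice. Light chains do not participate (their pairing is already
  enforced upstream).
* **Chao1.** The bias-corrected form
  $S_{obs} + f_1(f_1-1)/(2(f_2+1))$, defined when no doubletons are
  observed, computed on clone abundances by default.
* **Coupling estimator.** Least-squares slope of divisions on
  log-affinity; percentile bootstrap. On clonally structured data the
  bootstrap resamples clones, not cells — cells of a clone share affinity
  and division history, and the iid-cell bootstrap's intervals cover the
  null slope far below nominal rate (~45% observed vs 95% nominal).
* **Avidity model.** A hapten carrier of valency $n$ binds each species
  with effective $k_d/n$ and offers $n$ epitopes. Concentrations are
  normalized to composition before the occupancy computation, so the
  low/high-valency ratio is exactly invariant to serum dilution and runs
  between the analytic limits $49/784 = 0.0625$ (weak binding) and
  $7/28 = 0.25$ (saturation). The model is a monotone, bounded surrogate of
  mean affinity; no empirical ELISA value is treated as reproducible.
* **Decoupled control.** `myc_k = 0` removes the affinity–help coupling.
  The control keeps a baseline division rate (`myc_m0 = 1.5`, Poisson
  budgets): with the default intercept all budgets round to zero, nothing
  divides, and calibration gates would be degenerate.
* **Tests.** `run_test()` wraps the two-sided t (paired and unpaired),
  one-way ANOVA and Kruskal–Wallis; degenerate zero-variance paired input
  returns statistic 0, p 1 rather than NaN. No multiple-testing correction
  is applied within a preset by default.

## Problem sizes

Default runs use 30 founder clones (4 cells each), 40 selection slots, and
horizons of 16–56 twelve-hour steps (day 12 to day 32), yielding
10³–10⁴ cells per lymph node; presets subsample 300 cells per population
per snapshot, comparable to single-cell sequencing depth. Directional
claims are asserted over 20 seeded replicates (the GC-vs-PC comparison over
pooled 6-animal experiments, matching the pooled design it mirrors); the
decoupled-control calibration uses 1000 small simulated experiments of 5
animals each.

## Worked example

```{r example, eval = FALSE}
cfg <- preset_config("FIG2_DIVISION", seed = 1)
out <- run_simulation(cfg)
ann <- annotate_repertoire(pair_chains(out$repertoire)$paired)
pc <- ann[ann$c_celltype == "PC" & ann$c_live_state == "LIVE", ]
g <- gate_by_label(pc$c_mcherry)
compare_by_division(pc$c_animal, as.character(g$gate),
                    pc$v_call == "IGHV1-72*01")
```

## Open design points, resolved

* Whether PC budgets can be topped up by post-GC IL-21 or only scaled: we
  implement scale-only (`il21_scale` multiplies the budget at export);
  blockade is a scale below 1. Nothing in the package's scope
  distinguishes the two.
* prePC cells are classified with GC for node composition (the two-gate
  sorting that defines the populations does not resolve them); a switch
  (`prepc_as`) keeps them separate.
* Richness is computed on clone abundances by default; node-level mode is
  available by passing node sizes to `chao1()` directly.
* The affinity-enhancement rule defaults to *any* designated site
  (presence-based scoring); `rule = "all"` is available.
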