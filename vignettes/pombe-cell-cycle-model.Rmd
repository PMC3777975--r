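---
title: "A Boolean threshold-network model of the fission yeast cell cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Boolean threshold-network model of the fission yeast cell cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pombeBN)
```

## The model and its assumptions

`pombeBN` models the cell cycle control circuit of *Schizosaccharomyces
pombe* as a Boolean threshold network: twelve nodes with binary states,
a signed weighted interaction matrix, per-node activation thresholds, and
synchronous discrete-time updates. The deliberate assumptions are:

* **Binary activity.** Each protein or complex is ON or OFF; graded and
  intermediate activity is not represented. This is why purely graded
  alleles (temperature-sensitive mutants at semi-permissive conditions,
  weak overexpression of some targets) are declared *non-representable*
  in the strain catalog rather than encoded badly.
* **No real time.** A step is "whatever time the slowest switching event
  needs"; only the order of activation patterns is predicted, never
  durations or rates.
* **Synchronous updates.** All nodes switch together. The biological
  justification is the robustness of the circuit rather than genuine
  synchrony; the package deliberately implements no asynchronous or
  stochastic scheme (a non-goal).
* **Topology over kinetics.** All dynamical predictions derive from the
  wiring diagram, the signs of interactions, and three non-zero
  thresholds.

The node set is `Start` (the cell-size/mass trigger, an input rather than
a protein), the three start-kinase complexes `Cdc2/Cig1`, `Cdc2/Cig2`,
`Cdc2/Puc1`, the M-phase promoting factor `Cdc2/Cdc13`, its
Tyr15-dephosphorylation state `Cdc2_Tyr15` (ON = inhibitory phosphate
removed, i.e. fully activatable MPF), the antagonists `Ste9`, `Rum1`,
`Slp1`, the combined inhibitory kinase node `Wee1/Mik1`, the activating
phosphatase `Cdc25`, and the unnamed resetting phosphatase `PP`. Wee1 and
Mik1 are one node because they act as one redundant Tyr15-kinase activity
and are only ever perturbed jointly through Wee1; the three start kinases
are separate nodes so that their single and double deletions can be
simulated individually.

## The two update rules and why they agree

`build_pombe_model()` constructs either published variant.

**threshold_memory** keeps a node unchanged when its weighted input
exactly equals its threshold, and books protein turnover as inhibitory
self-loops `a_ii = -1` on the nodes that have no inhibitor among the
other nodes *and* a zero threshold: `Start`, the three start kinases, and
`PP`. Nodes whose threshold is non-zero are already offset from the
decay regime — with integer-valued input sums a threshold of −0.5, +0.5
or +1.5 can never be hit exactly, so `Cdc2/Cdc13`, `Cdc2_Tyr15` and
`Slp1` need neither a tie rule nor a decay loop. Putting a decay loop on
`Slp1` anyway would desynchronize the two variants (Slp1 would switch off
one step earlier under this rule than under the simplified one, after
which Cdc2/Cdc13 reactivates prematurely and the wild-type trajectory
never reaches G1); the package therefore exempts all finite-threshold
nodes from the loop bookkeeping, the only reading under which the two
variants produce identical dynamics.

**simplified** drops the tie branch entirely (`S' = 1` iff input exceeds
threshold, so unsupported nodes decay by default) and instead gives the
formerly non-decaying zero-threshold nodes `Rum1`, `Ste9`, `Cdc25` and
`Wee1/Mik1` a self-activating coupling `a_ii = +1`.

For a zero-threshold node the two bookkeepings are provably the same
function: with external input `e` and own state `S`, "1 if e>0, S if e=0,
0 if e<0" equals "1 iff e+S > 0" for integer `e`. The test suite verifies
the stronger, exhaustive property: the full 4096-state transition tables
of both variants are identical, for the wild type and for every
representable catalog strain.

One subtlety follows for overexpression encodings. Moderate
overexpression is defined as a threshold of −0.5 *without* a self-link.
Under the simplified variant, a node such as Rum1 carries the default
`a_ii = +1` purely as tie bookkeeping; once the threshold leaves the
integer lattice the bookkeeping is meaningless and, if kept, would
silently upgrade moderate to high overexpression (locking Rum1 ON and
turning a viable strain lethal). `apply_perturbations()` therefore clears
the default self-activation when applying `moderate_op` under the
simplified variant; `high_op` sets `a_ii = +1` under both variants. With
this rule the variant-equivalence property above extends to every
overexpression strain.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `θ(Cdc2/Cdc13)` | −0.5 | input units | constitutive synthesis: ON unless actively inhibited |
| `θ(Cdc2_Tyr15)` | +0.5 | input units | phosphorylated by default: needs net positive phosphatase input |
| `θ(Slp1)` (`slp1_threshold`) | +1.5 | input units | AND gate over Cdc2/Cdc13 and Cdc2_Tyr15; any value strictly in (1, 2) is equivalent and the constructor accepts any such value |
| op threshold | −0.5 | input units | overexpression as a constant positive drive; any value in (−1, 0) acts identically on integer inputs, −0.75 is used where a stronger printed bound (−1 < θ < −0.5) applies |
| `pyp3_weight` | 0.75 | edge weight | weak backup phosphatase acting through the Cdc25→Cdc2_Tyr15 link; the dynamics are insensitive to the exact value in (0.5, 1.0), and the test suite sweeps it |
| `max_steps` | `4·2^n` | steps | revisit is guaranteed within `2^n + 1` steps, the default is generous headroom |
| enumeration cap | 24 free nodes | — | exhaustive state spaces up to ~16.8M states; the oracle is capped at 16 |

## Time and deletion conventions

The initial condition is step 1; "reaches its fixed point at step *t*"
means `state(t+1) == state(t)` with `t` minimal. The standard initial
condition has `Start`, `Ste9`, `Rum1` and `Wee1/Mik1` ON.

A knockout clamps its node to OFF from the first update onward; the
step-1 initial vector is left untouched. This convention is not
cosmetic: it decides printed step indices. Under it, the Slp1 deletion
freezes at step 6 (at step 7 the wild type would fire Slp1, which the
clamp suppresses, so step 7 equals step 6), and the antagonist triple
knockout `Rum1Δ Ste9Δ Wee1Δ` runs `{Start,…} → {SKs} → {Cdc2/Cdc13} → …`
into a period-6 limit cycle. In that trajectory the earliest
state recurrence is step 9 repeating step 3; one step later, step 10
repeats step 4 — the pair of indices usually quoted for this mutant,
which `first_recurrence_of_step()` computes. The alternative convention
that would make (10, 4) the *earliest* recurrence — deletions taking
effect only from the second update — was rejected because it would let
the model reproduce the `Cig1Δ Cig2Δ Puc1Δ` triple mutant, which is
documented (and shipped in the catalog) as a known model failure: with
immediate clamping the start kinases never fire, Ste9/Rum1 stay ON, and
the model wrongly predicts a G1 arrest for a viable strain. Both facts —
minimal revisit (9, 3) and the quoted recurrence (10, 4) — are asserted
in the unit tests.

## Attractors, stationary states and basin accounting

`enumerate_attractors()` builds the exact successor table of the
non-clamped state space (vectorized, chunked) and identifies every
attractor and its basin. On the wild-type network it finds 13 attractors:
12 fixed points and one period-3 limit cycle, i.e. 15 distinct recurrent
**stationary states** (`n_stationary_states`), which is the natural
row-count when attractor states are tabulated one per row. The limit
cycle is a "mitosis echo" (Slp1 firing, reset, MPF reactivation) confined
to a region of state space the biological trajectory never enters.

Basins are reported over two ensembles:

* `basin_size` / `basin_percent` — all `2^f` states of the free nodes;
* `resting_basin_size` / `resting_basin_percent` — the `2^(f−1)` states
  with the trigger node (`Start`) OFF. `Start` is an externally set
  cell-size signal, not a regulatory protein, so the resting ensemble is
  the biologically meaningful space of protein initial conditions.

On the wild-type network the dominant fixed point is exactly the
biological G1 state (`Ste9`, `Rum1`, `Wee1/Mik1` ON, everything else
OFF); it holds 3220/4096 = 79% of all states and 1571/2048 = 77% of the
resting ensemble. Both numbers are computed by the test suite and the
acceptance script; the resting share is the headline figure.

`state_space_oracle()` recomputes the same report by naive per-state
simulation with no memoization and exists purely as an independent
cross-check; the suite asserts oracle equivalence on the yeast model and
on 100 seeded random threshold networks of up to 12 nodes.

## Phase labels and the viability rule

Phases are assigned per state from markers, in precedence order: `M` iff
Slp1 ON; `G2-M` iff Cdc2/Cdc13 and Cdc2_Tyr15 ON; `G2` iff Cdc2/Cdc13 ON
and Cdc2_Tyr15 OFF; `G1` iff Cdc2/Cdc13 OFF and Ste9 or Rum1 ON; `G1-S`
otherwise. Clamped nodes count as OFF.

No formal viability criterion accompanies the published per-strain
narratives, so the classifier distills one from them. A strain is
`VIABLE` iff

1. its attractor is a fixed point equal, on the surviving (non-clamped)
   nodes, to the wild-type G1 state restricted likewise, **and**
2. the trajectory visited a `G2`-labelled state before its first
   `M`-labelled state, **and**
3. it visited an `M`-labelled state at all.

Limit cycles are always `LETHAL` (periodic division without a mass
checkpoint). Condition 2 is forced by the `Wee1ts Cdc25op` strain, which
reaches a G1-like endpoint yet is lethal because mitosis fires without an
orderly G2; condition 3 by the whole-Cdk deletion (`Cdc2Δ`), which rests
in a perfectly G1-looking state it never left. Arrest-phase labels in the
concordance report are best-effort annotations; only the viable/lethal
call is compared against experiment.

## Strain encodings worth spelling out

* `Wee1ts` inside combined strains is encoded as a knockout of
  `Wee1/Mik1`: Boolean states cannot distinguish reduced from absent
  activity. Standalone graded alleles (`Wee1ts`, `Cdc25ts`, `Pyp3op`,
  `Cig2op`, `Cdc25op`, …) are catalogued with `representable = FALSE` and
  refuse to simulate.
* `Cdc2Δ` deletes every Cdc2-containing complex node (three start
  kinases, `Cdc2/Cdc13`) plus `Cdc2_Tyr15`, since Cdc2 itself is not a
  node.
* `Cdc25Δ` defaults to deleting the `Cdc25` node (the printed encoding).
  The alternative reading — reweighting `Cdc25→Cdc2_Tyr15` to 0.75 with
  everything else intact — turns out to be dynamically identical to the
  `Pyp3Δ` encoding and simulates *viable*: once `Wee1/Mik1` switches off
  at step 5, a weight of 0.75 still exceeds the +0.5 threshold. The
  supposed equivalence of the two encodings therefore does not hold in
  this model; the package keeps both options, defaults to the deletion,
  and the test suite asserts the measured behavior of each (32/32
  vs. 31/32 with only the `Cdc25Δ` row diverging).
* Known failures are first-class catalog entries: `Rum1Δ Wee1Δ` and
  `Ste9Δ Wee1Δ` (model: viable; reality: lethal through runaway division
  and shrinking cell size — a cell-size effect outside the model), and
  `Ste9Δ Rum1Δ` and `Cig1Δ Cig2Δ Puc1Δ` (casualties of the simplified
  start-kinase wiring). They are reported alongside the panel but never
  counted toward the headline concordance.

## The random-network generator

`generate_random_network()` produces seeded random threshold networks
(≤16 nodes, independent edges with configurable density, weights ±1,
thresholds and self-couplings from small sets) for property-based
testing: oracle equivalence, basin partition, convergence bounds,
serialization round-trips. It emulates the *formal class* the yeast model
lives in — nothing else: random nets have no phase semantics, no
biological initial condition, and no mutant catalog. Passing properties
on them certifies the machinery (enumeration, simulation, I/O), not any
biological claim; the biological claims are tested directly on the yeast
model against the published trajectory, landscape and panel.

## Numerical choices

* States are encoded as integers (one bit per node, declaration order)
  for enumeration and revisit detection; doubles carry the codes exactly
  up to the caps.
* The successor table is built in chunks of 2^16 states to bound memory.
* Revisit detection in `simulate_trajectory()` matches encoded states
  against the recorded prefix; the default `max_steps = 4·2^n` can never
  be the binding constraint for attractor detection.
* Ties (`Σ = θ`) arise only at zero-threshold nodes under the memory
  variant and retain the previous state; the simplified variant has no
  tie branch by construction.
* Degenerate inputs: empty node sets are rejected at construction;
  models with structural defects are buildable (so `validate_model()` can
  report them) but rejected by `read_model()`.

## Known limitations

* Endoreplication, the "cut" phenotype, cell-size thresholds and
  division speed are outside the model; strains whose lethality flows
  through these mechanisms are either captured for the wrong mechanical
  reason (fast-cycling limit cycles) or documented as failures.
* The two-variant equivalence holds for this network and its catalog
  perturbations; it is not a theorem for arbitrary user models (a
  user-supplied model with a reachable tie at a non-zero threshold will
  differ between variants).
* The enumeration caps (24 nodes exact, 16 for the oracle) are practical
  limits of exhaustive analysis, not of the formalism.
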