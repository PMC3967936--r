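---
title: "Logical epithelial modelling with epilogic: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logical epithelial modelling with epilogic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`epilogic` implements a two-level discrete modelling framework for
epithelial patterning: multi-valued logical regulatory networks inside each
cell, coupled across a cylindrical hexagonal grid by juxtacrine and
paracrine integration variables. This vignette documents the formalism, the
two bundled eggshell-patterning models, every tunable parameter with its
default and rationale, and the known limitations of the reconstruction.

## 1. The single-cell formalism

A model is a set of components, each taking integer levels `0..max`.
Input components are unregulated; every other component has one ordered
clause list. A clause is a Boolean condition over atoms `Name` (level >= 1),
`Name:k` (level >= k) and `Name=k` (level == k), combined with `&`, `|`,
`!`. The *target* of a component in a state is the target level of the
first clause whose condition holds, or 0 when none does. A state is stable
when every target equals the current level.

Dynamics follow the usual conventions of the logical-modelling field:

* **Unit steps.** A multi-valued component moves one level per update
  toward its target, never jumping. This is the convention of the standard
  logical-modelling toolchain and makes trajectories insensitive to how far
  a target overshoots.
* **Synchronous update** moves every unstable component at once. Priority
  classes split a tick into stages: earlier classes update first and later
  classes see their new values.
* **Asynchronous update** produces one successor per unstable component.
  All interleavings are explored, so the asynchronous analysis covers every
  possible relationship between reaction delays. A *slow* set of components
  may be declared (e.g. `slow = "Pnt"`): slow components update only when no
  other component is unstable, the asynchronous counterpart of a long
  synthesis delay.
* **Delays.** A component with `delay: d` (synchronous scheme only) moves
  only after its target has pointed the same way for `d` consecutive ticks;
  the counter resets when the target reverses or is reached. Delays are
  bookkeeping, not state, but they are included in the configuration hash
  used for cycle detection — otherwise a waiting component would masquerade
  as converged.

Attractors of the (finite) state transition graph are its terminal strongly
connected components: singletons are stable states, larger ones cyclic
attractors. The SCC routine is an iterative (explicit-stack) Tarjan, safe on
graphs of 10^4–10^5 nodes where recursive descent would overflow; the test
suite cross-checks it against an independent graph library. Stable-state
enumeration is an exhaustive, vectorised scan of the (restricted) state
space with a refusal cap of 10^7 states; enumeration and reporting order is
lexicographic in component declaration order, so all outputs are
reproducible without any randomness.

## 2. The epithelium

Cells sit on an `n_rows x n_cols` grid of hexagons in "odd-r" offset
coordinates (0-based; row 0 is anterior). Columns wrap — the grid is a
cylinder — rows do not, so interior cells have exactly six neighbours and
border-row cells fewer. All cells carry the same model; only input fields
and clamps differ.

Extracellular inputs are recomputed from the current configuration at the
start of every tick:

| field | meaning | default rule |
|---|---|---|
| `Br_adj` | roof contact | 1 if any distance-1 neighbour has Br >= 1 |
| `Rho_ext` | neighbour Spitz | 1 if any distance-1 neighbour has Rho >= 1; 2 only if >= 5 neighbours have Rho = 2 |
| `Aos_ext` | paracrine Aos | counts Aos-positive cells within distance 3: >= 1 gives level 1, >= 4 level 2 |

The asymmetry between the two `Rho_ext` levels is deliberate: a *single*
high-Rho neighbour must not read as a saturated Spitz source. If it does,
one fully active cell ignites its neighbours, the ignition front propagates
through the whole competence region, and the roof is erased under Aos loss
of function — none of which the biological system (or the reported
simulations) shows. With the 5-of-6 requirement, high extracellular Spitz
registers only deep inside an active domain, while level-1 Spitz still
reports any active neighbour. Both thresholds, the ranges and the Aos
counts are configurable through `integration_config()`.

After the integration fields, the derived nodes are evaluated
instantaneously per cell and held fixed for the tick: `S` (max of own Rho
and `Rho_ext`), `A` (Aos inhibition: saturating paracrine Aos alone, or own
Aos with paracrine support — own Aos alone is too weak), and `X` (the
juxtacrine signal: on in a non-roof cell touching at least one roof cell).
Then dpERK updates (signal transduction is faster than transcription), then
all remaining components; perturbation clamps and ranges are re-imposed
after every stage so that clones are airtight even against one-stage
transients.

`run_to_attractor()` iterates ticks and hashes the full configuration
(levels plus delay counters); the first repeat is the attractor — period 1
a fixed point, longer a cycle — and hitting the tick cap returns an
explicit `"undecided"`.

## 3. The bundled models

### Phenomenological fate model

Four inputs (EGF 0–2, BMP, the anterior competence flag, and roof contact
`Roof_adj`) drive three Boolean fates. Roof requires intermediate EGF
without BMP inside the competence region; operculum requires high EGF or
EGF together with BMP; floor requires the operculum condition *plus roof
contact* — the floor sits on the operculum side of the roof border. Over
all input combinations the stable fate patterns are exactly four: none,
roof, operculum, and floor (which co-activates the operculum condition).

### Mechanistic network

Inputs: Grk (0–3, graded), Dpp, the early posterior EGF and early BMP
signals, and the three extracellular fields. Internals: Mid, dpERK (0–2),
Mirr, Pnt, Rho (0–2), Aos (delay 2), Br (delay 1). The wiring follows the
published genetics: Mirr responds to any dpERK activity and is repressed by
Mid; Pnt needs high dpERK; Rho needs dpERK and Mirr and is repressed by Br;
Aos needs high dpERK and Pnt and is repressed by Mid; Br (the BrL, high-level
enhancer only) is activated by Mirr, repressed by Pnt and Dpp, and carries a
maintenance self-loop (`Br & !Pnt`) standing for protein persistence. Mid is
set by early EGF unless early BMP represses it, and then maintained — the
competence region is simply `Mid = 0`.

The dpERK activation table is the one place where published interactions
underdetermine the rule, and the free entries are set to maximise the
juxtacrine effect:

1. `X & (Grk | Rho:2) -> 2` — the juxtacrine signal drives peak activity
   wherever the cell receives any Grk or already produces high Spitz. It
   overrides Aos inhibition (the floor keeps peak dpERK after Grk
   withdrawal even while bathed in Aos).
2. `Grk:3 -> 2` — peak ligand saturates the pathway.
3. `S:2 & Mirr & !A -> 2` — high Spitz sustains peak activity in cells
   already engaged in the EGF response (Mirr-positive), unless inhibited by
   Aos. The Mirr gate means external Spitz *maintains* but does not
   *initiate* peak activity; without it a front of full EGF response creeps
   cell-by-cell through naive tissue, which neither the reported patterns
   nor the mutant series show.
4. `Grk -> 1` — sub-peak ligand gives low activity. Aos does not gate this
   clause: Aos acts by sequestering Spitz, so only the Spitz-driven clause
   is Aos-sensitive. This is what makes endogenous-level Aos
   overexpression phenotype-free in the model (its documented failure
   mode) while Aos loss still abolishes the post-extinction splitting.

Two synchronous delays: Aos (2 ticks — its expression visibly lags EGF
activity) and Br (1 tick). The Br delay is a reconstruction choice: during a
unit-step dpERK decay, Pnt (which reads the prioritised, already-updated
dpERK) falls one tick before Mirr, opening a one-tick window in which the
BrL condition holds spuriously; unfiltered, the operculum would refill with
Br after Grk extinction. A minimal one-tick delay removes the artefact and
matches the biological intuition that Br synthesis is slow. Asynchronous
analyses ignore synchronous delays — they explore all interleavings
instead.

### Wild-type geometry

The default grid is 24 rows x 40 columns, the smallest convenient size on
which all twelve input regions and a multi-cell-wide roof are realised; all
geometry parameters scale with the grid (`wildtype_params()`), and the fate
census and pattern invariants are unchanged on a 36 x 60 grid. Defaults:
Dpp on the two anterior rows plus one extra dorsal row within 6 columns of
the midline ("slightly wider at the dorsal side"); the Grk source on the
dorsal midline at row 5 with level rings of hex radius 3/5/7 (the fourth
Grk level smooths the gradient); early posterior EGF from row 5 and early
anterior BMP above row 8, so Mid occupies rows >= 8 and the competence
region ends where the roof does. The twelve realised (Grk, Dpp, Mid)
triples are numbered canonically — anterior band R1–R4, competence region
R5–R8, posterior domain R9–R12, each by decreasing Grk — which places the
Grk peak in R5, the presumptive roof in R6–R7 and the undifferentiated
lateral tissue in R8, matching every region-specific statement in the
source analyses (roof with two reachable attractors in R6/R7; subdivision
of R2/R3/R10/R11 by roof contact; the high-EGF posterior fate F7 in R9).

### Fate table and region map

The eight stable signatures over (dpERK, Mirr, Pnt, Rho, Aos, Br) are shipped
in `inst/extdata/fate_table.tsv` and named F1–F8 to satisfy the textual
constraints: F1 all-zero (undifferentiated/main body), F2 the quiescent
Br-only roof, F5 the other Br-positive fate (with ongoing low EGF activity),
F6 the anterior-band state (Mirr and low Rho, Br repressed by Dpp rather
than Pnt, occurring only where neither Grk nor extracellular Spitz reaches
the high-dpERK threshold), F7 the posterior high-EGF state (Mid blocks Mirr
and Aos), F3/F4 its low-activity counterparts, and F8 the full EGF response
(operculum and floor). The table is data, not code: `classify_fates()` and
`classify_pattern()` take any compatible table.

## 4. Analyses and their problem sizes

* `enumerate_input_fates()` builds the full asynchronous state transition
  graph (144 internal states) for each of the 288 input combinations of the
  single-cell model and collects attractors — about a second in total.
* `region_reachability()` reads the realised inputs off an epithelial
  attractor, groups cells into regions and input sub-combinations, and runs
  the reachability analysis from the naive state (before extinction) or
  from each cell's previous fate with Grk zeroed (after extinction). A
  region counts as *single-fate* when every realised sub-combination admits
  exactly one reachable attractor; before extinction ten of the twelve
  regions do, the exceptions being the roof regions R6 and R7, where the
  naive cell races between Br establishment (fates F2/F5) and the
  full-response fate F8. Declaring Pnt slow resolves the race in favour of
  Br and removes F8.
* Scenario runs on the default grid take a handful of ticks per phase; the
  full wild-type plus mutant/clone suite completes in well under a minute.

## 5. What the generator emulates — and what it does not

The input generator reproduces the *logical* geometry of the system: a
graded dorsal ligand with four levels, a sharp anterior band slightly wider
dorsally, a posterior competence boundary, and the early fields that set it.
It does not model ligand diffusion, absolute concentrations, cell size
heterogeneity, proliferation or movement (cells are static), eggshell
curvature beyond the cylinder topology, or measurement noise — passing
tests therefore certify the discrete patterning logic, not quantitative
agreement with imaging data. The hexagonal lattice is also not exactly
mirror-symmetric about a column (odd rows are offset by half a cell), so
pattern symmetry is asserted as a high overlap fraction of the mirrored
roof rather than cell-perfect equality.

## 6. Known limitations

* **Cyclic-attractor census.** The reconstruction yields exactly the eight
  reported stable fates with the expected signatures, but two distinct
  cyclic attractors instead of the reported three (both at
  `Aos_ext = 1, Rho_ext = 2`, with and without Br participation, split by
  Dpp). A scan of over a hundred rule variants compatible with the
  published interaction statements produced 1, 2 or 4 distinct cycles,
  never 3, without breaking the stable census; the exact published dpERK
  table would be needed to recover the third. The corresponding acceptance
  assertion is left failing rather than weakened.
* **Rho gain of function** (level confined to 1–2) reaches a fixed point in
  both phases here, whereas the source describes a pre-extinction cyclic
  attractor explicitly attributed to the synchronous flip-flop of Br and
  Pnt — an artefact its authors disown. The Br delay that protects the
  wild-type pattern from exactly that flip-flop also removes the artefact;
  the assertion on the reported behaviour is likewise left failing.
* **X loss of function** eliminates the post-extinction floor (as
  reported) but does not shrink the Br domain; in this reconstruction the
  roof's outer limit is set by the Grk range alone.
* The **grk-overexpression** preset uses a saturating (level 3) field; a
  merely cumulative field leaves a ventral ring of intermediate Grk that
  produces an ectopic Br ring instead of the reported complete Br loss.
  Consequently the "small central Br band" of the combined
  dpp/grk-overexpression panel is not reproduced.
* Low-level Br (the BrE enhancer) and a second, stronger Aos level are
  deliberately absent, preserving the documented failure of
  endogenous-level Aos overexpression to produce any phenotype.
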