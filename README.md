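# epilogic

Multi-valued logical models of gene regulation on epithelial hexagonal grids,
with two bundled models of *Drosophila* eggshell patterning.

## The problem

The dorsal appendages of the *Drosophila* eggshell arise from two
*broad*-expressing cell groups (the appendage **roof**) bordered by a
single-cell-wide *rhomboid*-expressing seam (the **floor**) in the follicular
epithelium, next to the anterior **operculum**. The pattern is set by two
signalling inputs — a graded dorsal EGF signal (Gurken) and an anterior BMP
signal (Dpp) — acting inside an anterior competence region whose posterior
limit is marked by the transcription factor Midline. How a one-cell-wide
floor is carved out exactly along the roof border is not explained by the
diffusible inputs alone; the models bundled here implement the hypothesis
that the roof sends an instructive **juxtacrine** signal (called X) to its
immediate non-roof neighbours, locally amplifying EGF pathway activity.

`epilogic` is a general engine for this class of models plus the two bundled
networks:

* **Single cells** carry a multi-valued logical (Thomas) network: each
  component takes a small number of discrete levels and an ordered clause
  list (`condition -> target level`, first match wins, default 0) gives its
  target; unstable components move one level per update toward their target.
  Updating is synchronous (with priority classes and per-component delays)
  or asynchronous (one successor per unstable component).
* **The epithelium** is a cellular automaton of identical cells on a
  cylindrical hexagonal grid (columns wrap; anterior/posterior rows do not).
  Extracellular inputs are integrated from neighbourhoods — `Br_adj`
  (juxtacrine, distance 1), `Rho_ext` (short-range Spitz), `Aos_ext`
  (long-range, distance 3) — and instantaneous integration nodes S, A, X
  combine them with the cell's own levels. Each tick updates the
  integration variables first, then dpERK (signalling is faster than gene
  expression), then all remaining components, re-imposing any perturbation
  clamps after every stage.
* **Analyses**: exhaustive stable-state enumeration, state transition
  graphs, attractor identification (fixed points and terminal strongly
  connected components, via an iterative Tarjan SCC), asynchronous
  reachability, fate classification against the F1–F8 fate table, and an
  in-silico mutant/clone scenario library (whole-tissue and clonal loss/gain
  of function, early-versus-late BMP disruption, dpp/grk overexpression).

## A worked example

```r
library(epilogic)

res <- run_scenario("WT")          # phase 0: anterior specification;
                                   # phase 1: Grk/Dpp; phase 2: Grk extinction
res$pre$outcome                    # "fixed_point"  (after 9 ticks)
res$post$outcome                   # "fixed_point"  (after 5 ticks)

cls <- classify_pattern(res$post$epi)
table(cls$fates)
#>  F1  F2  F8
#> 902  40  18
cls$summary$n_roof_patches         # 2   (mirror patches either side of the midline)
cls$summary$n_floor_cells          # 18  (single-cell-wide, all touching the roof)

cen <- enumerate_input_fates(mechanistic_single_cell(), table = fate_table())
cen$n_stable                       # 8 distinct stable cell fates (F1..F8)
```

The final wild-type configuration shows the two Br-positive roof patches
(fate F2), each framed along the dorsal midline and to the anterior by a
one-cell line of high-Rho floor cells (fate F8), with the operculum interior
having returned to the undifferentiated state after Grk extinction — the
hallmark "splitting" of the EGF activity pattern. `preset_names()` lists the
mutant and clone scenarios; `run_scenario("Aos_LOF")`,
`run_scenario("clone_Br_LOF")`, etc. rerun the full phase schedule under the
corresponding perturbation.

A thin command-line wrapper is installed under `exec/epilogic`
(`simulate`, `stable-states`, `enumerate-fates`, `reachability`,
`classify`, `fixtures`, `validate`).

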