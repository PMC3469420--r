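---
title: "A multiscale model of sprouting angiogenesis during fracture healing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiscale model of sprouting angiogenesis during fracture healing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angiocallus)
```

## The model

Bone fracture healing depends on the growth of a new blood-vessel network in
the callus. `angiocallus` simulates this as a deterministic hybrid model
with three coupled scales:

1. **Intracellular** — each endothelial cell (EC) carries VEGFR-2 (`V`),
   Notch1 (`N`, constant), Dll4 (`D`), active and effective-active receptor
   levels (`V'`, `N'`, `V''`, `N''`) and a polymerised-actin level (`A`)
   standing in for filopodia. Dll4–Notch1 lateral inhibition between
   junction-adjacent ECs decides which cells become migratory *tip* cells
   and which stay *stalk* cells.
2. **Cellular** — the vessel network lives on a 25 µm lattice (one EC per
   occupied cell, vessels one cell wide) but tip cells migrate lattice-free,
   guided by chemotactic (VEGF) and haptotactic (matrix) gradients, with
   sprouting and anastomosis rules.
3. **Tissue** — eleven continuum fields (four cell densities, three matrix
   densities, three growth factors, oxygen) evolve by
   taxis–diffusion–reaction PDEs on the callus geometry; vessels source
   oxygen, hypoxic chondrocytes source VEGF, closing the feedback loop.

### Intracellular update maps

All intracellular rules are discrete-time maps advanced once per inner step
and applied *synchronously*: every cell reads the previous step's committed
state of its neighbours (Jacobi update). The model gives no update order
between cells; a sequential sweep would make results depend on the cell
enumeration order, which a deterministic model must not.

- **Activation.** `V' = min(V, V_sink · g_v · V / M_tot)` with
  `V_sink = 0.275` (the VEGF fraction left over by VEGFR-1 decoy receptors)
  and `M_tot = 1500` membrane agents. This transcription was chosen because
  (i) it satisfies the stated bound `0 ≤ V' ≤ V` and is monotone in both
  `g_v` and `V`, and (ii) with the published constants it puts `V'` at the
  migration/actin threshold `V'* = 200` at `g_v ≈ 9.5` ng/ml — which
  recovers, mechanistically, the 10 ng/ml VEGF threshold that the legacy
  phenomenological sprouting rule uses explicitly. We regard this
  coincidence as strong evidence for the transcription.
- **Notch activation.** Each EC distributes its Dll4 uniformly across its
  cell–cell junctions (4-neighbour adjacency); a cell binds the sum of the
  shares presented to it, clamped at `N = 25000`. The amounts actually
  bound are removed from the presenting cells' Dll4 (proportionally when
  the clamp is active), so ligand is conserved at junctions. Dll4 facing
  matrix (non-EC neighbours) is not presented.
- **Delays.** `V''(t) = V'(t − 3 δt)` and likewise for `N''`: a
  three-inner-step translocation delay, implemented as per-cell ring
  buffers, zero-initialised for fresh cells. Because `δt` adapts slightly
  with the outer interval, the delays are fixed in *steps*, not absolute
  time.
- **Dll4 expression.** `D ← clamp(D + δ·V'' − consumed, 0, D_max)` with
  `δ = 6.32`. The production term is un-normalised (no `/M_tot`): the
  published `σ`, `δ` values are the 10 µm-agent calibration multiplied by
  3.16, and only with the un-normalised form do `σ·N''` and `δ·V''` span
  the ranges the clamps imply (a `/M_tot`-normalised receptor
  down-regulation could never move `V` by more than 790 of the
  112 500-count dynamic range, contradicting the stated clamping at
  `V_min`).
- **Receptor expression.** `V ← clamp(V_max − σ·N'', V_min, V_max)` with
  `σ = 47.4`; memoryless, so `V` is continuously in equilibrium with `N''`
  and returns to `V_max` wherever Notch signalling ceases.
- **Actin.** While `V' > V'*` the cell extends filopodia (`A` += 50 up to
  `A_max = 5000`, idle counter reset). After three consecutive idle steps
  the filopodia retract (`A` −= 500, floored at 0) and the counter
  restarts, so retraction recurs once per idle run — our reading of the
  "fails to extend for a time `D_3`" rule.

### Vascular rules

- **Tip criterion.** Standard mode: `V > V_max/2` **and** `A > A* = 3500`,
  strict inequalities (matching the published wording). A variant mode
  tests `V'` against a configurable threshold (default `V'*`; the
  original's value for this variant is unpublished, so it is a knob, not a
  guess). A legacy phenomenological mode reproduces the older
  comparison rules: local VEGF ≥ 10 ng/ml, ≥ 100 µm from any tip, sprout
  direction > 24° off the mother-vessel axis (refractory period exposed but
  disabled by default, as in the newer model).
- **Speed.** Zero at or below `V'*`, then a C1 Hermite-smoothstep cubic
  rising to the 35 µm/day cap. The saturation knot is not printed in the
  source material; the package default (`vp_sat = 400 = 2·V'*`, full speed
  by `g_v ≈ 19` ng/ml at `V = V_max`) reproduces the
  roughly-one-cell-per-day front advance the model describes. With the
  maximal outer step of 8.57 h a tip can never cross more than one 25 µm
  cell per outer step, which is what justifies freezing the vasculature
  during the tissue solve.
- **Direction.** Normalised weighted sum of the unit VEGF-gradient and
  unit matrix-gradient cues, interpolated bilinearly at the tip's
  continuous position; a degenerate (zero) cue retains the previous
  direction.
- **Movement.** Explicit Euler, lattice-free. Crossing into an unoccupied
  active cell moves the tip there and leaves a *fresh* stalk EC (initial
  intracellular state — no inheritance rule is published) in the vacated
  cell. Movement into an occupied cell is refused; if the occupant belongs
  to a foreign branch this is an anastomosis: the tip loses its phenotype
  and the two branches merge, so continued contact of the now-joined
  network is not recounted.
- **Sprouting.** Every non-tip EC passing the criterion becomes a tip in
  the same inner step (no cap — the inhibition dynamics, not an arbitrary
  limit, set the density). Its initial heading is perpendicular to the
  mother vessel's local axis (estimated from occupied 4-neighbours; ties
  break to the x-axis), taking the perpendicular sense with the larger
  interpolated VEGF (exact ties break to the lexicographically smaller
  direction). Isolated seed cells have no mother vessel and head along the
  combined taxis cue.

### Tissue model

The eleven fields follow the general taxis–diffusion–reaction structure:
migrating cell types (mesenchymal stem cells, fibroblasts) diffuse and
drift up growth-factor and matrix gradients; all other fields react and
(for growth factors and oxygen) diffuse. Matrix production saturates,
chondrogenesis is hypoxia-favoured, osteogenesis oxygen-requiring,
endochondral replacement of cartilage needs both cartilage and oxygen, and
the angiogenic factor is produced dominantly by hypoxic chondrocytes
(`Ggvc`). Vessel-occupied cells source oxygen at **half** a reference
rate — the model lineage's correction for the denser plexus that lateral
inhibition produces.

**Provenance.** The complete original equation set and parameter tables
live in a supplement that was not available to this package. The reaction
forms and coefficients implemented here are therefore a *documented
synthetic reconstruction* in the style of the cited bioregulatory lineage,
shipped as a single human-readable file
(`inst/extdata/tissue_parameters.tsv`, marked synthetic) so every value can
be reviewed and replaced line by line. The package's quantitative claims
are correspondingly structural (conservation, nonnegativity, source
structure, trends), not numerical reproductions of the original tissue
curves.

**Discretisation.** Finite volumes on the 25 µm grid: symmetric
zero-row-sum diffusion stencils (exactly conservative, no-flux by default)
and first-order upwind taxis fluxes in flux form (conservative and
monotone; the limiter choice is ours — the contract is conservation plus
nonnegativity). Time integration is IMEX: reactions and taxis advance
explicitly with a positivity-limited substep, diffusion implicitly
(backward Euler, sparse Cholesky with one iterative-refinement step and
mass-restoring clipping of roundoff negatives, keeping discrete mass
balance at machine precision). Boundary releases (progenitor cells at the
periosteal/marrow borders, osteogenic factor at the cortex interface,
chondrogenic factor at the degrading bone ends) are held values over
configurable time windows. The original's stiff Rosenbrock–Krylov solver
is deliberately replaced; the acceptance criterion is step-halving
consistency (differences contract and fall below 2% of the field scale at
`tissue_dt_max = 0.0025` day), not solver identity.

### Scheduler

Each outer step advances the tissue by at most `row = 8.57 h` with the
vasculature frozen, then runs the inner loop against the *frozen*
post-step fields: (1) retire ineligible tips, (2) move tips, (3) sprout,
(4) update every EC's intracellular state — in exactly that order, which
the public interface does not allow permuting. The inner step divides the
outer interval into the smallest number of equal steps not exceeding
`ee = 1.2 h`; "how many maximal steps fit" is ambiguous between floor and
ceiling, and we use the ceiling so that `δt ≤ ee` always holds — `ee` is
defined as a *maximal* step. Outer boundaries are the union of absolute
multiples of `row` and integer days, so a run resumed from a daily
checkpoint (which captures delay buffers and inactivity counters) is
bit-identical to an uninterrupted run.

## Geometry and the synthetic data world

The bundled callus is a stylised 2.5 mm × 2.5 mm rasterisation (25 µm
cells) of a week-3 fracture callus: a cortical band with a fracture gap,
periosteal and endosteal lobes and the intercortical region, each
labelled. The true outline exists only as a figure, so region-fraction
outputs depend on this rasterisation — a documented artifact. Initial EC
seeds line the cortex surfaces, spaced so the seeded occupancy fraction
matches the 0.63% density that fully stalled scenarios report (that value
is the no-growth reference, so it pins the seed count). The callus starts
as granulation tissue only (`m_f = 10` mg/ml), everything else zero.

Reduced fixtures exist for speed: all-callus rectangles with seed columns
and boundary releases (cells and osteogenic factor on the left,
chondrogenic factor on the right), rows/rings of 2–10 ECs under static
VEGF, and static-field domains with linear or mid-peaked VEGF profiles.
The non-uniform profiles floor at half their peak so that seed cells sit
inside the activation window. These fixtures emulate the *mechanisms*
(patterning, chemotaxis, sprouting geometry, anastomosis, arrest) — not
the full callus energetics, geometry or time course. A green test on a
fixture therefore establishes a mechanism, never a published density
value.

## Emergent behaviour the tests pin down

- **Salt-and-pepper patterning.** A 10-cell *line* under uniform 20 ng/ml
  VEGF settles to an alternating pattern (the ends break the symmetry) in
  which no two adjacent cells are tip-eligible. A perfectly symmetric
  *ring* cannot break symmetry in a deterministic model (two identically
  initialised cells stay identical forever) and instead settles to the
  all-inhibited
  state, where the adjacency assertion holds vacuously. In the full model
  the symmetry is always broken spatially, by gradients.
- **Dll4 under-expression.** Halving `δ` weakens inhibition: the ring that
  arrests completely at standard `δ` stays fully tip-eligible at 50%,
  reproducing the heterozygous-knockout trend; raising `σ` never increases
  the eligible count.
- **High-VEGF arrest.** Above roughly 27 ng/ml the mutual inhibition
  drives every cell's receptors (or its activation) below threshold and
  network growth ceases — the mechanism behind the non-union prediction at
  strong VEGF addition. Blocking VEGFR-2 (`V' = 0`) freezes the network at
  its seed layout because actin production stops.
- **Gradient dependence.** Sustained front advance needs a per-cell VEGF
  gradient of a few percent inside a window of roughly 15–27 ng/ml: the
  front cell of a pair then keeps `V > V_max/2` and `V' > V'*` while its
  follower is inhibited. Symmetric flat-VEGF pairs deadlock — both
  settle mid-range with activation just under threshold.

## Numerical choices and degenerate cases

- `tissue_dt_max = 0.02` day default; the positivity limiter shortens
  substeps so the explicit stage can never undershoot zero.
- Strict (`>`) threshold inequalities everywhere in the tip criterion.
- Zero-gradient cues retain the previous tip direction; a tip at the
  callus border stalls (clamped) rather than leaving the domain.
- Tie-breaks (sprout axis, perpendicular sense, matrix classification) are
  all deterministic and documented at their definition sites.
- Classification threshold for tissue fractions: 5 mg/ml on each matrix
  density, dominant type wins.
- The realized inner step is reported per outer step
  (`state$realized_dt`) as a diagnostic; the scheduler does not target any
  particular average.

## Limitations

No vascular remodelling or pruning (occupancy never decreases), no bone
remodelling, no Notch-mediated quiescence (receptor levels at the quiet
back of the network return to maximum by construction), no membrane-level
cell shape or polarity, no matrix-bound VEGF isoforms, no mechanics, no
blood flow, strictly 2-D. The continuum parameter set is a reconstruction
(see above): region-wise tissue-fraction *values* from this package are
not comparable to the original publication's curves, although their
structural behaviour (fibrous → cartilage → bone succession, vascular
dependence) is.

## Worked example

```{r example, eval = FALSE}
library(angiocallus)

# lateral inhibition on a 10-cell line under uniform VEGF
fix <- run_cell_row(make_cell_row(10, "line", gv = 20), 600)
eligible <- evaluate_tip_criterion(fix$st$V, fix$st$Vp, fix$st$A, "V")
paste(ifelse(eligible, "T", "."), collapse = "")
#> "T.T....T.T"

# a three-week reduced-domain healing run
sim <- run_simulation(list(nx = 20, ny = 20, end_days = 21))
sim
#> <ac_sim> 22 summary rows to day 21
#>   final: 5.00% vascular, 20 ECs (0 tips), mean V = 69996
```
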