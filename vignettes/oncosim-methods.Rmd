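---
title: "oncosim: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{oncosim: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncosim)
```

# The model

`oncosim` simulates the growth of a solid tumor from a single cancerous
cell, its starvation-driven signalling, and the sprouting angiogenesis that
signalling recruits, on a shared 3D lattice.  It is a hybrid
discrete–continuum model:

* **Agents** (tumor cells and endothelial cells) are discrete, occupy one
  voxel each, and carry their behavior as a live configuration of a
  hierarchical statechart;
* **Molecules** (oxygen and VEGF) are continuum concentration fields on the
  same lattice, evolved by explicit finite-difference reaction–diffusion.

All quantities are in *relative units*: concentrations, rates and times are
calibrated against each other, not against laboratory units.  The lattice
spacing is one cell diameter, the time step is one agent "tick".

## Tumor cells

Each tumor cell senses its local oxygen concentration `o2` and the number
of free face-neighbor voxels, and runs its statechart once per step.  Two
oxygen thresholds split the live behavior into three modes:

* `o2 >= T_div` with a free neighbor: **proliferating** — a cycle counter
  advances, and every `n_cyc` proliferating steps the cell divides into a
  uniformly chosen free face-neighbor voxel;
* `T_hyp <= o2 < T_div`, or no free neighbor: **quiescent** — alive,
  consuming, cycle frozen;
* `o2 < T_hyp`: **hypoxic** — the cell secretes `s_V` VEGF per step and a
  hypoxia counter advances; oxygen recovery above `T_hyp` resets it;
* after `n_nec` *consecutive* hypoxic steps the cell becomes **necrotic**:
  irreversibly dead, inert, but still occupying its voxel.

The two-threshold layering (proliferating rim, quiescent band, hypoxic then
necrotic core) is the minimal structure that produces the classic avascular
layering — a necrotic core forming in the inner tumor while the rim stays
alive.  Making necrosis require sustained hypoxia, with recovery possible
before the deadline, is what creates a genuine *turning point*: a cell
population caught between starvation and a slowly approaching oxygen supply
can tip either way.

Tumor cells do not migrate and are never removed from the lattice; dead
cells persist as an obstacle (and as the visible core).

## Oxygen and VEGF fields

Both fields evolve by an explicit forward-Euler step of

    dC/dt = D * Laplacian(C) - k_decay * C + sources - sinks

with a 6-point stencil and zero-flux (reflecting) boundaries, then
multiplicative decay `C <- C * (1 - k_decay * dt)`.  The scheme is stable
and positivity-preserving for `D * dt / h^2 <= 1/6`, which
`validate_config()` enforces at load time.  With zero decay the stencil
conserves total mass to floating-point rounding — the acceptance suite
checks 1e-9 relative over 1,000 steps, and exact 48-fold cubic symmetry of
a centered point source.

Molecules are continuum fields rather than particles because the displayed
quantities (radial profiles via `radial_profile()`, coarse cube totals via
`cube_histogram()`) are density summaries; individual molecules are never
needed by the model dynamics.

## Endothelial cells and vessels

The initial condition places a parent vessel — a chain of inactive stalk
endothelial cells — along one edge of the grid.  Tumor-secreted VEGF
diffuses outward; when the concentration at a parent-vessel cell reaches
`T_V`, that cell activates and spawns a migrating *tip* cell, starting a
sprout.  Tips perform a biased random walk: each step, with probability
`p_move`, the tip moves to the free face-neighbor voxel with the highest
VEGF (ties break to the lowest voxel index), or, with probability
`epsilon`, to a uniformly random free neighbor.  Every move leaves a new
stalk cell in the vacated voxel, spliced into the predecessor chain — this
is elongation, and the `pred` links are exactly what a viewer uses to
render chains of unit spheres as a connected tube.

A tip branches with probability `min(1, beta * V_local)` per step, spawning
a second tip sideways (never into its own next-move direction).  Branching
proportional to local VEGF is the simplest rule under which branch events
concentrate near the tumor — the enrichment the acceptance suite measures —
rather than being hard-coded to happen there.

Every endothelial cell, stalk or tip, root or sprout, deposits `s_O2`
oxygen per step at its voxel from birth (the model has no maturation or
lumen formation; see Limitations).  There is no anastomosis and no vessel
regression, so the network is a growing forest rooted in the parent vessel.

## The statechart engine

Agent behavior is executed by a small generic statechart engine
(`sc_chart()`, `enter_initial()`, `dispatch()`):

* hierarchy (compound states with a default `initial` child) and
  concurrency (orthogonal states whose compound regions are all active
  simultaneously);
* run-to-completion dispatch: one event is processed at a time; all
  maximal, non-conflicting enabled transitions fire, at most one per
  orthogonal region;
* conflicts resolve **inner-first** (a transition whose source lies deeper
  beats an ancestor's), matching the semantics family of the commercial
  statechart tools this style of modeling grew up in; ties among
  equally-deep candidates go to the lexicographically smallest transition
  id, so dispatch is fully deterministic;
* exit and entry sets follow least-common-ancestor semantics with default
  completion of every entered compound/orthogonal state.

Charts are static; validation (`validate_chart()`) returns violations as
data, and execution tables — per-transition exit scope and entry set —
are precomputed at construction, which is what keeps a million dispatches
within the acceptance-suite budget in pure R.  Timers are counters driven
by an explicit `tick` event delivered once per simulation step, never wall
clocks, so runs are exactly reproducible.  Guards and actions are *named*
hooks: the engine stores names, the embedding module supplies the
predicate functions and interprets the action tags, keeping the engine
free of domain knowledge.  History states, entry/exit actions and event
parameters are deliberately not implemented.

One semantic nuance worth knowing: the necrosis transition leaves from the
`alive` super-state, so inner-first priority lets a cell *enter* the
hypoxic leaf on the same tick its hypoxia counter first becomes lethal;
necrosis then fires on the next tick.  In practice (with `n_nec >= 2`) a
cell dies exactly on its `n_nec`-th consecutive hypoxic tick.

## The simulation step

`sim_step()` advances the coupled system in a fixed phase order: (1) vessel
perfusion; (2) tumor metabolism (consumption and hypoxic secretion);
(3) one diffusion/decay step for both fields; (4) agent ticks — tumor
cells in ascending id order, then endothelial activation, then each tip
(ascending id) moves and then possibly branches; (5) queued divisions in
ascending mother id; (6) bookkeeping.  A single global Mersenne-Twister
stream, seeded once from the configuration and snapshotted inside the
state, is consumed in exactly this documented order; identical
configuration and seed give byte-identical metrics tables and recordings.
The RNG draw discipline is part of the contract: the move draw precedes
the exploration draw, which is made only if the tip actually moves and has
a free neighbor; disabled branching consumes no draws at all.

# Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `dims` | 40³ (no-angio), 34³ (vascular presets) | lattice size, voxels |
| `dt` | 1 | time step |
| `baseline_o2` | 1.0 | initial uniform oxygen |
| `D_O2`, `D_V` | 0.15 | diffusion coefficients (λ = 0.15 ≤ 1/6) |
| `k_decay_O2` | 0.006 | ambient oxygen clearance |
| `k_decay_V` | 0.002 | VEGF clearance (range ≈ √(D/k) ≈ 8.7 voxels) |
| `T_div` | 0.30 | proliferation oxygen threshold |
| `T_hyp` | 0.08 | hypoxia oxygen threshold |
| `n_cyc` | 10 | cell-cycle length, steps |
| `n_nec` | 40 | consecutive hypoxic steps before necrosis |
| `k_O2` | 0.03 | oxygen consumption per live cell per step |
| `s_V` | 1.0 | VEGF secretion per hypoxic cell per step |
| `T_V` | 0.05 | endothelial activation threshold |
| `p_move` | 0.7 | tip move probability per step |
| `epsilon` | 0.1 | tip exploration probability |
| `beta` | 0.03 | branching coefficient (p = min(1, βV)) |
| `s_O2` | 1.0 | oxygen delivered per endothelial cell per step |

No quantitative parameter set ships with the biology this model abstracts;
the defaults above are this package's own calibration, chosen so that the
canonical qualitative behaviors emerge together on desk-scale grids:

* **No angiogenesis** (`scenario_config("no-angio")`, 40³, 500 steps): the
  ambient oxygen clearance `k_decay_O2 = 0.006` lets the colony grow for
  ≈130 steps (peaking at a few hundred cells) before consumption plus
  clearance starve first the core (necrotic core), then the rim — a
  rise-and-die-off curve in every seed.
* **VEGF dose contrast** (`low-vegf` s_V = 0.3 vs `high-vegf` s_V = 1.5):
  the VEGF range √(D_V/k_V) ≈ 8.7 voxels and `T_V = 0.05` put
  parent-vessel activation right at the edge of what low secretion can
  reach within a run, so the endothelial counts at the matched final step
  differ by one to two orders of magnitude.
* **Defective vessel growth** (`no-branch` vs `branch-control`): with
  branching on, ≈30–130 branch events wrap the tumor in a denser bush.
* **Turning point**: the shipped configuration pair
  (`inst/extdata/turning_point_*.yaml`) differs only in `s_O2`; the weak
  supply loses the race between rescue and the hypoxia deadline and the
  strong supply wins it.

During calibration the main failure modes of this coupled system were
mapped and are worth recording: with fast ambient clearance (k ≥ 0.01) the
tumor dies before its VEGF — whose travel to the vessel is
diffusion-limited, ≈ r²/6D steps for distance r — can recruit anything;
with very slow clearance (k ≤ 0.004) any established vasculature
eventually saturates the sealed (zero-flux) domain and the tumor grows
without bound in every arm.  The defaults sit between the two regimes.

# The experiments

`scenario_config()` ships the presets; `sim_run()` returns a metrics table
(counts per tumor state, endothelial and sprout counts, branch events,
tumor radius, live-cell asphericity, mean radial position of live and
necrotic cells, field totals).  The asphericity of a set of positions is
computed from the gyration-tensor eigenvalues `l1 >= l2 >= l3` as
`A = (l1 - (l2 + l3)/2) / (l1 + l2 + l3)`: 0 for an isotropic cloud, 1/4
for a planar disc, 1 for a line — the first two values are verified
against the closed forms in the test suite.

Problem sizes in the test and acceptance suites are desk-scale by design:
40³ × 500 steps for the ten no-angiogenesis seeds, 34³ × 420 steps for the
ten-seed vascularized panels, 20³ × 1,000 steps for conservation, 200
random charts × 100 event sequences for the engine-vs-oracle check.

# The wire protocol

The model side of the viewer architecture is a versioned XML schema of this
package's own design (the information content — per-step object diffs plus
scene statistics plus inbound commands — mirrors what a reactive-animation
viewer needs; no claim of wire compatibility with any other tool is made):

* one `<step t="...">` document per step, containing `create` / `update` /
  `delete` children (attribute order fixed: `id, type, x, y, z, state[,
  pred]`), optional `event` children logging parameter changes, and one
  `<stats>` element of per-type/state counts;
* inbound commands `<set>`, `<kill>`, `<create>`, `<query>`, `<pause>`,
  `<speed>`;
* recordings are newline-delimited: a `<run version seed config>` header
  line, then one step document per line (`*.ras.xml`), so files are
  seekable, diffable and streamable over any byte transport.

Encoding is byte-stable (fixed attribute order, no whitespace, `%.9g`
reals); decoding is strict — unknown elements or attributes are errors,
not warnings, so schema drift cannot pass silently.  `pause`/`speed` are
pacing hints only; replaying at any speed yields identical content.  The
`delete`-is-terminal and `create`-before-`update` ordering invariants are
enforced at encode time and re-checked during scene reconstruction.

# Numerical and design choices

* **One agent per voxel, shared occupancy.**  Tumor and endothelial cells
  compete for space in a single occupancy array; contact inhibition (no
  division without a free face-neighbor) follows directly, and vessel
  "tubes" can never overlap the tumor mass.
* **1-based voxel indices** with voxel centers at `(i - 0.5) * h`, the
  natural R convention.
* **Tie-breaks** are always "lowest voxel index" (lattice linear index) or
  "lowest transition id", never RNG, so only explicitly random choices
  consume the stream.
* **Degenerate inputs**: asphericity of fewer than two distinct points is
  an error, not a number; metrics rows report `NA` in that case.
* **Error taxonomy**: configuration problems raise
  `oncosim_config_error`, protocol problems `oncosim_decode_error`,
  command failures `oncosim_command_error` (reported as error replies on
  the command channel, never fatal), runtime invariant violations
  `oncosim_invariant_error` — the CLI maps these to exit codes 2/2/0/3.

# Limitations

* Cells neither migrate nor push; growth is purely by division into free
  voxels, so very dense vasculature can physically crowd out tumor
  regrowth.
* The defective-vessel-growth comparison (`no-branch` vs `branch-control`)
  reliably reproduces the vessel-count contrast, but its *shape* contrast
  is weak in this implementation: across seed panels the live-tumor
  asphericity difference between the arms is within noise, and the mean
  live-cell distance to the nearest vessel is systematically *smaller* in
  the branching-enabled arm — with several-fold more endothelial cells
  near the tumor, every live cell is simply closer to some vessel.  Both
  quantities are reported by the metrics and the acceptance script so the
  behavior is measurable, but an elongated "hugging" morphology that
  dominates the control's should not be expected from these movement and
  perfusion rules with a single edge-parent vessel.
* The domain is sealed (zero-flux): there is no far-field sink, so
  sustained strong perfusion raises the global oxygen level — runs are
  meant to be interpreted over the configured horizon, not asymptotically.
* One nutrient species; no blood flow, lumen, pericytes, anastomosis or
  vessel pruning; necrotic cells are never cleared.
* Relative units only: mapping to hours and micrometres is deliberately
  out of scope.
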