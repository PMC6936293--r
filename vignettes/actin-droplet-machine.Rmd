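---
title: "The actin droplet machine: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The actin droplet machine: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actomaton)
```

`actomaton` models droplet-confined actin bundle networks as excitable
media and characterizes them as computing devices. This vignette is the
package's own account of the science it implements: the model and its
assumptions, the parameters that matter, what the synthetic data
generator does and does not emulate, and the choices made where the
design was genuinely open.

## The excitable automaton

Actin filaments bundled by crowding effects form stable, long-lived 3D
networks inside droplets. The bundles conduct travelling localizations
— ionic waves, solitons, defects — and the presence or absence of such
a travelling excitation at a given site and time can carry logical
meaning. Rather than integrating a continuous reaction–diffusion or
FitzHugh–Nagumo system, the package uses a three-state cellular
automaton, a standard and much cheaper discrete tool for spatially
extended excitable media.

The substrate is the *conductive matrix* `C`: a boolean voxel grid.
Voxels outside `C` are inert — they never excite and contribute nothing
to neighbour counts. A confocal stack is converted to `C` by the strict
RGB rule `r > 40 & g > 19 & b > 19` per voxel; no deconvolution,
denoising or segmentation beyond this single threshold is attempted.

Each conductive voxel is resting, excited or refractory, and carries a
refractory counter `h`. With `σ(p)` the number of excited voxels within
Euclidean distance `r` of `p` (voxel index units), the synchronous
update is:

* resting → excited iff `σ(p) > θ` (strict);
* excited → refractory, setting `h = δ`;
* refractory stays refractory while `h > 0`, decrementing `h`;
  refractory with `h = 0` → resting.

Two consequences worth spelling out. First, a voxel excited at step `t`
is refractory for exactly `δ + 1` steps (`t+1 … t+δ+1`) and resting at
`t+δ+2`; the earliest possible re-excitation is one step after that.
This is asserted directly in the tests for `δ ∈ {0, 1, 2, 20}`. Second,
because excitation requires *strictly more* than `θ` excited
neighbours, `θ = 0` still requires one excited neighbour — there is no
spontaneous excitation, and input 0 (no stimulus) provably produces no
response. This quiescence is why two-input gates whose output is true
on `(0,0)` (nor, nand, xnor, not, constant true) are unreachable and
the mined gate vocabulary has exactly seven labels.

### Boundary and distance conventions

Positions outside the grid are treated as permanently non-conductive:
droplet networks are bounded and nothing suggests wraparound. All
distances are computed in voxel index units on the (possibly
z-compressed) grid. The physical anisotropy of confocal voxels
(0.22 × 0.22 × 4 μm by default) is carried as metadata only; the
automaton's metric deliberately ignores it, matching the voxel-based
neighbourhood definition. The z-compression of a stack is explicit and
configurable (bin width + OR reducer) with default factor 1: geometry
is never silently altered. Published electrode z-coordinates reach 23
on a 30-slice stack, which is consistent with either a raw or a mildly
compressed grid; both interpretations are expressible since compression
is user-controlled.

### Performance

The update is evaluated as a sparse adjacency–vector product over
conductive voxels only (`Matrix`), after pre-compiling the
neighbourhood structure once per (matrix, radius). A naive per-voxel
reference implementation lives in the test helpers and the test suite
asserts exact state-and-counter equality between the two on hundreds of
randomized lattices; the reference builds its neighbour lists by
brute-force pairwise distances, so the two paths share no geometry
code.

## Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `theta` (θ) | excitation threshold, strict | 7 | excited neighbours |
| `delta` (δ) | refractory delay; refractory span is δ+1 | 20 | steps |
| `radius` (r) | neighbourhood radius | 3 | voxels |
| `radius_e` (r_e) | electrode radius, strict `d < r_e` | 4 | voxels |
| `window` | coincidence window, strict `< window` | 6 | steps |
| `amp_threshold` | spike amplitude threshold | 1 | voxels |
| `steps` (T) | experiment length | 300–1000 | steps |
| `k` | electrodes / string length | 6 | — |

θ = 7 and δ = 20 are the values selected by gate-count maximization on
the laboratory network; the package defaults to them for machine
construction, and `sweep_params()` reproduces the selection analysis
(θ sweeps at fixed δ, δ sweeps at fixed θ) for any conductive matrix.
At r = 3 the neighbourhood has 122 offsets; at r_e = 4 the strict
recording sphere contains 251 voxels — both counts are asserted against
brute-force enumeration.

## Electrodes, impulses and spikes

Electrodes are spherical voxel domains used for both stimulation and
recording with the same strict criterion `d < r_e`. Three choices here
were genuinely open:

* **Impulse shape.** The duration and amplitude of an input impulse are
  not physically constrained in the model. The package applies a
  single-step impulse — all conductive voxels strictly inside the
  sphere set to excited at `t = 0` — as the simplest reading of
  "impulses generated on the electrodes"; `stim_steps` allows longer
  impulses for sensitivity studies. Refractory voxels are never
  overridden by stimulation.
* **Spike criterion.** Potentials are integer excited-voxel counts, so
  any non-zero local maximum marks a wavefront crossing the sphere.
  Detection therefore registers local maxima at or above
  `amp_threshold = 1` by default, taking the first step of a plateau
  as the spike time; both the threshold and the window are
  configurable. No baseline correction or waveform analysis is done.
* **Coincidence.** Spikes less than 6 iterations apart "happen at the
  same moment". Grouping is single-linkage on the pooled time axis
  with strict linking distance `< 6`, both within a trace (merge,
  keeping the earlier time) and across electrodes/runs. A gap of
  exactly 6 separates events. The tests pin both sides of this
  boundary and check the grouping against a transitive-closure oracle.

The ten-electrode table (two designated inputs, eight outputs) and the
six-electrode machine wiring (every electrode both input and output)
ship as CSV fixtures. The published six-electrode coordinate table
parses to eight rows; rather than guessing which rows are spurious, the
fixture ships all eight with a comment and the configuration selects
which labels form the k = 6 machine (default: the first six). Gate
mining supports both wirings explicitly (`fixed_inputs`, `all_triples`)
because the two published descriptions of the experiment disagree;
runs are cached by stimulated-electrode set so the `all_triples` sweep
costs `n + C(n,2)` simulations per parameter pair, not `3·n·(n−1)·(n−2)`.

## The finite-state machine

The machine state at a response moment is the k-bit string of
per-electrode spike presence within one coincidence group, decimal
encoded with `e0` as the most significant bit (a spike only on `e5`
encodes state 1). Successive *events* — coincidence groups of non-zero
state — define the state sequence; the machine-time index `t` counts
events, not raw automaton iterations. Raw iterations would make almost
every state the zero string, and the published transition tables (tens
of transition steps within a thousand iterations) are only consistent
with the event reading.

The weighted global graph pools transitions over all inputs:
`w(a→b) = N(a→b) / Σ_d N(a→d)`. Self-transitions are counted in the
normalization (the printed formula is garbled in the source material;
the prose definition is implemented). Outgoing weights of every
non-terminal node sum to 1 within 1e-12, a property asserted on a
thousand randomized logs. Pruning keeps one maximum-weight outgoing
edge per node, breaking ties towards the smallest successor decimal so
results are platform-independent. On the pruned graph, nodes with no
predecessors are Garden-of-Eden states; a node with no outgoing edge or
a self-edge is a fixed point (this operational definition covers the
"no successors" sense of a terminal state).

Inputs enumerated are decimals 1..63: input 0 is skipped as provably
quiescent. Richness `μ(t)` counts distinct states over all inputs at
event step `t`; `g(t)` maps each input with at least `t` events to its
`t`-th state and is the basis of Boolean reconstruction.

## Boolean minimization

Each electrode's k-ary function is read off `g(t)`: bit `e` of `g(v)`
is the output for input `v`. Inputs absent from `g(t)` become
*don't-cares* — they were never observed, and forcing them to 0 would
fabricate data; a strict mode (absent → 0) exists for users who prefer
a total function. Input 0 is always fixed to output 0 by quiescence.

Minimization is Quine–McCluskey: prime implicants by iterative cube
merging, essential primes first, then an exact branch-and-bound search
for the minimum completion of the cover. Don't-cares may be absorbed
into implicants but are never required to be covered. Among
minimum-size covers, ties break by fewest total literals, then
lexicographically on the rendered terms, so the output string is
deterministic. Every minimized DNF is verified equivalent to its source
table on all specified rows (exhaustive at k = 6, 64 assignments), and
the test suite additionally checks cover sizes against an independent
oracle that enumerates all 3^k product terms at k ≤ 4 — two fully
separate routes to the same minimum.

## The synthetic network generator

The generator emulates the geometry of regularly spaced bundle
networks in a droplet: points sampled uniformly in the grid, edges of
their 3D Delaunay triangulation rasterized as digital tubes
(point-to-segment squared distance ≤ tube_radius², integer-exact in
voxel units). Delaunay edges come from an incremental Bowyer–Watson
tetrahedralization written for this package (no installed R package
provides 3D Delaunay); it assumes points in general position, which
uniformly sampled continuous coordinates satisfy almost surely, and it
is tested for exact agreement with a brute-force empty-circumsphere
enumeration on small point sets. Two degenerate fixtures give
closed-form behaviour: an axis-aligned 1-voxel line (a wavefront
advances exactly `r` voxels per step, so arrival times are computable
by hand) and a closed ring, constructed as a digital circle in the L1
metric because that construction provably gives every loop voxel
exactly two 26-neighbours at every radius.

What the generator does *not* emulate: the anisotropic bundle thickness
distribution, branching geometry and density gradients of laboratory
networks, nor their imaging noise. Passing tests on synthetic networks
therefore validate the *machinery* — propagation, recording, gate
mining, graph extraction, minimization — not any quantitative claim
about a particular laboratory network, whose gate counts and transition
tables depend on the deposited confocal data and are out of scope here.
Confocal stacks remain first-class inputs via the TIFF/PNG readers.

## Numerical choices and degenerate inputs

* Rasterization tolerance: squared distances compared with a 1e-9
  slack to absorb floating-point noise at exact-tangency voxels.
* The Bowyer–Watson super-tetrahedron is scaled 1000× the point-cloud
  radius; insphere tests use the 4×4 determinant predicate on
  point-relative coordinates.
* Empty networks (no conductive voxels) are legal everywhere: traces
  are all-zero, spike trains empty, graphs empty, the pipeline still
  writes a complete manifest.
* Weight normalization never divides by zero: terminal nodes simply
  have no outgoing edges.
* Graph tie-breaks (pruning) and DNF term ordering are deterministic
  by construction; re-running any pipeline configuration reproduces
  byte-identical artifacts, which the tests assert via checksums.

## Problem sizes

The shipped tests and the acceptance script run a scaled-down machine:
a 64 × 64 × 8 voxel Delaunay network (40 points, tube radius 2), six
farthest-point-placed electrodes, `θ = 7`, `δ = 20`, 300 steps, all 63
non-zero inputs. These sizes were chosen so the full
characterization — simulation, spikes, graphs, richness, DNFs —
completes in a couple of minutes on one CPU while still exhibiting
non-trivial dynamics (waves crossing the droplet, collisions, and a
populated transition graph). Automaton-oracle equivalence runs on
10 × 10 × 10 lattices over a grid of `(θ, δ)` values; minimization
cross-checks run at k ≤ 4 where the exhaustive oracle is exact.

## Known limitations

* The automaton is a caricature of bundle electrophysiology: no
  continuous membrane dynamics, no attenuation, no noise. It is the
  appropriate tool for studying the *logic* implementable on a given
  geometry, not signal physics.
* Delaunay generation is O(n²)–O(n³) in points and intended for
  hundreds of points, not tens of thousands.
* Exact cover search in minimization is worst-case exponential; for
  the sparse truth tables arising from `g(t)` at k = 6 it is fast, but
  adversarial dense tables at much larger k would require a heuristic
  cover.
* The pruned graph's tie-break (smallest successor decimal) is a
  convention; analyses that depend on tie-broken edges should inspect
  the retained `count`/`weight` attributes of the full graph instead.
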