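# actomaton

Excitable-medium automata on voxelized actin bundle networks: a
simulation and analysis toolkit for *actin droplet machines* —
droplet-confined networks of actin bundles treated as unconventional
computing devices that map binary strings to binary strings.

Actin bundles self-assembled in a droplet of physiological solution form
a stable three-dimensional network that can conduct travelling
excitations (ionic waves, solitons, conformational defects). If the
network is interfaced with *k* electrodes, a binary input string can be
injected as impulses, the travelling excitations interact on the network
geometry, and the impulses recorded back at the electrodes encode a
binary output string. The device then behaves as a finite-state machine
whose transition structure is determined entirely by the network
architecture and the electrode configuration. `actomaton` implements
this machine end to end for users studying cytoskeleton computing,
collision-based logic, or excitable-medium automata in general.

## The model

The network is a **conductive matrix** `C`: a boolean voxel grid marking
where bundle material exists, obtained either by thresholding an RGB
confocal stack (voxel conductive iff `r > 40`, `g > 19`, `b > 19`) or
from synthetic generators (Delaunay tube networks, lines, rings). On `C`
runs a three-state **excitable automaton** `A = ⟨C, Q, r, h, θ, δ⟩`.
Each conductive voxel is resting (∘), excited (⋆) or refractory (∙),
with a refractory counter `h`, and all voxels update synchronously:

- a resting voxel excites iff its number of excited neighbours within
  Euclidean radius `r` is **strictly** greater than the threshold `θ`;
- an excited voxel becomes refractory with `h = δ`;
- a refractory voxel counts `h` down and returns to resting when
  `h = 0`, i.e. it is refractory for exactly `δ + 1` steps.

**Electrodes** are spheres of radius `r_e = 4` voxels. Stimulation sets
every conductive voxel strictly closer than `r_e` to excited; the
recorded potential `p_c^t` is the count of excited voxels strictly
inside the sphere. Local maxima of the potential are **spikes**
(logical True); spikes less than 6 iterations apart are coincident.
From spikes the package mines two-input Boolean gates (or, and, xor,
not-and, and-not, select), extracts the **machine states** (the k-bit
string of per-electrode spike presence, `e0` as most significant bit),
builds weighted transition graphs `G`, prunes them to the maximum-weight
graph `G*` (Garden-of-Eden / fixed-point classification, indegrees),
computes richness statistics `μ(t)`, and reconstructs each electrode's
k-ary Boolean function as a minimized disjunctive normal form
(Quine–McCluskey with exact cover selection; unobserved inputs are
don't-cares).

Defaults follow the machine-construction parameter set: `θ = 7`,
`δ = 20`, `r = 3`, `r_e = 4`, coincidence window 6, `k = 6` (hence
`2^6 = 64` machine states).

## Worked example

A scaled-down synthetic machine — a Delaunay tube network in a
48 × 48 × 8 voxel droplet, six electrodes placed by farthest-point
sampling:

```r
library(actomaton)

spec <- synth_spec("delaunay", extent = c(48, 48, 8), n_points = 25,
                   tube_radius = 2, seed = 7)
mat <- synth_network(spec)
net <- ca_network(mat, radius = 3)
net
#> <ca_network> 7792 conductive voxels on a 48 x 48 x 8 grid, r = 3

electrodes <- place_electrodes(net, k = 6, radius = 4)
params <- ca_params(theta = 7, delta = 20, radius = 3)

# stimulate with input 21 = 010101 (impulses on e1, e3, e5)
trace <- run_experiment(net, electrodes, pattern_bits(21, 6), params,
                        steps = 200)
spikes <- detect_spikes(trace)
spikes
#> <spike_train> 6 electrode(s), threshold 1, window 6
#>   e0: 9
#>   e1: -
#>   e2: 14
#>   e3: -
#>   e4: 9
#>   e5: -
states_from_spikes(spikes, k = 6)
#>   time state
#> 1    9    42
```

The three unstimulated electrodes record the passing wavefronts within
one coincidence window: the machine responds to input 21 (`010101`)
with state 42 (`101010`). Running all 63 non-zero inputs characterizes
the device as a finite-state machine:

```r
machine <- run_machine(net, electrodes, params, steps = 200, inputs = 1:63)
G     <- weighted_global_graph(machine$sequences)
Gstar <- prune_graph(G)
head(node_classes(Gstar), 3)
#>    state       class indegree
#> 54     1 fixed_point        0
#> 53     2 fixed_point        0
#> 52     3 fixed_point        0
head(richness(machine$sequences)$by_step[c("t", "mu")], 3)
#>   t mu
#> 1 1 54
#> 2 2  5
#> 3 3  1

g1 <- g_of_t(machine$sequences, 1)
dnf_to_string(minimize_dnf(table_from_g(g1, 5, 6)))
#> [1] "x2·x̄5 + x0·x̄5 + x1·x̄4·x̄5"
```

Here 54 distinct states appear at the first transition step, and the
Boolean function reconstructed at electrode `e5` says: `e5` spikes in
the first response when `e0`, `e1` or `e2` was stimulated but `e5`
itself was not — a readable signature of wave propagation from distant
electrodes into a sphere that is not refractory.

`run_pipeline()` performs all of the above and writes traces, spike
trains, state sequences, graphs (DOT/GraphML), richness tables, DNFs
and a checksummed manifest to an output directory. The same operations
are scriptable through the CLI (`inst/scripts/actomaton`) with
subcommands `synth`, `convert`, `simulate`, `gates-sweep`, `fsm`,
`minimize` and `estimate`.

Electrode coordinate tables for the laboratory-scale
1024 × 1024 × 30 network ship as fixtures
(`inst/extdata/electrodes_E1.csv`, `electrodes_E2.csv`).

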