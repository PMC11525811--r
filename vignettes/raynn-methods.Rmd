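---
title: "Ray-traced spherical neural networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ray-traced spherical neural networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raynn)
```

`raynn` implements a bio-inspired neural network in which every neuron and
glial cell occupies a physical position inside a three-dimensional sphere,
and connectivity is decided by geometry: two neurons connect only when they
have line of sight, with intervening cells acting as occluders. This
vignette describes the model, its tunable parameters, the numerical choices
made where the design was open, and what the synthetic experiments do and
do not demonstrate.

## Geometry of the network sphere

All lengths are measured in units of the cell radius `r_n` (default 1).
The network is a ball of radius `r_s`. Input neurons sit on the surface,
output neurons at the origin (all of them, co-located, so that every
input-to-output path has the same length and outputs aggregate from all
directions), and hidden neurons plus glial cells fill the interior
uniformly.

Uniformity is achieved by inverse-CDF sampling in spherical coordinates:
`r = R^(1/3) r_s`, `theta = acos(2(R - 1/2))`, `phi = 2 pi R` with
independent Uniform(0,1) variates. The radial CDF of the samples is
`(r/r_s)^3` and the expected shell population grows as
`n_T(r) = 3 N_T r^2 / r_s^3`, which `radial_density()` recovers by a
quadratic least-squares fit.

Cells may not approach each other closer than `2 r_n`. For `N_T` cells at
total density `eta_T` the probability that a newly placed cell collides
with an existing one is, in the sparse regime,

```
P_c = (32 pi / 3) eta_T r_n^3,
```

which inverts to a minimum sphere radius `r_s > (8 N_T / P_c,th)^(1/3)`
for a chosen collision budget `P_c,th` (default 1%). `populate_sphere()`
always realizes `max(requested r_s, minimum radius)`, so the collision
regime is honoured regardless of the requested geometry.

Two rates must not be confused here. When `N_T` cells are placed and then
scanned all-pairs (`detect_collisions()`, `mc_collision_curve()`), the
flagged fraction estimates `P_c` itself. During *sequential*
accept/reject placement the i-th candidate only sees the cells accepted
before it, so the realized rejection fraction approaches `P_c / 2`; the
tests assert exactly that process expectation.

Collision detection offers three algorithms with identical output:
`serial` (one cell per pass), `batch` (all pairs at once), and
`minibatch`, which bins cells on a uniform grid with bin side `2 r_n` and
processes fixed-size chunks against the 27 neighbouring bins — the only
practical choice beyond ~10^4 cells, and the engine behind the
480,000-cell characterization sweep.

### Input layouts and re-assignment

Ordered data keeps its order on the sphere surface: a grid layout spaces
sites uniformly in `cos(theta)` and `phi`, so every input neuron subtends
the same solid angle `4 pi / (N_x N_y)` and has unbiased access to the
hidden neurons beneath. One-dimensional features use the same grid
flattened row-major (`place_input_helix()`); channelled data co-locates
`C` neurons per site (`place_input_stacked()`), and a ray hitting a shared
site resolves to one co-located neuron chosen uniformly at random.

When a network grows, `grow_sphere()` rescales only the radial
coordinates (directions are preserved exactly), and the input set is
enlarged in one of two ways: *densify* inserts new surface sites between
the old ones, which keep their exact positions; *concat* compresses the
old neurons into one polar hemisphere via
`theta' = acos(2 (kappa v - 1/2))`, `0 < kappa <= 1`, vacating a polar
band for the new features. The densification index map matches each old
neuron to its nearest new-grid site for bookkeeping only — positions are
never moved, an open choice we resolved in favour of strict position
preservation because it keeps old connections geometrically valid.

## Connection formation by ray tracing

A candidate connection `i -> j` is vetoed when a third cell `k` lies
within `r_n` of the segment (boundary inclusive) and strictly between the
endpoints: `(r_k - r_i).(r_j - r_i) > 0` and
`(r_k - r_j).(r_i - r_j) > 0`. Glial cells never receive connections;
they only occlude.

* **RT-1** casts `K` random rays per neuron (default 10,000) and keeps the
  nearest intersected cell per ray: a glial hit discards the ray, a neuron
  hit creates a directed edge. Ties at identical parametric distance go to
  a random member for co-located cells and otherwise to the lowest cell
  index, a deterministic convention. Rays extend to the sphere boundary;
  the nearest-hit rule makes longer extents irrelevant.
* **RT-2** considers every ordered neuron pair and applies the occlusion
  predicate with all cells as obstacles.
* **RT-3** draws pivot cells uniformly without replacement from the cells
  not yet covered, forms the segment of all cells within `r_RT` of the
  pivot, and applies RT-2 *inside* the segment (segment members are the
  only obstacles — the complexity accounting of the method implies this
  scope, and it bounds the work per segment). Pivots are drawn until every
  neuron is covered; edge lists are pooled and deduplicated, and no edge
  can exceed `2 r_RT`. A backward traversal from the outputs then reports
  which inputs can reach every output.

One numerical detail is worth recording: in the vectorized RT-2 kernel the
squared segment length is read off the diagonal of the same Gram product
used for the betweenness test. Computing it separately (BLAS matrix
product versus `rowSums`) differs in the last ulp and can make a target
cell spuriously "block" its own segment.

### The connection-length distribution

For clusters of radius `r_m` in a medium of density `eta_T`, the length
density of RT-3 connections is

```
P(r) = K r^2 (1 - pi r_n^2 eta_T r) (r - 2 r_m)^2 (r + 4 r_m),  0 <= r <= 2 r_m,
```

with `K` normalizing the integral to 1. In the zero-density limit
`K = 3/(16 r_m^6)` and the mode sits at the positive root of
`5 r^3 - 36 r_m^2 r + 32 r_m^3`, i.e. `r ~ 1.0494 r_m`. The derivation
assumes sparse occlusion (the linear factor) and clusters fully interior
to the medium. Empirically the pooled RT-3 histogram matches the closed
form with Kolmogorov-Smirnov distance ~0.03 at `eta_T = 5e-3` even when
surface-truncated clusters are included (we measured KS 0.027 with all
clusters versus 0.030 interior-only at `r_s / r_RT ~ 11`), so the faithful
all-cluster accounting is the default and `interior_only = TRUE` remains
available. At `eta_T ~ 2e-2` and beyond the linear occlusion term is no
longer a good approximation and the closed form visibly departs from
simulation; the sweep in `mc_length_pdf()` reports the KS distance per
density so this divergence is measurable rather than assumed.

The mean out-degree falls with density only once occlusion dominates,
i.e. once `1/(pi eta_T)` is well inside the cluster diameter `2 r_RT`.
Below that regime, growing cluster occupancy outweighs blocking and the
count first rises: at `r_RT = 8` we measure mean out-degrees 12.1, 9.7,
5.2, 2.0 at densities 0.04, 0.08, 0.16, 0.3. The falling trend is
asserted over the occlusion-dominated range; full-scale sweeps with
`r_RT = 40` sit in that regime throughout.

## The sparse recurrent network

Connections map into an `N x N` sparse weighted adjacency matrix with
capacity headroom: `N` defaults to the next power of two above 1.2x the
active neuron count, so networks can grow or shrink without reallocating.
Entry `(i, j)` carries the signal *from* neuron `j` *into* neuron `i`
under the product `W Q` — the connection-table writer emits
`(source, target) = (j, i)` so files stay human-consistent. Entries are
stored in row-major coordinate order (the flattening order of the
gradient vector) and converted to a compressed-sparse product form per
forward pass. Three structural-zero regions are enforced after every
edit: rows `1..N_I` (nothing feeds an input slot — incoming values would
overwrite the injected inputs), the last `N_O` columns (outputs do not
feed back), and the diagonal unless self-loops are requested. The
forbidden output-column range is exactly the `N_O` columns backing the
output slots; weights are Xavier-uniform initialized with fans counted on
the traced structure.

Every neuron owns a five-parameter activation

```
f(x) = ln(1 + exp(A(x + B) - |C| x^2)) - ln(1 + exp(D(x - B))) + E,
```

evaluated with an overflow-safe softplus so it is finite for any finite
input (tested to |x| = 10^6). With `(A, B, C, D, E) = (1, 0, 0, -1, 0)`
it is exactly the identity; training can morph it per neuron toward
sigmoid-, tanh- or ReLU-like shapes. Untrained networks start at the
identity plus Gaussian jitter (sd 0.01), so they are near-linear — a
deliberate initialization choice: it makes the initial forward pass
well-scaled regardless of topology. The subgradient of `|C|` at `C = 0`
is taken as 0. Biases start at small normal values (sd 0.01) and are
forced to zero for input slots, whose states are overwritten anyway.

The forward pass iterates, from the all-zero state `S^0`,

```
Q^t <- S^t;  Q^t[inputs] <- X^t;  S^(t+1) <- f_UAF(W Q^t + H),
```

over `U = I_T + k` states, where `k >= 1` is the propagation delay; the
output for input step `t` is read from the output slots of `S^(t+k)`.
The default `k` is the smallest integer at or above the mean shortest
input-to-output path in the traced graph. During the final `k` flush
steps the input slots hold the last injected vector (zero-filling is
available via `flush = "zero"`); the tail behaviour is otherwise
unconstrained by the recurrence. Batches run as matrix columns through
the same recursion.

## Training

The loss is the sequence MSE `J = (1/I_T) sum_t ||Yhat^t - Y^t||^2`,
averaged over batch columns. `backprop()` is reverse-mode
backpropagation through time over all `U` steps (no truncation — desk-
scale sequences are short): gradients accumulate only at the live sparse
positions, the input-slot overwrite cuts gradient flow into the
overwritten coordinates, and bias and activation parameters ride the same
chain through the activation partials. Gradient correctness is enforced
by tests: every coordinate of `dW`, `dH`, `dC_eff` matches central finite
differences to relative error < 1e-4 on randomized small models,
including rows with `C = 0`.

The optimizer is Adam (beta1 0.9, beta2 0.999, eps 1e-8) by default, with
plain SGD available; the reference description names only gradient
descent, so the concrete choice is ours. Adam moments are indexed by the
current entry layout and reset whenever pruning changes it.

Two pruning operations shrink a network. *Probabilistic connection
deletion* scores every live entry by `|R w|` with `R ~ Uniform(0,1)` and
removes exactly `ceiling(fraction * nnz)` smallest scores (default
fraction 5%, stable tie-break by entry order): zero weights always leave
first, large weights leave with ever lower probability, and an occasional
large-weight deletion is the intended stochastic kick. *Redundant-neuron
removal* deletes neurons whose outputs were all pruned away: their
incoming rows are zeroed and their positions removed, cascading to a
fixed point. Only hidden neurons are eligible — removing an input slot
would change the model's input dimension, so disconnected inputs are
instead reported by the connectivity check. Because removed neurons fed
nothing, forward outputs are bitwise unchanged, which the tests assert.

## Transfer by growth

`grow_network()` applies a growth plan: rescale the sphere, enlarge the
input set (densify or concat), place new hidden/glial cells
collision-free against all existing cells, and ray trace again keeping
only edges that touch at least one new cell. Old weights, biases and
activation rows survive bit-exact at remapped slots (inputs keep their
slots, hidden slots shift by the input growth, old outputs keep the
leading positions of the output block so target ordering is stable).
New entries are Xavier-initialized with fan counts from the combined
structure; an `init_scale` multiplier exists so functional continuity —
grown outputs converging to the old model's as the new-weight scale
vanishes — is a testable property rather than a claim. Capacity doubles
when exceeded. `shrink_network()` runs deletion sweeps to a target
live-entry fraction and then removes redundant neurons; surviving values
are untouched.

## Synthetic localization data

No external dataset ships with the package. `synth_localization()`
emulates the semantics of Wi-Fi RSSI indoor-localization data: `P` access
points and `n` devices uniform in a square arena (default 20 m),
`RSSI = -10 gamma log10(d) + offset + N(0, sigma^2)` clipped to
`[-99, -1]` dBm, with path-loss exponent `gamma = 2.5`, offset `-30` dBm
and noise sd 2 dB — typical indoor propagation values. Access points
beyond the 14 m detection range report the `+100` sentinel (about 20-30%
of entries under the defaults). For network input, detected values map
affinely to `[-1, 1]` and sentinels to the neutral 0; targets are arena-
normalized coordinates. The generator reproduces the *format and
semantics* of such data — bounded dBm features, not-detected sentinels,
coordinate targets — but not multipath, wall attenuation, or correlated
fingerprints, so passing the pipeline tests demonstrates mechanism
(training works, transfer preserves and accelerates) rather than
real-world localization accuracy.

The transfer demonstration trains a 6-AP network (40 hidden neurons, 40
glial cells — the reference geometry at this scale), grows it to 8 APs
and 50/50 cells, and retrains, comparing against a scratch-initialized
control of the final geometry. Both are measured by epochs to reach a
fixed threshold, set at half the scratch control's initial loss; the
transfer-initialized model starts below or near the threshold and
reaches it consistently earlier (measured 1 versus 4 epochs across three
seeds).

## Problem sizes and determinism

The characterization experiments run at the following sizes, chosen so
each property is measured in the regime where it holds: the collision
sweep at the full 480,000 cells over six densities in `[1e-4, 1e-3]`
with three seeds (~90 s); the length-distribution comparison at 30,000
cells with `r_RT = 10` (the sphere-to-cluster radius ratio ~11 keeps the
closed form's interior assumption adequate); uniformity and radial-
density checks at 1.2e5 samples; gradient checks on networks of at most
12 slots and 3 input steps.

Every random draw derives a sub-stream from a master seed via a small
deterministic hash (`derive_seed()`), so adding cells in one stage never
perturbs draws in another, and any population, sweep, or training run is
bit-reproducible from its configuration and seed.

## Known limitations

* The occlusion predicate treats boundary contact (`|d| = r_n`) as
  blocking; configurations exactly on the boundary are resolved
  deterministically but are measure-zero in practice.
* RT-3's obstacle scope is segment-local; a blocker just outside the
  cluster ball of both endpoints is invisible to it. This is the
  documented epsilon-discrepancy with RT-2 and follows from the
  segment-local complexity contract.
* The analytic length distribution degrades above `eta_T ~ 2e-2`, where
  the linear occlusion approximation fails.
* Training is full-batch; mini-batch and parallel-sample semantics beyond
  plain column batching are out of scope, as are GPU execution,
  classification heads, and non-spherical network shapes.
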