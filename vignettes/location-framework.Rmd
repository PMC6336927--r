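---
title: "Location-based cortical computation with grid and displacement codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Location-based cortical computation with grid and displacement codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexgrid)
library(dplyr)
```

## The model

cortexgrid simulates a location-based account of cortical computation in
which every cortical column carries its own analog of the entorhinal
grid-cell system.  The building block is the **grid-cell module**: a
population of cells that tile 2D space with a shared periodic lattice.
Position within one lattice tile is a **phase** in $[0,1)^2$ along the
two lattice axes, and self-motion updates it by **path integration**:

$$\phi' = \left(\phi + \tfrac{1}{s}B^{-1}R(-\theta)\,m\right) \bmod 1,$$

where $m$ is the world movement, $s$ the module's lattice period
(scale), $\theta$ its orientation, and $B$ the lattice basis (identity
for a square tile; a 60° rhombus for `rhombic60`, which emulates the
triangular firing-field lattice of real grid cells).  Because the update
is linear in $m$, returning to the same physical point restores the same
phase regardless of the path taken — the defining property of path
integration.  Every invariant in the test suite (path independence,
periodicity under lattice translations, linearity) holds for any
nonsingular basis, so the lattice choice is a modeling convenience, not
a correctness assumption.

A single module is periodic and therefore ambiguous.  A **location
code** concatenates the phases of $M$ modules with different scales
and/or orientations; the joint code repeats only at the (typically
enormous) joint period.  Discretizing each module's phase into
$b_a \times b_b$ half-open bins gives the module's active cell, and the
per-module cells form a **code key** — the identity used for
associative storage.  Capacity is the product of per-module cell
counts: ten modules of twenty cells already distinguish
$20^{10} \approx 10^{13}$ locations:

```{r capacity}
ten <- suppressWarnings(
  module_set(scale = seq(1, by = 0.3, length.out = 10),
             bins_a = 5L, bins_b = 4L)
)
capacity(ten)
```

The brute-force oracle `enumerate_unique_keys()` verifies the product
structure exactly on small commensurate systems (periods 2, 3, 5 along a
30-point line give 30 distinct keys — a residue-number-system view of
the same fact), and the Chinese-remainder co-activation property: fixing
one preferred cell in each of two coprime modules leaves exactly one
co-active position per joint period.

## Displacement codes

The complement of path integration is the **displacement cell**:
per-module phase differences between two location codes,

$$\Delta = (\phi_b - \phi_a) \bmod 1,$$

with the inverse operation $\phi_b = (\phi_a + \Delta) \bmod 1$.  Within
one reference frame a displacement code is a movement vector; across
frames it is the rigid placement of one object's space in another's.  A
single displacement module is as ambiguous as a single grid module —
with period 3, "two right and one up" drives the same cell as "five
over and four up" — but the code across modules is unique to the
displacement, and between object frames it is unique to the object pair.

`decode_vector()` turns a displacement code back into a Cartesian motor
vector by explicit grid search: candidates on a grid of spacing
`grid_step` within `search_radius` are encoded and the minimum-norm
candidate matching within `tol` wins, with ties broken lexicographically
on (norm, $v_x$, $v_y$).  We chose transparent brute force over lattice
algebra deliberately: it is exactly testable at desk scale, and its
failure mode — "undecodable within radius" — is an explicit condition,
not a wrong answer.  The default `tol = grid_step / (2 * min(scale))`
is the tightest tolerance that still always admits the candidate nearest
the true vector, which bounds a successful decode's error by half a grid
step per axis.  Decoding is unique only within the modules' joint
period; beyond it, congruent candidates alias, which is the same
ambiguity the capacity analysis quantifies.

## Object models, composition, behaviors

An object model is a set of location representations unique to the
object — an **anchor** code drawn at first contact plus an associative
map from code keys to feature labels, written while an exploration trace
moves a sensor over the object.  Featureless locations (`"none"`) are
legal and common: an object's space includes places one can move to that
carry no feature.  Writing a *different* feature at an existing key is
an error rather than an overwrite, because at desk scale such a clash
almost always means a discretization collision worth noticing;
`force = TRUE` restores overwrite semantics for noisy experiments.

Composition is explicit: `add_component()` stores one displacement code
that converts parent-frame locations to child-frame locations, so a
single code places an entire learned object (and implicitly all of its
own components).  `feature_at()` resolves a location against the
object's own map first — direct observations shadow inherited ones —
then recurses through components in insertion order.  Cycles are legal
(a logo may contain a picture of the cup that bears it); the only guard
is `depth_limit` (default 5 translations), which makes resolution total
and pure.

A **behavior** is a learned change of morphology: an ordered sequence of
displacement keys through which a component's placement steps.  The
sequence memory is a variable-order suffix model: every observed suffix
of length 1..`max_order` (default 3) maps to the set of symbols that
followed it, and prediction uses the longest stored suffix of the recent
history.  This replaces the neuron-level sequence memory of related
cortical models with an exactly testable functional equivalent; the
contract — high-order, context-disambiguating prediction — is the same,
and an order-2 context already separates any behavior from its reverse
(opening vs closing) at every interior position, which the suite checks
exhaustively on alphabets up to six.  `recall_sequence()` extends a seed
only while the *full* high-order context has been seen and predicts a
unique successor.  Recall deliberately does not fall back to shorter
contexts the way `predict_next()` does: past the end of a learned
sequence only low-order fragments match, and replaying those would walk
back down the reversed sequence instead of stopping.

## Sensorimotor recognition and voting

Recognition maintains an explicit **candidate set** of (object,
location) hypotheses.  Sensing a feature activates every stored pose of
that feature across the library; each movement path-integrates every
hypothesis in its own object's frame; each sensation eliminates
hypotheses whose model predicts something else.  In `strict` mode
(default) a model predicting `"none"` at a sensed feature is eliminated
too — the right semantics when learning traces covered the object, as
the synthetic sweep traces do.  Multiple columns observing the same
object through different sensors share only their object-identity sets:
a vote intersects them and prunes every column to the consensus, with
an empty intersection flagged as disagreement rather than silently
zeroing everyone's state.

Two design choices here depart from the most literal reading of the
framework, both for exactness.  First, hypotheses are enumerated
explicitly rather than superimposed in a shared sparse code; this keeps
the candidate-set dynamics transparent and lets a brute-force oracle
(test every stored pose against the full observation history) confirm
the update rule exactly.  Second, a hypothesis starts at the *stored*
phase code recorded when its feature was learned, not at the key's bin
center.  With continuous-uniform anchors a bin-center pose sits a
sub-bin offset away from the true phase; after enough movement that
offset eventually straddles a bin edge, the predicted key diverges from
the learned one, and the true hypothesis can be eliminated without any
noise in the world.  Storing the exact code (which the learning loop has
anyway) makes noiseless elimination exact, so recognition soundness is a
theorem rather than a tendency; `pose = "bin_center"` remains available
for experiments that want the coarser variant.

## Synthetic worlds and what the experiments show

Objects are generated as distinct integer-coordinate feature points on a
10×10 canvas with labels from a finite alphabet — integer coordinates
keep every worked example exact and every oracle trivial.  The
recognition experiment's default conditions are 50 objects, 10 features
each, an alphabet of 8, learned with a full row-major sweep; columns
explore by random tours of the target's feature points, and arms with
different column counts run on identical per-trial seeds, targets and
start points, so voting is evaluated paired.  Experiment problem sizes
throughout (1000 random code pairs for the inverse-operation checks, 200
closed loops, 100 decodes, 30 recognition trials per arm, 10,000
collision trials at capacity 625 with 50 anchors) were chosen as the
smallest runs at which the binomial or worst-case error bars are far
from the asserted thresholds.

With these conditions a single sensed feature is typically present on
most objects (each object holds any given label with probability
$1-(7/8)^{10} \approx 0.74$), so consensus in literally one sensation is
rare for any column count; what voting buys is the second-sensation
collapse — the intersection of three columns' candidate sets is almost
always a singleton after one movement.  The recognition checks in the test suite therefore
assert orderings (3-column fraction-at-one $\ge$ single-column, medians
non-increasing, zero noiseless failures), not absolute speeds.

What the generator does *not* emulate bounds what passing tests show
about real perception: features are symbols with no similarity
structure; sensors translate but never rotate (orientation
representation is left out of the model entirely, so rotated-object
recognition is not claimed); phases are ideal apart from optional
Gaussian integration noise (`noise_sd`, phase units per step, default
0); and there is a single level of columns — no hierarchy, no multiple
spatial scales, no attention.

## Numerical choices

- Phases are reduced into $[0,1)$ everywhere, with the float artefact
  `x %% 1 == 1` (tiny negative `x`) mapped back to 0.
- Binning adds an edge tolerance of $10^{-9}$ before flooring, so exact
  rational phases (e.g. $4/3 \bmod 1$ times 3 bins) land in the bin
  their real value owns instead of one below.
- Key equality is exact on bins; continuous comparisons use
  `phase_distance()` (max circular distance over modules and axes) with
  a recommended tolerance of a quarter of the smallest bin width.
- All indices are 1-based, following R convention (behavior steps,
  component positions, sensation counts).
- Randomness flows through R's global RNG; every experiment function
  takes or derives an explicit seed and reports are bit-reproducible
  given (config, seed), carrying the config hash.

## Known limitations

Anchors are uniform-random per object, which is a convention — the
framework states that location sets are unique per object, not how they
are chosen.  Displacement modules reuse their grid module's bin counts;
nothing in the theory fixes a separate displacement resolution, and the
parameter is overridable.  The step cap for recognition is 50
sensations; with noiseless sensing and covering traces the cap is never
reached in practice, and hitting it is reported as `"failed"` rather
than retried.  Finally, the voting rule is plain set intersection —
richer consensus schemes (weighted, probabilistic, attention-gated) are
out of scope.
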