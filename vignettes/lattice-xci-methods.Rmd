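---
title: "Lattice-based chromosome reconstruction and XCI interpolation: methods"
author: "hiclattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lattice-based chromosome reconstruction and XCI interpolation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiclattice)
```

This vignette is the package's own account of its model, its parameter
choices, and the places where the design was genuinely open. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The polymer model

A chromosome at a given Hi-C resolution is a chain of `n` beads, one per
genomic bin, living on the integer sites of a cubic lattice of side
`s = 5n` (volume `(5n)³`). The factor 5 leaves ample free volume, so the
non-periodic boundary is essentially never felt. Two families of hard
constraints define a legal conformation, both expressed in **squared**
lattice distances:

* **bond**: consecutive beads must satisfy `d² ∈ {2, …, 10} \ {8}`;
* **excluded volume**: every other pair must satisfy `d² ≥ 2` and
  `d² ≠ 8`.

The squared-distance reading is the one used by the lattice-polymer
protocols this construction descends from (bond-fluctuation-style models);
interpreting 2–10 as plain Euclidean distances would allow absurdly loose
bonds of up to ten lattice units. The `8`-exclusion, inherited from those
protocols, removes a geometric class of bond crossings and so suppresses
knotting. Two consequences worth knowing:

* `d² = 7` is admitted by the rule but is not a sum of three squares, so
  no lattice offset realizes it — the effective bond set is
  `{2, 3, 4, 5, 6, 9, 10}`;
* the constraint set is enforced during *moves* as well as during
  initialization. Enforcing it only at growth time would let the
  excluded-volume violations the rule exists to prevent re-enter during
  the long annealing phase.

Chains are grown bead by bead: each new bead is drawn uniformly from the
sites that are bond-valid with its predecessor and excluded-volume-valid
with everything placed so far; dead ends trigger a 10-bead backtrack, and
repeated failure a restart (50 allowed). At `s = 5n` restarts are
essentially never needed.

## From contacts to target distances

Contacts convert to distances by the classic power law `δ = c^(-1/3)` and
are then normalized so the largest target equals `n√3`, the diagonal of a
cube of side `n`:

`δ' = n√3 · δ / max(δ)`.

The conversion is strictly decreasing and the normalization is a positive
scaling, so contact order is preserved and a global rescaling of the
matrix (any multiplicative normalization upstream) leaves `δ'` unchanged.
The package accepts pre-normalized matrices and deliberately does not
implement ICE/KR balancing — matrix balancing is a separate, well-served
problem.

Pairs that still have zero contacts after imputation (empty windows) are
assigned exactly the maximum distance `n√3`: zero observed contact is
treated as "as far apart as the model allows", the least informative
consistent choice.

One structural consequence of the `n√3` normalization is discussed under
*Known limitations*: it stretches the shortest-range targets beyond what
the bond constraint can realize, which puts a floor under the achievable
loss.

## Imputing zero contacts

Each off-diagonal zero entry `(i, j)` is estimated from the non-zero
entries `(a, b)` of its sequential window (`|a−i| ≤ d0`, `|b−j| ≤ d0`)
with Gaussian weights `w = exp(−μ((a−i)² + (b−j)²))`. Two normalizations
are implemented:

* `"kernel"` (default): divide by the summed weights — the standard
  kernel-weighted (Nadaraya–Watson) average. It reproduces a locally
  constant matrix exactly, so an imputed count always sits on the scale
  of its neighbours.
* `"count"`: divide by the *number* `n'` of contributing pairs. Distant
  window entries contribute near-zero weight but still inflate `n'`, so
  this estimator is biased low by the mean kernel weight — about 15-fold
  at `μ = 1`, `d0 = 3` — which in turn inflates the imputed target
  distances by `15^(1/3) ≈ 2.5` and contaminates the normalization
  maximum. We measured the consequence on the synthetic fixture: with
  count normalization even the generating structure correlates only
  r ≈ 0.73 with the resulting targets, versus r ≈ 0.998 with kernel
  normalization. The count form is kept because the imputation rule is
  sometimes described with an explicit `1/n'` factor; it is not a good
  default and the package does not use it as one.

Defaults: `μ = 1` (the natural unit decay; larger `μ` shrinks the
influence of distant neighbours) and `d0 = max(3, ceiling(10·z))` with
`z` the zero fraction — a wider window when more interpolation support is
needed. Both are plain arguments; resolution- and coverage-specific tuning
is expected.

## Simulated annealing

The loss is a relative squared error summed over unordered pairs,

`L = Σ_{i<j} w (d_ij − δ'_ij)² / δ'_ij²`, `w = 10⁻⁴`,

(the `i<j` reading keeps each pair counted once, matching the calibration
of `w`). Moves displace one uniformly chosen bead to one of its 26 Moore
neighbours; proposals that violate a constraint count as trials but can
never be accepted; valid proposals are accepted by the Metropolis rule
(always if `ΔE < 0`, else with probability `exp(−ΔE/T)`). Cooling is
geometric, `T_c = 10 · 0.9^c`. A temperature ends after `10n` acceptances
or `100n` trials, and the run halts after 3 consecutive temperatures miss
the acceptance quota.

`ΔE` is computed incrementally from the `n − 1` terms involving the moved
bead; to bound floating-point drift the full loss is recomputed every
10⁴ accepted moves. All randomness flows through R's RNG (`set.seed()`
gives bit-identical fits); the compiled core draws from the same stream.

Two empirical properties of this schedule, measured on the package's own
fixtures, matter for interpreting traces:

* with `w = 10⁻⁴` the per-move `ΔE` is of order 10⁻⁴ or less at
  `n ≈ 50`, so temperatures above ~10⁻² accept essentially everything:
  roughly the first two thirds of the schedule is an athermal random walk
  and the per-temperature minimum loss jitters there. The minimum-loss
  trend is monotone only in the late, selective phase; tests assert a
  majority-nonincreasing trend plus a substantial cumulative reduction
  rather than strict monotonicity.
* the three-failure halt triggers while roughly 7% of trials are still
  downhill — the protocol trades the last sliver of convergence for
  bounded runtime.

## Hierarchical refinement

A factor-`k` refinement multiplies the coarse coordinates by `k`
(recentred in the lattice of side `5·n_fine`; an integer scaling, so all
pairwise distance ratios are preserved exactly) and grows `k − 1` beads
into each coarse gap toward the straight-line interpolation targets,
under the full constraint set. The literal rule yields
`n + (k−1)(n−1)` beads — the trailing `k − 1` fine bins of the last
coarse bin have no bead; `pad_terminal = TRUE` appends them to reach
`k·n`.

Refinement then reruns the annealer from `t_start = 0.1` with a trial
budget of `5·n_fine` per temperature. Composed with the unchanged
quota/halt rules, the 10-per-bead quota can never be met within `5n`
trials, so refinement spans exactly 3 short temperatures — a local polish
that cannot undo the coarse geometry. Note the scale dependence: with
`w = 10⁻⁴`, `T = 0.1` only exerts real selection once `ΔE` reaches
~10⁻¹, i.e. at chromosome-scale bead counts (thousands of beads at
40 kb); at test scale these sweeps are near-neutral.

One genuine failure mode is detected and reported rather than worked
around: a coarse bond of squared length 9 or 10, scaled by `k`, admits an
essentially unique straight fine path (no other combination of legal
steps covers `3k` in `k` steps). Two adjacent forced corridors can clash
at the forbidden squared distance 8, making insertion infeasible for that
geometry; `insert_beads()` then errors after bounded retries.

## The XCI kinematic models

Between the 0 h and 48 h target matrices, each bead pair is assumed to
change its target distance with a per-period rate tied to Xist
localization: the pair intensity is `R_ij = (RAP_i + RAP_j)/2`, and the
rate of period `p+1` is the rate of period `p` times the intensity ratio
at the boundary. On the canonical 0/3/6/24/48 h grid:

* **velocity model** — `v₀(3 + 3r₁ + 18r₁r₂ + 24r₁r₂r₃) = δ₄₈ − δ₀`,
  then `δ₃ = δ₀ + 3v₀`, `δ₆ = δ₃ + 3v₃`, `δ₂₄ = δ₆ + 18v₆`;
* **acceleration model** — zero initial velocity, per-period constant
  acceleration scaled by the same ratios, displacements
  `vΔt + aΔt²/2` with velocities accumulating across periods; `a₀` has a
  closed form, reducing to `a₀ = (δ₄₈ − δ₀)/1152` (= `½·48²`) when all
  ratios are 1.

Only intensity *ratios* enter, so any global scaling of the RAP tracks
cancels; a floor of `10⁻⁶ ×` the maximum signal guards the ratios against
zero-coverage bins. The final time point's track is validated for shape
but unused by the ratio chain. Internally, positive rate means growing
target distance; the negated "closing speed" view usual in XCI figures is
exported alongside. Kinematic overshoot can drive an intermediate
distance non-positive; such pairs are clamped to a small `ε` (default
10⁻⁶) and counted, and any intermediate matrix whose maximum exceeds
`n√3` is renormalized onto the bound with the scale recorded — both
choices are plumbing to keep the matrices inside the annealer's input
contract, and both are reported when they fire.

## Ensemble selection

Independent fits (different seeds; 40 in the reference protocol, smaller
ensembles are fine for smoke checks) are compared pairwise with TM-score
under fixed bead correspondence — genomic order replaces any alignment
search — using the protein convention
`d0 = 1.24(n−15)^{1/3} − 1.8` (floored at 0.5), iterative subset
re-superposition, and proper rotations only. A structure's Q-score is its
mean TM-score against the rest of the pool; ranking is by descending Q,
ties broken by lower final loss, then seed order.

Two caveats are inherent and documented rather than hidden:

* **chirality**: Hi-C distances cannot distinguish a structure from its
  mirror image, and TM-score (correctly) does not identify them — an
  ensemble can split into two enantiomeric families;
* **scale sensitivity**: TM-score saturates when deviations are small
  relative to `d0` and decays quickly past it. In this package's lattice
  units, independent fits of the synthetic fixture typically score
  0.25–0.45 against each other even when each correlates r > 0.95 with
  the targets; absolute TM values depend strongly on the coordinate
  units, which is why `d0` is exposed as an argument and ranking (not the
  absolute score) is the supported use.

Validation of a single structure is the Pearson correlation between the
upper triangles of its realized distance matrix and the target matrix
(`stats::cor.test` provides the t-distribution p-value).

## The synthetic generator, and what passing tests mean

`make_ground_truth()` produces lattice-valid chains: a snapped helix, a
plain self-avoiding walk, or a bipartite "two_domain" shape — two compact
balls (radius `max(3, ⌈(n/2)^{1/3}⌉ + 2)`, centres `5ρ` apart) joined by
a linker — mimicking the two-superdomain organization of the inactive X.
`structure_to_contacts()` inverts the distance law deterministically
(`c = (d/scale)^{-3}`), giving exact round-trip oracles; a `poisson`
option adds count noise for robustness checks. A configurable fraction of
pairs is zeroed *uniformly at random* to exercise imputation.
`make_rap_timeseries()` emulates the qualitative Xist picture: signal
peaking at the Xist locus, spread width growing with time, amplitude
rising through 24 h and dropping by 48 h.

Real Hi-C differs in ways the generator deliberately does not model:
zeros are distance-biased rather than uniform, counts are overdispersed,
bins are unevenly mappable, and the distance–contact exponent varies
along the chromosome. Passing the recovery tests therefore shows the
pipeline is *self-consistent* (it inverts its own forward model under
noise and missingness), not that it resolves real chromatin structure at
any particular accuracy.

Problem sizes used throughout the tests and the acceptance script — 50
beads for recovery, 30–40 for kinematics and property sweeps, 5-member
ensembles, 20-seed sweeps — were chosen as the smallest sizes at which
the relevant effects are comfortably measurable.

## Known limitations

* **Loss floor under the `n√3` normalization.** Stretching the maximum
  target to the lattice diagonal scales *all* targets by `n√3/max(δ)`;
  short-range targets then demand bonded-pair distances well above the
  `√10` bond cap (about 2.5× on the bipartite fixture). The loss
  therefore has a geometric floor — final/initial ratios of ~0.2 on
  consistent targets, not arbitrarily small — and the annealer's halt
  rule stops slightly short of even that floor. Relative-error loss plus
  Pearson validation are insensitive to this, but absolute loss values
  should be read against the floor, not against zero.
* **Chirality and TM scale**, as above.
* **Single chromosome, pre-normalized input**; no `.hic`/`.cool`
  containers (dense/sparse text, BED, bedGraph, TSV and pseudo-atom PDB
  only).
* **Imputation is smoothing**, not a contact model: it cannot recreate
  structure lost to systematically missing long-range contacts, and at
  high zero fractions imputed regions inherit the local mean.
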