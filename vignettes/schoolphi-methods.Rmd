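---
title: "Measuring integrated information in small schools: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring integrated information in small schools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schoolphi)
```

`schoolphi` measures how strongly a small group of moving animals is
integrated, in the sense of IIT 3.0: how much of the group's cause–effect
structure is destroyed by the least damaging unidirectional split. This
vignette explains the model behind each stage, the parameters that
matter, what the synthetic generators do and do not emulate, and the
numerical choices we made where the method leaves them open.

## From trajectories to a binary Markov process

The raw input is a table of per-frame 2-D positions (mm) for N
individuals in a bounded arena (the defaults assume the 3000 × 2500 mm
space the simulator uses, origin at a corner). Velocities are backward
finite differences of positions: the heading at frame *t* is the unit
vector of x(t) − x(t−1). This is the simplest convention consistent with
defining a turning rate between consecutive steps; no smoothing is
applied. A zero displacement carries the previous heading forward (and is
counted), because inventing a direction would fabricate motion.

Each individual's binary state is the conjunction of three conditions,
each a standard ingredient of zonal flocking models:

* **distance** — ON iff some other individual is strictly closer than ζ
  (mm). Symmetric.
* **visual field** — ON iff some other individual lies strictly within
  the half-angle η = VF/2 of the focal heading. We test the vector *to*
  the neighbour (x_j − x_i), so VF < 2π is a rear blind spot; the printed
  opposite-sign convention is available as
  `visual_vector = "as_printed"`. VF is the axis unit users see; η is
  derived, and η ≥ π short-circuits to ON so that VF = 2π is exactly
  "always ON".
* **turning rate** — ON iff the angle between consecutive headings is at
  least δ (rad *per step*; thresholds quoted in rad/s are multiplied by
  Δt). The comparison is non-strict, so δ = 0 is always ON.

Strictness (`<` for distance and vision, `≥` for turning) follows the
defining set-builder expressions. States exist from the third frame on
(headings need one step, turning two).

The collective state sequence is modelled as a first-order Markov chain
in *state-by-node* form: a 2^N × N matrix of conditional ON-probabilities,
rows indexed little-endian (node 1 = least significant bit), nodes
conditionally independent given the past state. Estimation is maximum
likelihood from transition counts. Past states never visited carry no
information; we fill their rows with 0.5 — the maximum-entropy choice,
consistent with how IIT treats unconstrained variables — and record
per-state occupancy so users can see how much of the matrix is data.
Optional Laplace smoothing (`alpha`) is available but off by default.

## The IIT 3.0 computation

All quantities are computed from the TPM and a collective state.

**Repertoires.** The effect repertoire of a mechanism M over a purview Z
clamps M to its current state, marginalises all other inputs uniformly,
and factorises over purview nodes (each purview node is constrained
independently; correlations due to shared inputs outside the mechanism do
not count as constraint). The cause repertoire is the Bayesian inversion
with a uniform prior over purview pasts; mechanism nodes act as
independent virtual elements whose likelihoods multiply before a single
normalisation. An all-zero likelihood (the mechanism state is unreachable
from the purview) makes the repertoire undefined: we return uniform with
a flag and score that purview φ = 0.

**Mechanism φ.** For every purview, the repertoire is compared with its
minimum-information partition over all mechanism/purview bipartitions,
including cuts against the empty set; the comparison is the earth mover's
distance with Hamming ground metric between purview states. φ^max is
maximised over purviews, ties resolved to the larger purview (the
convention of the reference ecosystem, so that expanded concepts carry
maximal context); among equal sizes the first in little-endian order is
kept. A concept exists when min(φ_cause^max, φ_effect^max) > 0.

**System Φ.** A unidirectional cut {S1 ⇏ S2} replaces the inputs from S1
into S2 with maximum-entropy noise (each severed target's conditional is
averaged uniformly over the severed input bits). Φ is the minimum over
cuts of the extended EMD between the intact and cut cause–effect
structures: φ mass moves between concepts — ground cost the sum of
cause- and effect-side repertoire EMDs after expansion over the full
subsystem — or is created/destroyed at the null concept (the unconstrained
repertoires). The default search is the cut-one family (the 2N cuts
isolating one node in either direction), which upper-bounds the
exhaustive search available via `cuts = "exhaustive"`; ties between cuts
resolve to the earliest cut in canonical order (from-part size, then node
order) and the winning MIP is reported in `{1} -/-> {2,3}` notation.
States that the TPM cannot reach at all are reported as Φ = 0 with an
`unreachable` flag rather than an error.

Two facts we rely on, and test: effect repertoires (and their partitioned
products) are product distributions, for which the Hamming EMD equals the
sum of per-node marginal differences; and extending both distributions by
a common independent factor leaves the EMD unchanged, so expanding
repertoires to the full subsystem is well defined. Cause-side EMDs and
the concept-space transport are solved exactly by a successive-shortest-
path min-cost flow written for this package (no LP dependency); it is
cross-validated in the tests against an independent LP solution and
against a second, independently written transport routine.

**Aggregates.** `phi_over_series()` computes Φ once per collective state
and averages either unweighted over the 2^N states (`by_state`, the
default used for heat maps, since every state has a defined Φ under the
estimated TPM) or weighted by occupancy (`by_time`, the average of the Φ
time series). Standard deviations are population-style (weighted second
moment), matching the usual array-std convention. Both weightings are one
argument apart because the underlying study language is ambiguous between
them; defaults are stated in every output.

## Comparison measures and leadership

Mutual information between X(t−1) and X(t) and the sum of ordered
pairwise transfer entropies (one step of history) are plug-in estimates
in bits, with no bias correction — they are used only for within-study
contrasts on series of 10^4–10^5 steps where plug-in bias is small
relative to the effects of interest.

A collective state with exactly one OFF individual defines a candidate
IIT leader. `leadership_records()` joins, per step: that index, the
positional leader (maximal projection onto the normalised mean heading;
ties to the smallest index; steps whose headings cancel are excluded and
counted), the state's Φ and MIP, and a classification — *passive* when
the MIP is {off} ⇏ rest (the weak link is the flow severed from the
leader, so most information flows from the others), *active* when it is
rest ⇏ {off}. The two matching rates (`matching_rate()`,
`mip_single_off_match_rate()`) are percentages over single-OFF steps.

## Synthetic data: what it emulates, what it does not

The **Boids simulator** reproduces the study conditions used to emulate
small fish schools: a 3000 × 2500 mm arena, Δt = 0.05 s, zonal rules with
repulsion radius R = 10 mm (a body length), alignment radius O = 120 mm
(the observed 80–140 mm neighbour distances), attraction shell O..A with
A = ∞, all scaled by a coupling strength C, and per-size speeds and
heading-noise SDs (n = 2..5: v = 11.1, 12.4, 8.47, 10.2 mm per step;
noise 0.20, 0.17, 0.21, 0.23 rad). Speeds are displacements per step:
real-fish velocities of 150–340 mm/s at 0.05 s give 7–17 mm per step,
which is the only reading compatible with the interaction radii. Where
the source is silent we chose once: the three rule vectors are summed
(alignment includes the agent itself, providing inertia) and only the
direction of the sum is used; Gaussian noise perturbs the heading angle
after the rules; walls reflect both position and heading (`"wrap"` is
available for sensitivity checks); agents start as a loose group at the
arena centre. Under the defaults the school is cohesive with mean
pairwise distances of roughly 40–80 mm — somewhat tighter than the
80–140 mm band of the real schools the parameters point at. The
simulator emulates spatial scale, time scale and interaction structure;
it does not emulate burst-and-coast swimming, body shape, or
individuality of real fish, so tests passing on Boids data show the
pipeline's mechanics, not biological conclusions.

The **random Markov-chain baseline** draws every conditional
ON-probability independently from Uniform(0, 1). This choice is recorded
prominently because the baseline values depend on it; it is the natural
maximum-ignorance ensemble over state-by-node TPMs. σ(Φ(n)) is the SD of
Φ across the 2^n states within one TPM, averaged over TPMs (the ±
ranges quoted alongside are SDs across TPMs).

The **leader-school generator** (`simulate_leader_school()`, and
`synthetic_leader_tpm()` built on it) is a deliberately asymmetric
variant: agent 1 ignores everyone, the others align with and are
attracted to all agents. With a rear blind spot, the front agent tends to
be the unique OFF individual. The resulting estimated 5-node TPM is a
*synthetic stand-in* for an empirically estimated school TPM with
leadership structure; we use it to exercise the all-ON-peak /
OFF-isolating-MIP pattern because the published supplementary matrix is
not redistributable inside this package.

## Problem sizes and numerical notes

Tolerances: repertoires sum to 1 within 1e−10; φ below 1e−10 counts as
zero; oracle comparisons in the tests require agreement to 1e−8. The
exhaustive MIP search is practical to N = 4 in tests; the cut-one search
is the default everywhere and is what the baselines use. The test suite
runs the baseline at 100/60/40 TPMs for n = 2/3/4 — enough that the
cross-TPM standard error is an order of magnitude below the acceptance
bands — while the acceptance script uses the full 100 TPMs per size.
Boids-based checks use 10 runs of 3000 steps at n = 3 and the
leader-school checks 8000 steps at n = 5; these sizes were chosen as the
smallest at which the qualitative patterns are stable across seeds.

Known limitations: first-order Markov estimation only (no multi-step
history); N ≤ 8 for the major-complex search and realistically N ≤ 5 for
routine sweeps; no sampling-based Φ approximations beyond cut-one; plug-in
information estimates without bias correction; the leadership analysis
assumes the single-OFF definition and does not rank individuals by
directed information flow.
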