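---
title: "Copy-number profile distances and clone-tree evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number profile distances and clone-tree evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnpdist)
```

## The model

A copy-number profile (CNP) records, for each of `n` genomic positions
(genes or segments), how many copies a tumour clone carries. Segmental
mutations — breakage–fusion–bridge cycles, focal deletions, chromosome
missegregation — change the copy-number of a *contiguous* block of
positions at once, and can change it by more than one unit. We model this
with events `(s, t, delta)`: every position in `[s, t]` with a positive
copy-number moves by `delta`, clamped at 0. A position at 0 is absorbing
("a lost gene stays lost"), which is what makes the distance directional.

The cost of an event under a unit-cost scheme is 1 when the scheme permits
it and infinite otherwise:

* `mdc` — only `delta` of +1/-1 (the MEDICC-style unit-event model);
* `dbl` — amplifications at most double a copy-number, deletions are free
  of constraint;
* `any` — any `delta` (motivated by processes such as BFB cycles that can
  more than double a copy-number in one sweep).

`d_f(u, v)` is the minimum total cost of an event sequence turning `u`
into `v`. Under `any` this minimisation is strongly NP-hard, so the
package computes bounds, approximations, and exact answers only on small
instances.

## The difference vector and flat intervals

Everything is driven by `w = u - v` with virtual zeros at positions 0 and
`n + 1`. The maximal runs of equal values in `w` — its *flat intervals* —
play the role that breakpoints play in classical rearrangement distances:

* Lower bound: `d >= ceiling((|F_w| - 1) / 2)`, where `|F_w|` counts flat
  intervals, and `d >= k` whenever `w` contains a staircase of `k`
  strictly increasing positive values (`lower_bound()` combines both; the
  staircase bound is also applied to `-w` and to the left-right mirrored
  vectors, a symmetry we verified against the exact oracle on an
  exhaustive small-instance family before enabling it).
* Approximation: one event per non-extreme flat interval solves the
  instance, giving cost `|F_w| - 2` — within a factor 2 of optimal for
  zero-free profiles (`flat_count_distance()`).
* Improvement: an event `(i, j, delta)` with
  `w[i-1] - w[i] = w[j+1] - w[j] = delta` merges two flat intervals and
  removes *two* intervals at once. `heuristic_distance()` greedily applies
  such merge events while they exist (smallest `i`, then `j`), otherwise
  zeroes the leftmost nonzero flat interval; it never does worse than the
  plain count. The merge search hashes interval boundaries by their
  difference and answers validity queries with a range-maximum table,
  avoiding the cubic rescan per step.

A merge event is *valid* only if no position with a positive target would
reach 0 (irrecoverable, by zero-absorption) and no position would be
clamped below 0 (which would break the merge arithmetic); positions whose
target is 0 may land exactly on 0. Zero-valued interior flat intervals
need no event, so `flat_count_distance()` may return fewer events than its
counted cost; the returned sequence always transforms the (reduced) source
into the target, which the test suite checks.

## Null positions

Three reductions remove nulls without changing any unit-cost distance:
positions null in both profiles are dropped; of two adjacent target-nulls
the one with the smaller source value is dropped; a target-null whose `w`
value does not strictly dominate both neighbours is dropped. What remains
are "sandwiched" nulls — local peaks of `w`. `reduce_null_positions()`
iterates the rules to a fixed point and reports what it removed; we
verified on exhaustive small families that the exact distance is unchanged.

## The unit-event distance

For the `mdc` scheme the distance can be computed exactly. Any optimal
unit-event solution can be reordered deletions-first, so it is determined
by per-position deletion and amplification coverages whose cost is the
number of "rises" of each coverage sequence. For zero-free pairs the
minimum has a closed form: the rises of the positive part of `w` plus the
rises of its negative part (`zzs_distance()`'s fast path). With sandwiched
target-nulls, the deletion coverage at the null is a free variable above
`u_i` and amplifications sweep over dead positions at no effect, which
leaves a small chain dynamic program over the non-null positions with a
closed-form bridge across each isolated null. Fast path and dynamic
program are checked against each other and against exhaustive search on
every zero-free pair of length-3 profiles with entries 1..4 and on a
999-pair null-containing family; equality holds on all of them.

## The exact oracle

`exact_distance_oracle()` is exhaustive breadth-first search over all
profiles with entries up to a cap, with the event set filtered by the cost
scheme. Precomputing the successor table once per `(n, cap, scheme)` and
caching it lets one search serve every target from the same source, which
is what makes the 4032-pair validation family cheap. The cap matters:
optimal solutions may overshoot transiently (e.g. `(1,4,1)` to `(4,1,4)`
in two events via `(4,7,4)`), so the default cap is twice the largest
copy-number involved, and the tests confirm that widening it further never
changes a distance on the validation families.

## Symmetrisation

Event distances are directional; the pipeline follows the usual practice
of taking the minimum of the two directions after null reduction. A
direction whose source is null where its target is positive is undefined
and scored as infinite. When *both* directions are undefined — routine for
simulated tumours, where each clone loses a few private genes — the
positions null in exactly one profile are dropped from both and the
minimum is taken on the remainder. This pragmatic fallback keeps the
distance finite and symmetric without silently hiding the directionality
when one direction is genuinely available. The Euclidean distance ignores
nulls and reductions entirely.

## The simulator

`simulate_instance()` evolves chromosome *strings*, not profiles, so the
inferred distances face model misspecification just as they would on real
data: after a few duplications and deletions the gene order no longer
matches the reference, while the distance model assumes reference
contiguity.

* Tree: uniform over the `(2l-3)!!` rooted binary labeled topologies, by
  stepwise leaf insertion at a uniformly chosen edge (including above the
  root). Uniformity is a distributional contract of the generator and is
  chi-square-tested at `l = 3` and `l = 5`.
* Branch lengths: each branch receives `k ~ U{e_min..e_max}` events,
  multiplied by a rate-heterogeneity factor uniform on
  `[1 - sqrt(3), 1 + sqrt(3)]` — the unique uniform law with mean and
  standard deviation 1 — clamped at 0 and rounded half-up. The clamp and
  the rounding convention are our choices; only the first two moments of
  the factor are prescribed.
* Events: tandem duplication with probability `dup_prob`, else deletion;
  start uniform; length geometric with stop probability `r`, truncated at
  the chromosome end. A deletion that would empty the chromosome keeps one
  symbol, since downstream profile comparison of an extinct lineage is
  meaningless.
* Last-copy guard: whenever a proposed deletion would remove every
  remaining copy of some gene — at its start position, or at any extension
  step once such a gene is inside the range — it proceeds only with
  probability `q`. We read the guard as covering the start position as
  well as extensions; with the guard restricted to extension steps only,
  the null fraction at the default `q = 0.25` roughly doubles, far from
  the intended regime of mostly-retained genes.
* Noise: each observed copy-number is redrawn from
  `Normal(u_i, alpha * u_i)` and rounded, so relative error is constant
  and nulls stay null.

What passing tests show — and what they do not: the generator produces the
*mechanism* (segmental dup/loss on strings along a clone tree), not
calibrated human-tumour data. In particular, under the uniform-topology
tree model the mean leaf depth at `l = 100` is about 16 branches, and the
null-position fraction at default parameters settles around 5–9%, above
the 2–5% regime reported for comparable simulators whose recursive-split
tree constructions are biased toward balanced (hence shallower) trees. We
kept the uniform model because it is the stated sampling target and the
distributional tests pin it; the consequence is a harsher simulation —
more deletions per lineage — than a balanced-tree variant would give, and
one band-style expectation in the acceptance suite documents this gap by
failing rather than by our re-tuning the generator.

## Evaluation pipeline

`distance_matrix()` symmetrises all pairs (the three event distances run
in compiled code; Euclidean uses `dist()`), `neighbor_joining()` wraps the
Saitou–Nei implementation in \pkg{ape} (negative branch lengths are kept;
tie-breaking is ape's), and `normalized_rf()` compares unrooted
bipartitions via \pkg{phangorn}, divided by `2(l - 3)` so that 0 is
topological identity and 1 is total disagreement. `run_experiment()`
drives a parameter grid with per-replicate seeds split deterministically
from one master seed, so adding or removing methods never perturbs the
simulated data.

```{r example}
set.seed(1)
inst <- simulate_instance(sim_config(l = 20, n = 60, seed = 11))
D <- distance_matrix(inst$profiles, "heuristic")
rf <- normalized_rf(inst$tree, neighbor_joining(D))
rf
```

## Problem sizes used in validation

The test suite validates the algorithms on exhaustive families (all 4032
ordered pairs of distinct zero-free length-3 profiles with entries 1..4;
999 null-containing pairs), checks the simulator's distributions with
3000–8400 tree draws and 20000–40000 scalar draws, and runs the full
noisy-reconstruction experiment at the default study conditions
(`l = 100`, `n = 100`, `alpha = 0.25`) with 50 replicates.

## Limitations

* No exact polynomial algorithm exists for the unrestricted-event
  distance (the problem is strongly NP-hard); the heuristic's
  approximation factor beyond the flat-interval bound is open.
* The `dbl` scheme is supported only in the exact oracle.
* No inversions, translocations, chromothripsis, or allele phasing; one
  chromosome, single-allele profiles.
* The approximation guarantee assumes zero-free profiles; with many nulls
  the flat-interval count can be far from optimal (the alternating
  high/low pattern collapsible by two whole-profile events is the
  canonical bad case).
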