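---
title: "Karyotype evolution by rearrangement parsimony: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Karyotype evolution by rearrangement parsimony: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyevol)
```

## The problem

Comparative cytogenetics of fishes often has, per species, little more than a
diploid chromosome number and a karyotype formula — how many chromosomes are
biarmed (metacentric/submetacentric, "m-sm") and how many are uniarmed
(subtelocentric/acrocentric, "st-a") — plus a count of chromosome pairs
bearing CMA3-positive (GC-rich, typically NOR-associated) fluorescent
signals. Given such data for the tips of a phylogeny, the question is which
ancestral karyotypes and which chromosomal rearrangements most economically
explain the observed diversity. `karyevol` answers it with event-count
parsimony and provides a generative simulator to probe how reliable that
answer is. The worked dataset shipped with the package is the five-species
South American dwarf cichlid clade *Nannacara*–*Ivanacara*–*Cleithracara*
(2n between 44 and 50).

## State representation

A karyotype is reduced to a point on an integer lattice: `M` biarmed pairs
and `A` uniarmed pairs (plus an optional CMA3 pair count `c <= M + A`). Two
modelling choices are baked in:

* **Pair units.** Every rearrangement in the model acts on whole homologous
  pairs, so counting pairs rather than chromosomes keeps all event effects
  integral, and `2n = 2(M + A)` is even by construction. Odd per-class
  chromosome counts in a formula are rejected by default (there is no model
  of supernumerary B chromosomes); a `lenient` parser flag floors them to
  pairs with a warning.
* **Two arm classes.** The four Levan-style categories are pooled into
  biarmed (m, sm) and uniarmed (st, a, t), exactly as comparative karyotype
  tables group them. Within-class centromere position, chromosome size, and
  NOR placement (terminal versus centromeric) are deliberately out of scope:
  the data that motivate the model do not distinguish them.

The parser accepts both dialects seen in published tables
(`"18m-sm+26st-a"`, `"14sm+36st-a"`, `"48st-a"`); the canonical output
dialect is always `"<2M>m-sm+<2A>st-a"`.

## The event model

Six event kinds act on a state, each costing one step:

| event | effect (dM, dA, dc) | precondition |
|---|---|---|
| centric (Robertsonian) fusion | (+1, −2, 0) | `A >= 2`, and `c < M + A` when scored |
| fission | (−1, +2, 0) | `M >= 1` |
| pericentric inversion, m-sm → st-a | (−1, +1, 0) | `M >= 1` |
| pericentric inversion, st-a → m-sm | (+1, −1, 0) | `A >= 1` |
| CMA3 gain | (0, 0, +1) | `c < M + A` |
| CMA3 loss | (0, 0, −1) | `c >= 1` |

Fusions and fissions change 2n by −2/+2; inversions leave it unchanged; the
fusion precondition on `c` merely keeps the signal count from exceeding the
pair count after two pairs merge. Both inversion directions cost 1: the
narrative of karyotype evolution in this clade invokes both the creation and
the reduction of sub-metacentrics by pericentric inversion, with no basis
for weighting them differently. The CMA3 count evolves as an independent
ordered character with unit step cost — the data report it as a separate
phenotype column, and nothing in the count data ties a specific signal
change to a specific rearrangement.

## Minimal distances

With `dN = (M2 + A2) − (M1 + A1)` and `dM = M2 − M1`, the minimal number of
events between two states is

```
distance = |dN| + |dM + dN|
```

because only fusions/fissions move the pair total (`|dN|` of them are
forced), and they overshoot the required `dM` by exactly `−dN`, which
`|dM + dN|` inversions repair. The corresponding minimal multiset — which
never mixes an event with its inverse — is unique even though event
orderings are not. `event_distance()` certifies each closed-form answer by
searching for a feasible ordering of that multiset (a memoised search over
remaining counts); if none exists it falls back to the breadth-first-search
oracle `min_event_path()`, which walks the bounded lattice under the exact
preconditions. Empirically the two routes disagree nowhere except on pairs
involving the chromosome-less state (0, 0), which no event enters or
leaves: there the distance is reported as `Inf` and the oracle reports
unreachability. The test suite sweeps every lattice pair with `M <= 12`,
`A <= 25` to confirm the equivalence, and checks the metric axioms on
sampled triples. When both endpoints carry a CMA3 count, `|dc|` is additive:
gains can always be scheduled where the pair total is largest along a
minimal karyotype path, and losses where it is smallest, so the combined
distance never exceeds the sum of its parts.

## Sankoff parsimony and the state space

Ancestral reconstruction is Sankoff (generalized) parsimony: leaf costs are
0 at the observed state and infinite elsewhere, internal costs accumulate
`min_t(cost(s, t) + cost_subtree(t))` in post-order, and a pre-order pass
marks every state attaining the optimum at each node (the MPR set). Branch
lengths are ignored throughout — the criterion is event counting, not
likelihood. The finite state space is the observed tip bounding box widened
by `slack` pairs per side (default 4, clipped at zero). Widening the slack
never changes the optimum once all geodesic intermediates fit; the fixture
optimum is stable from slack 0 through 6, which the tests assert.

Ties are first-class citizens. `enumerate_mprs()` lists every optimal full
assignment (lexicographic order, truncated at a cap with an explicit flag),
and `decompose_all_branches()` maps any of them to per-branch minimal event
multisets whose totals always sum to the optimum.

### Root ties and the anchor

On the cichlid fixture the root MPR set is genuinely ambiguous: both
2n = 48 (16m-sm+32st-a) and 2n = 50 (14sm+36st-a) explain the tips with
five events. Ingroup parsimony alone cannot split them — the extra
information that decides the matter is phylogenetic context: the ancestral
karyotype widely accepted for cichlids (and most teleosts) is 2n = 48 with
48 acrocentrics ("48st-a"). `sankoff_reconstruct(anchor = )` therefore
accepts an optional anchor state and, among tied root states only, prefers
the one with the smallest event distance to it (16m-sm+32st-a lies 8
inversions from 48st-a; 14sm+36st-a lies 9 events away). The anchor never
alters MPR sets, costs, or non-root choices, and the scenario report prints
all tied root states whenever they exist. Without an anchor the selection
falls back to the lexicographically smallest `(M, A)` state, purely for
determinism.

### CMA3 reconstruction

The count character runs through the same machinery over states
`0..max_count` with cost `|dc|`; `max_count` defaults to the observed
maximum plus 2, which is enough headroom for any minimal scenario. On the
fixture the root is unambiguously one CMA3 pair at total cost 2 (the
three-pair phenotype of *N. aureocephalus* requires two unit gains). Note a
deliberate distinction: count parsimony prices that change as two steps,
while a mechanistic account might attribute the multiplication to one or
two inversion events hitting NOR regions — the count-level model cannot and
does not adjudicate the number of underlying inversions; both readings are
compatible with its output. The karyotype and CMA3 characters are
reconstructed independently (a combined view simply sums the per-branch
multisets, as `write_report_table()` does), mirroring how the data report
them as separate columns.

## The simulator

`simulate_history()` is the generative counterpart of the event model: per
branch, the count of each event kind is Poisson with mean `rate × length`
(or `rate` per branch when the tree has no lengths or `per_branch = TRUE`),
the drawn events are applied in uniformly shuffled order, and an event that
is infeasible at its moment is *skipped and logged* rather than resampled —
resampling would distort the Poisson interpretation of the counts and can
loop near the lattice boundary. A single seeded RNG stream makes every
output byte-identical under a fixed seed. Trees come in via Newick or from
a pure-birth (Yule) generator (`ape::rphylo`), which suffices because only
a topology with positive lengths is needed.

What the simulator emulates: event-count evolution of the two-class
karyotype and the CMA3 count under homogeneous per-kind rates. What it does
not emulate: translocations, polyploidy, sex chromosomes, chromosome-size
effects, branch-specific or correlated rates, and any mechanistic coupling
between rearrangements and signal counts. Recovery results therefore speak
to the reconstruction machinery under the model's own assumptions, not to
the full complexity of real karyotype data.

No event rates are estimated from data anywhere in the package; the
defaults (0.1 per karyotype event kind, 0.05 per CMA3 kind) are
illustrative magnitudes only.

## Recovery experiments

`recovery_experiment()` simulates, reconstructs, and scores each replicate:
is the true root state (and its 2n) inside the root MPR set, how does the
parsimony total compare with the number of events actually applied
(parsimony is a lower bound, asserted in every replicate), and what
fraction of branches recover the exact applied multiset. The Sankoff state
space for this experiment is built from the tip states *together with the
true node states* before widening: with tips alone, a rare replicate whose
true internal states drift outside the tip range plus slack could violate
the lower bound through space truncation rather than through anything about
parsimony. The acceptance regime — chosen a priori as a low-rate setting —
is 200 replicates on 20-leaf Yule topologies with per-branch rates
(fusion 0.12, fission 0.12, each inversion 0.08; 0.40 expected events per
branch), where root-2n recovery is required to reach at least 0.8.

## Numerical and design notes

* All distances and costs are small integers; no floating-point tolerances
  are involved anywhere in the optimisation.
* Determinism: reported MPR states are sorted lexicographically by
  `(M, A)`; the selected scenario breaks every tie lexicographically (after
  the root anchor, if any); reports and annotated trees are written in
  pre-order; simulation is reproducible from its seed, and every CLI run
  echoes a machine-readable `config.json`.
* The BFS oracle searches a box slightly larger than the states under test
  (margin 2 on `M`, 4 on `A` in the exhaustive sweep) so that shortest
  paths are never clipped by the box boundary.
* Problem sizes used by the shipped checks: the full lattice sweep covers
  the 338 states with `M <= 12`, `A <= 25` (113,000+ ordered pairs); the
  recovery experiment runs 200 replicates of 20-leaf trees; the fixture
  reconstruction itself is a 154-state, 5-leaf problem that completes in
  well under a second.

## Limitations

The model is a count-level abstraction: it cannot distinguish which
particular pairs fuse, so karyotypes that differ only in *which*
chromosomes carry a feature are identical states; it has no notion of
homology of signals between species; and parsimony reports minimal
scenarios — real histories may contain extra, self-cancelling events that
no count-based criterion can see (the taenia lineage's "at least one"
inversion is reported at its minimum of one, for instance). Uncertainty is
expressed only through MPR-set enumeration; there is no likelihood or
Bayesian machinery, and no rate estimation (ChromEvol-style inference is a
different tool for a different question).
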