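# karyevol

Ancestral karyotype reconstruction on phylogenies by chromosomal
rearrangement parsimony, with a generative simulator for recovery testing.

Comparative fish cytogenetics typically observes, per species, a diploid
number (2n), a karyotype formula splitting the complement into biarmed
(metacentric/submetacentric, "m-sm") and uniarmed
(subtelocentric/acrocentric, "st-a") chromosomes, and a count of chromosome
pairs carrying CMA3-positive (GC-rich, NOR-associated) signals. `karyevol`
maps such data onto a phylogeny and reconstructs ancestral karyotypes and
per-branch rearrangement scenarios under event-count parsimony. The package
ships the five-species South American dwarf cichlid clade
*Nannacara*–*Ivanacara*–*Cleithracara* (2n = 44–50) as a worked dataset.

## Model in brief

A karyotype is a lattice point `(M, A)` of biarmed/uniarmed homologous
*pair* counts (so `2n = 2(M + A)`), optionally with a CMA3 pair count `c`.
Six unit-cost events act on it: centric fusion `(+1, −2)` (2n − 2), fission
`(−1, +2)` (2n + 2), pericentric inversion in either direction `(∓1, ±1)`
(2n unchanged), and CMA3 gain/loss `(0, 0, ±1)`. With
`dN = ΔM + ΔA` the minimal number of events between two states is

```
d = |dN| + |ΔM + dN|        (+ |Δc| when both states are scored)
```

with a unique minimal event multiset; a breadth-first-search oracle over
the feasibility-constrained lattice backs the closed form wherever
boundary preconditions bite. Ancestral states are computed by Sankoff
(generalized) parsimony with this distance as the cost matrix, reporting
*all* most-parsimonious states per node, enumerable into complete tied
scenarios. The CMA3 count is reconstructed as an independent ordered
character. A Poisson event simulator on (Yule or user) trees provides
ground-truth histories for recovery experiments.

## Worked example

```r
library(karyevol)
fx <- nic_fixture_files()
run_reconstruct(fx[["tree"]], fx[["karyotypes"]], "out/",
                anchor = "48st-a")  # ancestral cichlid karyotype breaks root ties
```

`out/scenario.txt` then contains:

```
Most parsimonious karyotype scenario (total events: 5; CMA3 events: 2)
Root ancestral karyotype: 16m-sm+32st-a (2n=48); CMA3-positive pairs: 1
Note: 2 equally parsimonious root states (14m-sm+36st-a, 16m-sm+32st-a); tie broken toward the anchor karyotype 0m-sm+48st-a
Branch node6 -> maronii: 1 fission [2n 48 -> 50]
Branch node6 -> node7: no events [2n 48 -> 48]
Branch node7 -> adoketa: no events [2n 48 -> 48]
Branch node7 -> node8: 2 fusions + 1 pericentric inversion (m-sm->st-a) [2n 48 -> 44]
Branch node8 -> taenia: 1 pericentric inversion (m-sm->st-a) [2n 44 -> 44]
Branch node8 -> node9: no events [2n 44 -> 44]
Branch node9 -> aureocephalus: no events [2n 44 -> 44]
Branch node9 -> anomala: no events [2n 44 -> 44]
```

Reading: the ancestor of the clade carried 2n = 48 (16 biarmed + 32
uniarmed chromosomes) and one pair of CMA3 sites; the *Cleithracara
maronii* karyotype arose by one fission, the three 2n = 44 *Nannacara*
species descend from two fusions followed by a pericentric inversion on
their stem plus a second inversion in *N. taenia*, and *Ivanacara adoketa*
retains the ancestral karyotype unchanged. The five karyotype events are
the parsimony optimum; the two CMA3 gains account for the three-signal
phenotype of *N. aureocephalus*. The root note records that ingroup
parsimony alone ties 2n = 48 with 2n = 50 and that the anchor karyotype
(48 acrocentrics, the ancestral state of cichlids generally) resolved it.

Alongside `scenario.txt` the run writes `report.tsv` (per-node MPR sets and
per-branch event multisets, pre-order), `annotated_tree.nwk` (states as
`[&...]` comments that tree viewers ignore) and `config.json` (run echo).

Other entry points: `run_distance("16m-sm+32st-a", "14sm+36st-a")` prints
`distance=1 events={1 fission}`; `run_simulate()` writes a simulated
dataset that feeds straight back into `run_reconstruct()`;
`recovery_experiment()` scores root-state recovery and the parsimony lower
bound over simulation replicates. A command-line wrapper for all three
lives at `inst/scripts/karyevol.R`.

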