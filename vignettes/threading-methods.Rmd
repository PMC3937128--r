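---
title: "Monte Carlo threading: model, movers, energies and design notes"
author: "ThreadMC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo threading: model, movers, energies and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ThreadMC)
```

## Why a stochastic sampler

Pairwise sequence alignment under per-position scores and affine gaps is
solved exactly by dynamic programming. The moment the score couples
alignment columns — a contact potential mapped through the alignment, a
TM-score that depends on a global superposition — the optimum is no
longer decomposable and exact search becomes intractable. ThreadMC
therefore treats an alignment as the state of a Monte Carlo simulation:
local stochastic moves, Metropolis acceptance, and either simulated
annealing or replica exchange to cross barriers. The sampler is an
*optimizer*: it reports the best state ever visited (and ranked
suboptimal states), not a Boltzmann ensemble, and proposal asymmetries
are deliberately not corrected for in the acceptance rule.

## State space

An alignment is an ordered list of blocks `(queryStart, templateStart,
length)`, 1-based closed intervals, non-overlapping and strictly ordered
in both sequences. Two restrictions shape the space:

* `minBlockLength` (default **4** residues): no block may be shorter;
* `minNumberOfBlocks` (default **4**): every alignment must carry at
  least this many blocks.

The second rule only guarantees each mover something to act on: because
neighbouring blocks may abut with zero gap, any alignment can be written
with more blocks than its canonical form has, so the rule does not
restrict which alignments are reachable — a perfect 100-residue
self-alignment is equally 25 blocks of 4, 4 blocks of 25, or one block of
100, all with the same energy. `canonicalize()` merges abutting blocks;
alignment identity (and suboptimal deduplication) is defined on canonical
forms. For chains too short to host
`minNumberOfBlocks * minBlockLength` residues the count constraint is
relaxed to the largest feasible value, with a warning.

Indexing is 1-based with closed intervals throughout, the R and
Bioconductor convention; reports and PIR output are 1-based as well.

## Movers

Seven operators, selected with probability proportional to configurable
weights (defaults 100, 100, 100, 10, 10, 1, 1):

| mover | action | notes |
|---|---|---|
| shift | move one block on the alignment matrix | uniform over the rectangle its neighbours allow, current position excluded |
| shrink_expand | move one block end by N | N ~ 2^-N truncated to the feasible range; never below `minBlockLength` |
| part_jump | move a terminal segment to the adjacent block | segment re-aligned on the neighbour's diagonal; donor keeps >= `minBlockLength` |
| split | cut one block into two abutting parts | both parts >= `minBlockLength`; pair set unchanged, energy unchanged |
| merge | fuse two blocks abutting on both sequences | refused at the minimum block count |
| annihilate | delete one block | refused at the minimum block count |
| create | insert a new block of exactly `minBlockLength` | uniform over all feasible positions |

The published proposal ratio names six entries; block creation is not
among them, so its default weight is set equal to annihilation (1),
keeping creation and deletion symmetric. A geometrically impossible move
returns an *infeasible* outcome — never an error — and counts as a
rejected proposal in acceptance statistics. Every mover reports the set
of query columns whose template partner changed; the closure property
(every feasible proposal from a valid state is valid) is property-tested
over 10^5 random moves.

## Sampling

`metropolisAccept()` implements min(1, exp(-dE/T)) with dimensionless
energies and temperatures. Two drivers:

* **Simulated annealing** visits the configured temperatures from hottest
  to coldest, equal proposal counts per stage.
* **Replica exchange** runs one replica per temperature of the default
  ladder 0.08, 0.1, 0.15, 0.2, 0.5, 1.0, 2.0, 5.0, 7.0, 10.0. After each
  cycle of `innerSteps` proposals per replica, adjacent pairs (alternating
  even/odd pairings per cycle) swap states with probability
  min(1, exp((1/T_i - 1/T_j)(E_i - E_j))). The ladder's adjacent-replica
  energy histograms overlap on the bundled fixtures
  (`energyHistograms()`), which is what lets states random-walk in
  temperature.

Defaults where a choice had to be made: `innerSteps = 200 x query length`,
`cycles = 100`, per-replica initialization from a random valid alignment
built by repeated block creation (with a direct random-layout fallback
for chains so short that sequential placement corners itself), observer
memory bounded at the 1000 best distinct records, and an optional
early-stop when the best energy is unchanged for `stopAfterStable`
cycles. Identical seeds give bit-identical runs; all randomness, including
inside the compiled kernels, flows from R's RNG.

## Energies

A force field is a weighted list of terms; similarity-like terms enter
negated so the sampler minimizes, penalties are positive. The term
taxonomy mirrors how each term can be evaluated:

* **BigMatrix** terms (substitution, profile cross-score, secondary
  structure, burial/ASA agreement, hydropathy mismatch, user-supplied
  matrices) depend only on the (query position, template position) pair:
  they are pre-computed once into a query x template matrix
  (`precomputeMatrix()`), summed over aligned pairs, and re-evaluated
  incrementally over the changed columns of a move. Incremental and full
  evaluation agree to < 1e-9 over 10^5-move storms (tested).
* **Contact-based** terms (Miyazawa-Jernigan two-body energies, Go-like
  contact recovery, structural gap penalty) transform the template
  contact map through the current alignment; they are pairwise but not
  precomputable, and are recomputed per proposal (cheap, linear in the
  number of contacts).
* **Structure-based** terms (TM-score, RMSD, DALI) need the query
  coordinates and a superposition; they are recomputed in full at every
  move.
* **Affine gaps** charge open + (g-1) x extend per run of g unaligned
  residues between consecutive blocks, query and template runs counted
  separately; terminal gaps are free by default (`open = 5.0`,
  `extend = 0.5`).

Parameter notes, with units and why:

* Contact map: C-alpha pairs within **8 Angstrom**, sequence separation
  >= 3 (cutoff and definition configurable). The bundled traces carry only
  C-alpha coordinates, so the C-alpha map is the natural default.
* Miyazawa-Jernigan: the 1996 upper-triangle contact-energy table (RT
  units), shipped as a documented TSV and user-replaceable.
* TM-score: d0 = 1.24 (L_norm - 15)^(1/3) - 1.8, floored at 0.5 (the small-L
  regime), normalized by the **query** length — threading semantics, where
  the query is the chain being modelled.
* DALI: envelope 0.2, 20 Angstrom Gaussian decay; the elastic sum is taken
  once per unordered pair of aligned columns plus 0.2 per column.
* Default threading weights: env 0.1, secondary 0.25, profile 0.5,
  Go-like 1.0, two-body 0.4, structural gap 0.15.

## Numerical choices

* **TM-score search.** The score is a maximum over superpositions, found
  by iterative Kabsch refinement on shrinking inlier sets (inlier cutoff
  max(d0, 3.5) Angstrom, bumped by 0.5 when fewer than 3 pairs survive).
  Inside the sampler a single all-pairs seed with an 8-iteration cap is
  used — evaluated at every proposal, cost matters; the scoring API
  (`tmScore(..., thorough = TRUE)`) additionally seeds from fragment
  windows of several lengths. Records produced by a sampling run carry
  energies from the sampler's evaluation, so their per-term breakdown sums
  exactly to the sampled total; final rankings of reported alignments are
  re-scored with the thorough search. On small instances the thorough
  search agrees with an exhaustive all-windows restart oracle to
  femto-scale differences (tested at 1e-3 tolerance).
* **Degenerate inputs.** TM-score of fewer than 3 aligned pairs is
  undefined and scored 0 with a warning; RMSD of an empty alignment
  likewise. Unknown residue letters score through a substitution matrix's
  wildcard row, sit mid-scale for hydropathy, and contribute nothing to
  the pair potential.
* **Exact DP cross-check.** `nwAffineOracle()` is a three-state Gotoh
  solver (free terminal gaps by default) used as the exact optimum for
  force fields that are fully per-position decomposable. For such checks
  the sampler is run with `minBlockLength = 1, minNumberOfBlocks = 1` so
  the Monte Carlo state space coincides with the DP search space; with the
  default 4/4 constraints the DP optimum may simply not be representable.
  On 30 x 30 iid N(0,1) score matrices with the default gap parameters,
  replica exchange at 2 x 10^4 proposals per replica attains the exact DP
  optimum in 19/20 instances (the acceptance suite asserts >= 18). Under
  much harsher gap parameters (open = 2) the same budget reaches only
  about half the instances — the optima fragment into many scattered
  blocks — though every instance checked converges at a 100x budget.

## What the synthetic data emulate — and what they do not

`makeHelixTrace()` builds ideal alpha-helix geometry (1.5 Angstrom rise,
100 degrees per residue, 2.3 Angstrom radius) with a seed-fixed random
sequence; `makeHomolog()` derives a query with Gaussian coordinate noise,
optional substitutions and deletions between preserved segments, keeping
the exact ground-truth alignment; `makeProfile()` concentrates a chosen
probability mass on the true residue; `makeSS2()` and `makeBurial()`
derive secondary structure and burial from the geometry; every file
format the package reads can be written back by the fixture writers.

These fixtures give exact ground truth and full format coverage, but they
are *easy* instances: a single regular secondary-structure element,
profiles whose signal is uniform along the chain, noise that is iid and
unstructured. Passing the recovery tests (AL_4P >= 0.9 on low-noise
homologs, TM-score 1.0 on identical chains) demonstrates the machinery is
correct and the search converges on desk-scale problems; it does not
demonstrate threading accuracy on real, evolutionarily divergent protein
pairs, which depends on profile quality and weight calibration outside
the package's scope.

One quantitative consequence of the fixture scale is worth spelling out.
For a converged structure-alignment run on the 60-residue homolog pair,
the ten best *distinct* alignments necessarily include states that drop
or remap at least one aligned pair, and at L = 56 a single pair is worth
about 0.85/56 ~ 0.015 TM-score units. The observed top-10 spread is
therefore ~0.02-0.03 — the "suboptimal alignments within 0.01 TM-score"
behaviour reported for real benchmark proteins of 100-300 residues, where
the per-pair quantum is below 0.01, cannot materialize at this chain
length. The acceptance suite states the 0.01 expectation and records the
honest measured value.

## Problem sizes used by the test and acceptance suites

Chosen as the package's own desk-scale defaults: 24-60-residue fixtures
for unit tests; 10^5-draw distributional checks and 10^5-move
incremental-vs-full storms; 20 instances of 30 x 30 for the DP
equivalence suite at 2 x 10^4 proposals per replica; 60-residue pairs
with 5 x 10^3 proposals per replica per cycle, up to 200 cycles with
early stop, for the structure-alignment runs.

## Known limitations

* One instance each of the gap, contact and structure terms per compiled
  force field (multiple BigMatrix instances are unrestricted).
* Global alignment semantics only; no local (Smith-Waterman-style) mode,
  no multi-chain alignment, no mmCIF input.
* The profile-to-profile score slot for pair-vector comparison beyond the
  cross score (and upstream profile generation against sequence
  databases) is out of scope; the package reads the standard ASCII
  formats and synthesizes fixtures instead.
* Mover weights and the temperature ladder are exposed but not
  auto-tuned.
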