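---
title: "Benchmarking 2D fingerprints for virtual screening: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking 2D fingerprints for virtual screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpbench)
```

## The experiment

Ligand-based virtual screening (VS) asks whether a similarity method can
recognize molecules active against a target given a handful of known
actives. `fpbench` implements the standard retrospective simulation of that
task as a three-stage pipeline:

1. **Scoring.** Per target, the experiment is repeated R times (default 50).
   In each repetition a set of query actives (default 5) and a fraction of
   the decoys (default 20%) are held out as training molecules; the
   remaining actives and decoys form the test set. Every test molecule is
   scored by its *maximum* similarity to any query (MAX group fusion) and
   the test set is sorted by that score.
2. **Validation.** Each ranked list is reduced to evaluation-metric values
   (AUC, EF, RIE, BEDROC), and within each repetition the fingerprints are
   ranked by metric value (rank 1 = best, average ranks on ties).
3. **Analysis.** Ranks are averaged over repetitions per target and over
   targets per method; a global Friedman test across targets checks for
   consistent differences between fingerprints, followed by bootstrapped
   post-hoc pairwise comparisons with maxT multiplicity adjustment.

The underlying assumptions are those of every retrospective VS benchmark:
decoys are presumed inactive, the active/decoy split is ground truth, and
repetitions differ only in the random training split. Targets are treated
as independent blocks in all cross-target statistics.

## Evaluation metrics and their parameters

With *n* actives among *N* test molecules and 1-based active ranks $r_i$:

* **AUC** — the ROC area, computed in its Mann–Whitney form, i.e.
  normalized by $n(N-n)$. This is a deliberate numerical choice: the
  alternative normalization by $nN$ that sometimes appears in discrete
  write-ups cannot reach 1 for a perfect ranking and does not average to
  0.5 under random ordering, both of which are properties the benchmark
  relies on (and which the test suite asserts). AUC weighs the whole list;
  it is insensitive to *where* in the top the actives sit.
* **EF(χ)** — actives found in the top fraction χ over the random
  expectation, $\mathrm{EF}(\chi) = \sum_i \delta(r_i \le \chi N) / (\chi
  n)$, bounded by $\min(1/\chi, N/n)$. The rank threshold $r_i \le \chi N$
  compares integer ranks with the real-valued product, which is equivalent
  to $r_i \le \lfloor \chi N \rfloor$. Defaults χ = 0.01 and 0.05. χ should
  stay above the actives/total ratio, otherwise the bound degrades to
  $N/n$ and values are not comparable across targets.
* **RIE(α)** — exponentially rank-weighted enrichment,
  $\sum_i e^{-\alpha r_i/N}$ divided by its analytic random average
  $(n/N)(1-e^{-\alpha})/(e^{\alpha/N}-1)$. $1/\alpha$ plays the role of χ;
  defaults α = 20 and 100. `rie()` warns when $\alpha n/N$ is not small,
  the regime where RIE saturates. The closed-form extremes
  (`rie_bounds()`) are exact for the discrete sum, and the implementation
  verifies to $10^{-9}$ that the extreme rankings attain them.
* **BEDROC(α)** — RIE rescaled by those bounds onto [0, 1]; depends only on
  the ordering, never on the similarity scale.

## Fingerprints and similarity

SMILES parsing is delegated to OpenBabel (via ChemmineR/ChemmineOB); the
fingerprint algorithms themselves operate on the parsed heavy-atom graph:

* Circular fingerprints (ECFP/ECFC/FCFP/FCFC, diameters 0–6) use iterative
  neighbourhood hashing. Initial atom invariants for the EC family are
  element, heavy-atom degree, implicit-H count, formal charge and ring
  membership; the FC family hashes simple pharmacophoric features (donor,
  acceptor, aromatic, halogen, basic N, acidic O). ECFC0 deliberately uses
  the *element only* as invariant, making it a pure atom count: two
  molecules with the same heavy-atom-type multiset get identical ECFC0.
  That property is what qualifies it as a baseline and as the decoy
  atom-count matching rule.
* AP encodes atom-type pairs (element, heavy-neighbour count, π-electrons)
  with their topological distance; TT encodes 4-atom linear torsion paths
  of the same atom types; both are count vectors. RDK5 hashes all linear
  paths up to 5 bonds over (element, aromaticity) atom codes and bond
  orders into a 1024-bit string.
* MACCS delegates to OpenBabel's 166-key implementation. Avalon has no
  backend in this stack; its registered descriptor raises a clear
  capability error at compute time so that configurations naming it fail
  loudly, not silently.
* Bit strings default to 1024 bits; the `l`-variants fold into 16384 bits,
  and `folding_collisions()` reports the on-bits merged by folding.

Aromaticity is perceived pragmatically from the kekulized input: a ring
system is aromatic when every member atom either carries a π electron or is
a heteroatom with a lone pair (N, O, S, Se). This marks the common
benzenoid and five-membered heteroaromatic systems and leaves saturated
carbocycles alone; it is not a full Hückel treatment.

Eight similarity measures are supported; Dice is the default. For count
vectors the multiset generalization is used ($c = \sum_i \min(a_i, b_i)$),
which keeps ECFC/FCFC scoring well defined. Manhattan and Rogot–Goldberg
need the common off-bit count and are therefore restricted to bit strings.
Zero-feature vectors get similarity 0 with a warning (avoiding 0/0). Dice
and Tanimoto are monotonically related at fixed query, so they induce the
same ranking; the suite property-tests this on 10⁴ random triples.

## Ties, seeds and reproducibility

Similarity ties are common (many decoys share a score under coarse
fingerprints), and any systematic tie order biases early-recognition
metrics. Ties are broken by a pseudo-random key hashed from (seed, target,
repetition, internal ID). Keying on molecule identity rather than list
position makes the ranking invariant to permutations of the input files;
sharing the key across fingerprints of a repetition means fingerprints are
compared on identical tie decisions. All stochastic stages (training-list
sampling, tie keys, bootstrap, maxT sign-flips) derive per-stage substreams
from one master seed, so the whole pipeline is bit-reproducible.

## The statistical analysis

The global Friedman test uses targets as blocks and the per-target mean
ranks (over repetitions) as observations, with the tie-corrected chi-square
statistic on k − 1 degrees of freedom; it agrees with
`stats::friedman.test` exactly on tie-free data (asserted in the tests).

The post-hoc machinery makes two design choices that the literature leaves
open:

* **Joint bootstrap.** Each of the 100 bootstrap replicates resamples the
  repetition ranks *jointly* across fingerprints within a target,
  preserving the within-repetition correlation structure; resampling each
  fingerprint independently would destroy exactly the dependence the
  pairwise comparison relies on.
* **maxT null by sign-flipping.** Within a replicate the pair statistic is
  $T = |\sum_t d_t| / \sqrt{\sum_t d_t^2}$ on per-target mean-rank
  differences (studentized so pairs share a scale under the max step). The
  null distribution flips the sign of whole target rows, again jointly
  across pairs; the adjusted p-value of a pair is the fraction of
  `n_adjust_resamples` (default 1000) flips whose maximum statistic over
  all pairs reaches the observed one. This reproduces the Westfall–Young
  maxT contract — adjusted ≥ raw, ordering preserved — which the suite
  asserts, along with calibration under an exchangeable null.

Each pair's 100 adjusted p-values are categorized against α = 0.05: "-"
(all below, highly significant), "X" (all above), "o" (mixed). With
sign-flip nulls the smallest attainable p-value is $2^{1-T}$ for T
targets, so clear "-" calls need roughly a dozen targets or more; small
studies will see "o" even under perfect dominance. When the global test is
not significant the post-hoc report is still computable but flagged
exploratory.

## Scaffold analysis

Bemis–Murcko frameworks are extracted as the 2-core of the heavy-atom graph
(iterative pruning of terminal atoms), i.e. ring systems plus linkers.
Framework keys are canonical graph labelings (BLISS) with element/charge
vertex colors; bond orders participate through an edge-subdivision
construction, and aromatic ring bonds share one bond code so that the
kekulization phase chosen by the parser cannot split identical frameworks.
Acyclic molecules share the sentinel key `"ACYCLIC"` and count as one
scaffold. The scaffold enrichment factor divides the distinct active
scaffolds in the top χ fraction by $\chi \cdot S$, where $S$ counts the
distinct scaffolds among the *test-set* actives of that repetition — the
convention that makes scaffold EF collapse exactly onto EF when every
active carries its own scaffold. (A full-active-list denominator is the
main alternative; it breaks that identity and mixes training information
into a test-set quantity.)

## The synthetic generator

`generate_target()` builds benchmark-shaped targets from an internal
library of 20 active and 10 decoy scaffold templates plus ~30 acyclic and 8
ring-bearing substituents, by string-level substitution — license-free,
deterministic per seed, and with every product SMILES parsable (tested).
Analog series share a framework and differ in acyclic decorations, so
`n_series` directly controls the scaffolds/actives ratio. The three styles
mirror the public collections' curation logic: MUV-like (30 maximally
diverse actives via MaxMin picking, embedded in many decoys), DUD-like
(analog series with decoys matched on heavy-atom count), ChEMBL-like
(diverse actives with exactly two decoys each passing the ECFC0
Dice > 0.5 atom-count rule). Defaults mirror the collections' sizes
(30/15000, 30/1080, 100/200). The `difficulty` knob sets the fraction of
decoys built from active scaffold templates; at 0 the structural separation
is clean, at 1 every decoy is a near-analog and mean AUC drops for every
screening fingerprint (asserted on seeded fixtures).

What the fixtures do *not* emulate: real physicochemical property matching
(only heavy-atom counts), MUV's descriptor-space spread-embedding
optimization, assay noise, and the structural breadth of real
collections. Green tests on fixtures therefore validate the machinery and
its statistical behaviour, not the empirical fingerprint ranking on real
data.

The curation operators themselves are first-class: `pick_diverse()` (greedy
MaxMin with seeded first pick), `select_decoys_by_atom_count()` (sampling
without replacement among eligible pool members, failing loudly and naming
the active when the pool is short), and `filter_compounds()` (MW ≤ 700
g/mol, metal exclusion, where a metal is any element outside H, B, C, N,
O, F, Si, P, S, Cl, Se, Br, I).

## Degenerate inputs and edge policies

* Metrics are undefined at n = 0 or n = N and error explicitly.
* Unparsable SMILES are retained as flagged records and excluded from
  scoring with a reported count — silently dropping them would change every
  metric denominator.
* Compound numbering is 0-based everywhere ("determined by list order");
  the choice is isolated behind the reader/writer.
* A repetition whose test set loses all valid actives raises a
  degenerate-repetition error naming target and repetition.
* `regress()` errors on zero variance in x and reports r = 0 for constant
  y.

## Problem sizes

The shipped tests and the acceptance script run entirely at desk scale, a
deliberate choice: metric identities are checked on exact closed forms and
exhaustive enumerations (e.g. all label placements for N ≤ 12), the
statistical properties on planted or exchangeable rank matrices (8–14
targets, 10–12 repetitions), and pipeline behaviour on synthetic targets of
10–30 actives and 30–90 decoys with 3–10 repetitions. The defaults
(R = 50, 5 queries, 20% training decoys) match the standard protocol and
are exercised for shape, determinism and counting guarantees.

## Known limitations

* Fingerprint implementations are faithful to their algorithm families but
  not bit-compatible with any other toolkit's hash functions; comparisons
  should stay within one toolkit, which is standard practice.
* OpenBabel's MACCS key definitions differ in detail from other public
  SMARTS sets; MACCS serves as a baseline, not as an exchange format.
* Formal charges are read from the molfile charge-code column; exotic
  charge encodings (property-block overrides) are not interpreted.
* The pairwise post-hoc test is the k = 2 Friedman reduction on per-target
  mean ranks; with few targets its discreteness limits attainable
  p-values, as noted above.
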