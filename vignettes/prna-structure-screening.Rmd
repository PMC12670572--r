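---
title: "Structure-first discovery of phage packaging RNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-first discovery of phage packaging RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prnascreen)
```

## The biological model

Phi29-like bacteriophages package their genome with an ATP-driven motor
whose moving part includes a ring of small non-coding packaging RNAs
(pRNAs). Three structural facts anchor everything this package does:

1. **The fold, not the sequence, is conserved.** pRNA domain 1 folds
   into a three-way junction (3WJ): a closing helix opens into a
   multiloop from which two further helices emanate, each arm carrying
   a loop — the right-hand (RH) and left-hand (LH) loops. Family
   members from different phages share this architecture while their
   primary sequences diverge freely.
2. **Subunits link hand-in-hand.** One subunit's RH loop base-pairs
   with the *next* subunit's LH loop. Mutation assays show a 3–4 bp
   Watson–Crick block suffices, that a 2 bp block works only when both
   pairs are G:C, and that natural blocks follow a GG:CC core with
   zero to two A/U additions. Evolution preserves pairing by
   compensatory covariation: a mutation in one loop is mirrored by the
   complementary mutation in its partner.
3. **The ring is a hexamer.** Mixtures of individually inactive loop
   variants regain activity when their loops cross-pair: a two-species
   mixture implies a ring size divisible by 2, a three-species mixture
   one divisible by 3, and joint consistency forces six.

`prnascreen` turns these facts into a testable pipeline: detect the
architecture, test the loop pairing, model the ring combinatorics, and
quantify conservation — exercised end to end on synthetic data with
known ground truth.

## Folding: base-pair maximization with an energy tie-break

`fold_max_pairing()` predicts pseudoknot-free structures by maximizing
the number of base pairs (dynamic programming over intervals, compiled
in C++), breaking ties first by the lowest additive pair energy
(G:C = −3, A:U = −2, G:U = −1, dimensionless) and then by a
deterministic traceback that pairs each 3′ base with its smallest
admissible 5′ partner. Hairpin loops must span at least `min_hairpin`
unpaired bases (default 3, the universal steric minimum); G:U wobble
pairs are allowed inside helices by default (standard RNA behaviour),
configurable.

This folder is intentionally *not* a nearest-neighbour thermodynamic
model. The pipeline's criteria are defined on structures — the presence
of a 3WJ, the loop inventory, loop-loop complementarity — and a
maximization objective with a deterministic tie-break makes every one
of those criteria oracle-testable: the test suite checks the fold
against exhaustive enumeration over all structures for short sequences
and against an independent recursion up to 25 nt. Where a user has a
thermodynamic prediction (or a crystal-informed structure), every
consumer accepts an externally supplied dot-bracket instead.

Two numerical conventions matter downstream. The fold *score* is the
total pair energy (more negative = more stable); the screen's
`score_threshold` (default −20) plays the significance-filter role.
All coordinates in result objects are 0-based half-open; only printing
converts to 1-based.

## Junctions, loops, and the pairing rules

`parse_junctions()` decomposes a structure into hairpin loops, internal
loops/bulges, multiloops and the exterior loop; every unpaired position
belongs to exactly one region (a property enforced by a randomized test
suite). A multiloop's degree counts the helices incident to it,
including its closing helix, and `has_3wj` requires degree exactly 3 —
"clear three-way junction" is operationalized as *exactly* three
emanating helices, neither more nor fewer.

`max_complementary_block()` performs the string search between two
loops: the longest contiguous antiparallel Watson–Crick block, ties
broken toward more G:C pairs, then the 5′-most offsets. Loop–loop
pairing is Watson–Crick only by default because the covariation logic
of the family is framed in WC complementarity; a G:U flag exists.
`predict_activity()` encodes the assay rules: active iff the block has
length ≥ 3 *and* a GG:CC core, or length exactly 2 with both pairs
G:C. Whether a ≥3 bp all-A/U block would function has never been
tested experimentally; requiring the core for long blocks is this
package's explicit assumption, surfaced in the `rule_fired` field so a
user can see which rule produced a call.

## Ring closure as graph combinatorics

A panel of loop variants becomes a directed graph: species u → v when
u's RH loop forms an active block with v's LH loop. Because an
experimental mixture supplies unlimited copies of each species, a ring
of n subunits is feasible iff the graph admits a *closed walk* of
length n — not merely a simple cycle — computed by boolean powers of
the adjacency matrix. `hexamer_verdict()` reports the feasible sizes up
to `max_n` (default 12, the hexamer plus one harmonic), the minimal
period, and whether a hexamer closes. The classic complementation
patterns fall out: a cross-complementary pair gives {2, 4, 6, …}, a
three-species cycle {3, 6, 9, …}, and `smallest_common_ring()` over
both mixtures returns 6.

## The genome screen

`scan_genome()` slides `window_len` windows (default 120 nt, the scale
of pRNA domain 1; step 10) over both strands and keeps a window when

* its fold score is at or below `score_threshold` (−20),
* the fold contains a 3WJ,
* no internal loop/bulge spans more than `max_bulge_span` (30 nt,
  honouring the folding constraint used for the family),
* some ordered pair of eligible loops (hairpin loops and
  internal-loop tracts of length 3–12) carries an active block of at
  least `min_block_len` (3), and
* window/template coverage is at least `min_coverage` (0.8).

No primary-sequence template is consulted anywhere — that is the point.
`naive_sequence_search()` provides the exact-substring baseline for
comparison, and `window_score_percentile()` an optional empirical null
(fold scores of dinucleotide-preserving shuffles, Altschul–Erickson
style, seeded) for users who want a calibrated filter rather than the
fixed threshold.

Two behaviours deserve honesty. First, base-pair maximization folds
random sequence into structure too, so the default screen has a
nonzero false-positive rate (window-level FP windows on i.i.d.
background; merging reduces them to loci). A screen tuned for
specificity should raise `min_block_len` to 4 or apply the shuffle
null. Second, `merge_candidates()` keeps the best-scoring window of
each transitively-overlapping cluster; on FP-dense backgrounds a chain
can link a true locus to neighbouring noise, so recall statistics in
the tests are computed on unmerged windows.

## The synthetic generator

`sample_prna()` draws family members from a fixed abstraction of the
architecture: closing helix of 9 bp, two arm helices of 8 bp, 6-nt RH
and LH loops, junction tracts of 2/3/2 nt with a fixed critical G (the
ATP-binding-relevant residue) in the central tract, and a designed
4-nt LH/RH block — GG or CC core centred, A/U additions at the edges —
mirrored between the loops as exact reverse complements. Three design
choices make the designed structure the *unique* max-pairing optimum in
practice: helix ends are pinned to G:C (so count-neutral "slippage"
alternatives lose the energy tie-break), loop free bases are drawn from
sets that exclude any intra-loop pair, and every draw is
rejection-sampled against the folder itself — a draw is accepted only
when folding recovers the 3WJ, both designed loops, and the designed
block as the active maximum. Acceptance is deterministic given the
seed.

`diverge()` models evolution. In compensatory mode a substitution at a
helix position applies the complementary substitution to its partner,
and a substitution inside the designed block swaps within its pair type
(G:C ↔ C:G, A:U ↔ U:A), preserving block length, core, and hence the
activity call; draws whose mutated free positions would refold the
molecule away from the designed architecture are redrawn, on the view
that selection purges fold-breaking mutations in a family whose
function requires the fold. In non-compensatory mode every site mutates
independently, degrading helices and pairing — the contrast that makes
the screen's structure-over-sequence claim measurable.

`make_alignment()` produces annotated family alignments: because
all rows share the scaffold coordinates they are aligned by
construction, and the designed regions become the feature map (Bulge1 =
RH loop, Bulge2 = central junction tract, Bulge3 = LH loop, critical_G,
3WJ = junction tracts). Pairwise-distinct bulge strings are achieved by
cycling rows through the block's 16 pair-type-preserving swap variants
and redrawing loop free bases on collisions; rows of an alignment are
never folded, so no structural re-validation applies there. Occupancy
options (`k` of `n` rows keep a feature) and critical-G variants
reproduce the 92%-style regimes exactly (100·k/n).

`make_loop_panel()` realizes the complementation-experiment tags. For
the cross tags it exploits an identity: the block between rh\_u and
lh\_v = revcomp(rh\_{v−1}) is determined by the common substrings of
rh\_u and rh\_{v−1}, so drawing each species' RH loop from a disjoint
"flavor" — {A,G} strings with a GG core, {U,C} strings with a CC core,
alternating G/C — guarantees that exactly the intended cycle edges are
active, for every seed; the result is still verified against the real
pairing rules.

### What the generator does and does not emulate

It emulates: a conserved 3WJ scaffold, complementary LH/RH loops with
the observed GG/CC ± A/U pattern, compensatory covariation, sequence
divergence at free sites, decoy genomic background and k-of-n feature
occupancy. It does not emulate: the full domain-1 helix inventory or
the CCA bulge geometry (the central tract is a simplified stand-in),
thermodynamic stabilities, real phage sequence composition, or 3D
structure. Tests passing on this generator therefore demonstrate the
pipeline's internal consistency and its structure-over-sequence
behaviour under the stated model of divergence — not performance on
real genomes, where fold heterogeneity and covariance-model-grade
search statistics would matter.

## Conservation statistics

For each annotated feature region, `existence_rate()` is the percentage
of rows whose feature columns are all non-gap, and `similarity_rate()`
the percentage of *occupied* rows matching the region's majority
string (ties broken lexicographically; a single occupied row scores
100 by convention; all-distinct regions score 0). The majority-string
definition was chosen because a single rule reproduces both observed
regimes — 0% for bulges that exist everywhere but never repeat a
sequence, and ~92% (46/50) for a near-universally conserved residue.
Comparison is case-insensitive with T ≡ U.

## Protein co-occurrence and distances

`local_align()` is exact Smith–Waterman with affine gaps
(BLOSUM62, gap existence 11 / extension 1 — the standard protein-search
parameterization), computed by Biostrings; the tests check it against
an independent plain-R affine DP. Query coverage is the aligned
fraction of the query; percent identity divides identical columns by
alignment columns (gaps in the denominator), with
`denominator = "reference"` exposing the alternative reading of
"divided by the total number of amino acids". Pass thresholds default
to 50% coverage and 25% identity; neither is prescribed by the source
experiments, so both are configuration.

`distance_matrix()` computes p or JC69 distances with pairwise deletion
(complete deletion via flag); JC69 is −(3/4)·ln(1 − 4p/3) and is
flagged infinite at saturation (p ≥ 3/4). `nj_tree()` wraps classical
neighbor joining (negative branch lengths clamped to 0 with a message)
and `patristic_report()` sums branch lengths to a reference leaf.
Maximum-likelihood inference is out of scope by design: the per-node
distance table is tree algebra, and `read_newick()` lets an externally
inferred tree (e.g. GTR ML) drop straight into the report.

## Problem sizes and reproducibility

All stochastic functions take an integer seed and restore the caller's
RNG state. The shipped test battery uses desk-scale sizes chosen once:
exhaustive fold enumeration on all length-5 sequences plus random
sequences to length 12 (and an independent recursion to length 25),
1,000 random loop pairs against the brute-force block search, 100
random additive trees for NJ round-trips, and the planted-genome
recall experiment at 20 seeds × 3 kb genomes × 30% compensatory
divergence, where structural recall is 1.0 and exact-substring recall
is 0.

## Known limitations

* The folder is a maximization model; its energies are ordinal
  stand-ins, and suboptimal ensembles are not enumerated. Filtering,
  not ranking, reproduces the selection criteria.
* Kissing interactions with bulged (non-contiguous) blocks are not
  searched.
* The screen's E-value analogue is a fixed score threshold plus an
  optional shuffle percentile, not a calibrated covariance-model
  statistic.
* Ring feasibility treats any closed walk as a ring; heterogeneous
  rings beyond planned alternation are permitted by the model even
  though the experiments never assert them.
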