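# prnascreen

Structure-based discovery and analysis of bacteriophage packaging RNAs
(pRNAs) in R.

The dsDNA-packaging motor of phi29-like bacteriophages is geared by a
small non-coding RNA whose primary sequence drifts rapidly while its
secondary structure is conserved: a thermodynamically stable three-way
junction (3WJ) flanked by two hairpin arms whose right-hand (RH) and
left-hand (LH) loops pair intermolecularly ("hand-in-hand") to close a
hexameric ring around the motor. Because the sequence diverges while the
fold persists, primary-sequence search (exact or BLAST-like) misses
family members that a structure-driven screen recovers.

`prnascreen` implements that screen and its downstream analyses:

* **Folding and junction detection** — `fold_max_pairing()` predicts a
  pseudoknot-free structure by base-pair maximization (Nussinov-style
  dynamic programming in C++, G:C = −3 / A:U = −2 / G:U = −1 energy
  tie-break, deterministic traceback); `parse_junctions()` decomposes it
  into hairpins, internal loops/bulges and multiloops, and flags the
  3WJ (a multiloop of degree exactly 3). Externally predicted
  structures can be supplied as dot-bracket wherever a fold is an input.
* **Loop pairing and activity rules** — `max_complementary_block()` is
  the string search for the longest antiparallel Watson–Crick block
  between an RH and an LH loop; `classify_pattern()` detects the
  recurring GG:CC core with 0–2 A/U additions; `predict_activity()`
  encodes the mutation-assay rules (a lone GG:CC pairing is sufficient;
  two A:U pairs are not; longer blocks need the GG:CC core).
* **Ring-closure stoichiometry** — `build_pairing_graph()` turns a panel
  of loop variants into a directed graph (edge u→v when u's RH loop
  actively pairs v's LH loop); `feasible_ring_sizes()` /
  `hexamer_verdict()` give the closed-walk ring sizes and minimal
  period; `smallest_common_ring()` combines mixtures (periods 2 and 3
  force a hexamer).
* **Genome screening** — `scan_genome()` slides windows over both
  strands and keeps windows with a qualifying fold score, a 3WJ, no
  oversized internal loop, and an active LH/RH pair; plus candidate
  merging, BED6-compatible TSV reports, an exact-substring baseline and
  a dinucleotide-shuffle empirical null.
* **Conservation statistics** — `existence_rate()` and
  `similarity_rate()` per annotated feature region (Bulge1/Bulge2/
  Bulge3/critical G/3WJ), with `table1_report()` for the
  function-vs-sequence conservation table.
* **Motor-protein co-occurrence** — `motor_component_check()` verifies
  homologs of the connector (gp10) and the packaging ATPase (gp16) by
  exact Smith–Waterman local alignment (BLOSUM62, gap 11/1), reporting
  query coverage and percent identity.
* **Phylogenetic distances** — `distance_matrix()` (p / JC69,
  substitutions per site), `nj_tree()` (neighbor joining) and
  `patristic_report()` (per-leaf distances to a reference such as
  phi29), with Newick I/O for externally inferred trees.
* **Synthetic data with ground truth** — `sample_prna()`, `diverge()`
  (compensatory covariation or free mutation), `plant_in_genome()`,
  `make_alignment()` and `make_loop_panel()` generate every input the
  pipeline consumes, with truth recorded.

## Worked example

```r
library(prnascreen)

# a synthetic pRNA with the conserved architecture
p <- sample_prna(seed = 1)
p
#> <prna_instance> prna, 69 nt, designed block ACCA:UGGU
parse_junctions(fold_max_pairing(p$record))
#> <junction_report> 2 hairpin(s), 2 internal loop(s)/bulge(s), 1 multiloop(s); has_3wj = TRUE

# complementation mixture of two individually inactive loop variants
pair <- make_loop_panel("cross_pair", seed = 1)
pair$species[, c("name", "rh", "lh")]
#>   name   rh   lh
#> 1  A/i GGAA AGGG
#> 2  I/a CCCU UUCC
hexamer_verdict(pair$species[, c("name", "rh", "lh")])
#> <ring_verdict> feasible sizes: 2,4,6,8,10,12; minimal cycle: 2; hexamer_active: TRUE

# mixing a period-2 and a period-3 panel forces a hexamer
trip <- make_loop_panel("cross_triplet", seed = 1)
smallest_common_ring(list(pair$species[, c("name", "rh", "lh")],
                          trip$species[, c("name", "rh", "lh")]))
#> [1] 6

# conservation table for a 50-member family with paired but pairwise
# distinct LH/RH bulges
table1_report(make_alignment(50, seed = 1))
#>      feature existence_rate similarity_rate n_rows
#> 1     Bulge1            100               0     50
#> 2     Bulge2            100              36     50
#> 3     Bulge3            100               0     50
#> 4 critical_G            100             100     50
#> 5        3WJ            100               8     50

# structure-driven screen of a genome with one planted, 30%-diverged
# family member
d <- diverge(p, 0.3, compensatory = TRUE, seed = 101)
pg <- plant_in_genome(list(d), genome_len = 3000, seed = 201)
cands <- merge_candidates(scan_genome(pg$genome,
                                      template_len = nchar(d$record$residues)))
head(screen_report(cands), 1)
#>         genome_id start end strand fold_score coverage block_len block_rh block_lh gg_cc_core n_au_additions
#> 1 synthetic_genome   560 680      +       -115        1         4     UGGU     ACCA       TRUE              2
pg$truth
#>   start end strand family_id
#> 1   561 630      + prna_d101
```

The screen's top candidate window covers the planted locus
(truth `[561, 630)`), even though the planted copy differs from the
family reference at ~30% of its sites — exact-substring search finds
nothing here. Candidate coordinates are 0-based half-open; `fold_score`
is the additive pair-energy stand-in (more negative = more stable);
`block_*` columns describe the maximal LH/RH complementary block and its
GG:CC-core pattern. Existence 100% with similarity 0% in the
conservation table is the signature the screen exploits: every family
member *has* paired bulges, no two share their sequence.

A thin command-line wrapper with `fold`, `screen`, `loops`, `ring`,
`conserve`, `phylo` and `simulate` subcommands is installed at
`inst/exec/prnascreen`.

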