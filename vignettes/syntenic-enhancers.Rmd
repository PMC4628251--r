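---
title: "Finding syntenic enhancers with divergent sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding syntenic enhancers with divergent sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sef)
```

## The problem

Many enhancers keep their regulatory function over hundreds of millions of
years while their sequences drift beyond the reach of alignment: binding
sites for the same transcription factors are gained, lost and reordered
(stabilizing selection with TFBS turnover), so the element stays active in
the same tissues even though no aligner can pair its bases across distant
species.  Conservation-based enhancer scans are blind to this class.
`sef` implements a search strategy that does not require the enhancer
sequences themselves to align.  The idea is to exploit synteny at the
intron level:

1. pick several groups of closely related species (a rodent-like, a
   bird-like and a fish-like clade) whose genomes align well *within* each
   group and whose exons — but not introns — align *between* groups;
2. restrict attention to introns whose orthology across the group
   references can be established unambiguously by matching the two
   bracketing exons;
3. call conserved elements (ECRs) inside those introns *within* each group
   with a phylogenetic hidden Markov model;
4. discard every element that is also conserved *between* groups — those
   are ordinary conserved enhancers;
5. prioritize the remainder by the enhancer-associated histone mark
   (H3K4me1 without H3K4me3) and developmental Gene Ontology annotation.

Elements that survive sit at the same position of the same intron in all
groups but cannot be aligned across groups — candidates for functionally
homologous enhancers with divergent sequences.  The package also scores
zebrafish reporter-assay count tables for the downstream wet-lab readout
and searches candidate trios (fish/mouse/human) for short exactly shared
motifs with chance statistics.

## Coordinate conventions

Everything internal is 0-based half-open on the forward strand (the BED
convention).  GFF3 and browser-style `"chrN:a-b"` spans are 1-based
inclusive and converted exactly once, on ingest; the inclusive length
`b - a + 1` equals the half-open width.  MAF `s` lines on the minus strand
are normalized to forward-strand intervals at parse time, keeping the
strand as metadata.  Readers reject `start >= end` instead of clamping.

## The conservation model

Conserved-element calling follows the standard two-state phylo-HMM design:

* **Neutral model.** A fixed tree topology with branch lengths in
  substitutions/site and a reversible substitution model (HKY85 by
  default; JC69 for closed-form test oracles).  `fit_neutral()` estimates
  branch lengths (and κ; base frequencies are empirical) by maximizing
  the product of per-column Felsenstein pruning likelihoods with L-BFGS-B
  from a fixed start (all branches 0.1, κ = 2), so fits are
  deterministic.  The intended input is putatively neutral columns —
  4-fold degenerate coding sites in real data; the synthetic bundle ships
  a neutral-training alignment from intergenic spacers as the stand-in.
  Separate neutral models per chromosome class (autosome vs X) are
  supported via a chromosome→class map, because X divergence is lower and
  an autosomal model would inflate conservation scores there.
* **Conserved state.** The neutral model with every branch multiplied by
  ρ = 0.3 (configurable in (0,1)).
* **Transitions.** μ = 1/L with expected element length L = 45 bp and
  ν = μγ/(1−γ) with stationary conserved coverage γ = 0.3.  These two
  values are package choices near common phastCons-style conventions —
  the source method names the tool but not its transition settings — and
  are fully exposed in `conserved_state_model()`.
* **Decoding.** Emissions are pruning likelihoods per alignment column
  (gaps and Ns are missing data and are marginalized; a fully missing
  column has likelihood 1).  Elements are maximal runs of the *Viterbi*
  conserved state — Viterbi rather than posterior thresholding because it
  yields non-overlapping maximal segments directly — projected to
  reference coordinates (reference-gap columns stay in the chain but
  contribute no bases), kept at `min_ecr_length >= 10` bp.  The element
  score is the mean conserved-state posterior over its columns.  No
  minimum score threshold is applied; the length floor is an exposed
  default flagged for sensitivity analysis.

Overlapping calls are resolved by the stated 90 % rule: whenever two
regions overlap by more than 0.9 of either one's length, only the longer
survives (ties: higher score, then leftmost), applied transitively; the
result is invariant to input order.

## Cross-group subtraction

Two independent filters remove elements conserved between groups:

* **Alignment overlap** (`remove_aligned()`): one base pair of overlap
  with any between-reference pairwise alignment block removes the element.
* **Homology search** (`homology_search()`): a BLAT-style seed-and-extend
  scan of each element against the other reference genomes — exact
  11-mer seeds on both strands (enhancers are orientation-free), chained
  within 100 bp on a diagonal, extended ungapped at +1/−1 with an X-drop
  of 10.  A hit needs `score = matches − mismatches − gap_openings ≥ 30`
  and `identity ≥ 50 %`.  The score formula approximates BLAT's; only the
  two thresholds are fixed by the source method.  The X-drop value and
  both-strand search are package choices, exposed in `homology_config()`.

## Orthologous introns

`match_exons()` pairs exons of ortholog genes whose alignment-projected
spans overlap reciprocally (≥ 1 bp; no overlap fraction is imposed beyond
the identity confirmation) and whose ungapped aligned identity reaches
0.70.  Where one species lacks annotation, `project_exon()` accepts a
projection when some 100-bp window of aligned bases reaches 70 % identity
(whole-exon window for shorter exons) — the conventional 70 %/100 bp
conservation criterion.  `derive_introns()` then emits an orthologous
intron for every pair of pivot-adjacent matched exons whose partners are
adjacent in the *full* exon list of every species: an intervening
unmatched exon breaks bracketing, which is what makes the intron
orthology unambiguous.  Ambiguity (an exon with several partners,
inconsistent exon order) skips the candidate rather than guessing.

## Candidate selection

`group_syntenic()` keeps intron sets with at least one fully contained
element in every group (an element crossing an exon boundary is excluded
with a warning).  `mark_filter()` partitions elements into marked
(overlaps H3K4me1, not H3K4me3, at ≥ 1 bp — the same 1-bp convention as
the subtraction step), unmarked, and both-marked (tracked separately, as
promoter-overlapping cases are in the source data); groups without mark
data (the bird-like clade) pass through with a notice.  `prioritize()`
caps per-group counts at 3 (the documented stricter selection used 2;
both are one `selection_config()` argument away), requires a configured
GO term — exact label match against the supplied table, no ontology
traversal; ancestor expansion is a documented pre-processing step outside
the tool — and ranks by (groups with marked elements, then single-element
groups) to favor univocal correspondence.  The GO lookup is keyed by one
species' gene id (the pivot reference by default); the source method does
not state which species' annotation was used.

## Shared-motif discovery

For a fish/mouse/human trio of candidate sequences:

1. `mask_simple_repeats()` soft-masks tandem repeats (unit 1-6, span
   ≥ 12 bp, ≥ 2.5 copies — the masker and its parameters are package
   choices, exposed); masked bases never participate in hits.
2. `find_exact_hits()` reports all maximal exact matches of length ≥ 7
   (the length of most TFBS) on both orientations.  Exact maximal matches
   replace word-seeded local alignment: at perfect identity and n ≥ 7 the
   two coincide, and exactness admits a brute-force O(n·m) oracle.  The
   per-region counts are counts of maximal matches (whether the source
   counted maximal matches or all ≥ 7 windows is not stated).
3. `intersect_threeway()` maps the mouse region to the human assembly
   through a pairwise alignment, recomputes fish-human hits on the mapped
   human sequence (mirroring the stepwise procedure), and reports
   fish-coordinate overlaps of ≥ 7 bp between the fish-mouse and
   fish-human hit sets; the shared string is the overlapping fish
   substring.
4. `chance_statistics()` computes the Karlin-Altschul expectation
   `E = m·n·2^(−13.9)` per pair (13.9 bits being the heptamer bitscore),
   the chance fraction `f = mean(min(E/O, 1))`, and the joint chance
   probability `f²` for a three-way shared motif — conservatively
   assuming the same chance alignments occur in both pairwise sets.
5. `match_pfm()` annotates shared n-mers against a MEME-format PFM
   database by mean per-aligned-column Euclidean distance over all
   full-overlap offsets and both strands.  Significance uses a
   permutation null (queries assembled from the database's pooled
   columns, 10 000 draws, fixed seed) and a Bonferroni-style E-value
   `p × (#PFMs)`, reported at E ≤ 0.1; among overlapping reported sites
   only the smallest E-value survives.  This is a stated simplification
   of TomTom, of which only the Euclidean distance choice is inherited.

## Reporter-assay scoring

`call_positive()` implements the 15 % rule: a construct is positive in a
(tissue, time point) if `(expressing − ectopic)/alive` minus the
empty-vector background proportion for that tissue and time reaches 0.15.
Ectopic fish are subtracted at the count level and the vector background
as a proportion, combining the two stated forms of the rule; evaluation
is per (tissue, time), the finest granularity the assay tables support.
`cross_species_consistency()` intersects call sets after tissue-synonym
normalization (shipping `olfactory bulb ↔ olfactory epithelium`, the
epithelium being the sensory component of the bulb); a pair is
functionally homologous when the intersection is non-empty.  The package
ships the validation panel — coordinates and expression annotations of
the tested zebrafish and mouse constructs — as plain TSVs; running the
consistency logic over them yields the five functionally homologous
enhancers (6, 7, 10, 11, 12) and their shared tissues, and those five
pairs drive the chance-expectation report in `scripts/acceptance.R`.

## The synthetic world

`generate_study()` emulates the input universe with planted ground truth.
Its defaults are fixed once and state the world the tests probe:

* three groups (4 rodent-like, 3 bird-like, 5 fish-like species) with
  within-group neutral tree lengths of 0.60, 0.50 and 0.78
  substitutions/site — deep enough that neutral intron sequence is
  informative for the HMM, shallow enough that exons stay alignable;
* genes of 4 exons × 150 bp with 1.5 kb introns; exons evolve at 0.2× the
  neutral rate within groups and diverge 0.07 substitutions/site per
  group from the common ancestor, giving ~80 % between-reference exon
  identity (comfortably above the 70 % confirmation threshold, which is
  the point: groups are "alignable at the exon level");
* 10 true elements of 200 bp in distinct introns, evolving at ρ = 0.3
  within groups, with *independently redrawn* sequence per group
  ("resample" divergence: it guarantees no detectable between-group
  conservation without simulating deep time) except at two planted
  8-mers per element, identical in all groups with randomized strands;
* 3 decoy elements descending from a single shared ancestor (~94 %
  between-reference identity), which the cross-group cascade must remove;
* an outgroup annotation reference ("hs") 0.06 substitutions/site from
  the first group's reference, giving the genome-wide pairwise alignment
  used for human-sequence extraction — motif positions are masked on
  that branch too, so planted motifs are three-way recoverable;
* H3K4me1 peaks over 70 % of true elements and H3K4me3 over 10 % of
  those (mark data only for the first and last group's references,
  mirroring the missing bird data);
* reporter tables as binomial draws: ~100 injected embryos, 90 %
  survival, per-tissue expression 0.30 above a 0.02 background with an
  8 % ectopic fraction — strong-enhancer rates for which the 15 % rule
  is informative but not trivially saturated.

The indel process is deletion-only (a deletion becomes an inherited gap),
which keeps the true alignment in root coordinates; it is off by default
because the HMM treats gaps as missing data.  Everything is a pure
function of `(config, seed)`; the determinism test compares bytes on
disk.

What the generator does **not** emulate: real chromatin-state structure,
codon-aware exon evolution, rearrangements, assembly gaps, alignment
error.  A green planted-signal test therefore establishes that the
pipeline's logic recovers what its model assumes — not that the model
captures real genomes.

## Numerical choices and degenerate inputs

* Forward-backward is scaled per column; Viterbi runs in log space;
  posteriors of the two states sum to 1 within 1e−9.
* Likelihoods are floored at 1e−300 inside logs; HKY85 transition
  matrices come from a symmetrized eigendecomposition (the model is
  reversible) with tiny negative entries clipped to 0.
* `fit_neutral()` requires ≥ 500 columns and warns when it fits at the
  zero-branch-length boundary (all-identical columns).
* `map_interval()` returns nothing when under half the bases map
  (`min_mapped_fraction = 0.5`, a package default; the source is silent
  on partial mappability).
* Empty alignments, regions outside all blocks, targets shorter than the
  seed word, and dead clutches (0 fish alive) all degrade to empty
  results with notices, never errors.

## Known limitations

* The homology search implements ungapped extension with single-diagonal
  chaining — adequate for the ~200 bp elements screened here, not a full
  BLAT replacement (no translated search, no gapped chaining across
  distant diagonals).
* The PFM E-value is a Bonferroni bound on a permutation p-value, not
  TomTom's analytic null; reported E-values are comparable within a run,
  not across databases.
* `derive_introns()` applies no gene-level completeness filter (how many
  exons may fail to match before a gene is dropped is unstated in the
  source method); every bracketing pair stands on its own.
* Genome-scale element counts from real assemblies are out of reach at
  desk scale by design; the acceptance suite substitutes property-based
  checks on the synthetic world plus the in-text chance-statistics and
  consistency computations.
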