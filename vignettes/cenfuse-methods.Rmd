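---
title: "cenfuse: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cenfuse: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cenfuse` characterizes centromeric satellite DNA arrays and traces the
origin of Robertsonian (centric) fusion chromosomes from their donor
centromeres. This vignette documents the models, the parameters that
matter, the numerical choices, and what the synthetic-data validation
does and does not establish.

## The biological setting

Acrocentric chromosomes of cattle-like bovids carry a ~1.4-kb satellite
repeat (satellite I, the "1.715" family) at their centromeres. A
Robertsonian fusion joins two such chromosomes; the fused centromere
retains blocks of monomers from each donor array, recognizable by high
consensus identity, and often in inverted orientation at the flanks of
the fusion region. The analysis therefore proceeds bottom-up: find the
monomers, group them into higher-order-repeat (HOR)-like blocks, compare
block consensuses between the fused chromosome and its candidate donors,
and summarize sequence evolution (CENP-B box conservation,
transition/transversion spectra, saturation, monomer trees).

## Pairwise alignment

All sequence comparison rests on one affine-gap aligner (Rcpp, single
pass of the three-state Gotoh recursion with byte-packed traceback):

* scoring: match +1, mismatch −1, gap opening −2, gap extension −1; a gap
  of length $L$ contributes $\mathrm{open} + L\cdot\mathrm{ext}$. These
  are package defaults exposed via `align_params()` — satellite-search
  studies rarely report their aligner settings, so nothing in the method
  depends on these exact values.
* identity: matching columns divided by **all** alignment columns, gap
  columns included in the denominator (closest to BLAST's
  "identities/length"). One definition, used everywhere.
* N never matches anything, including another N. N marks masked or
  unknown sequence; treating it conservatively biases identity downward,
  never upward.
* ambiguity codes: in the default ("strict") mode, IUPAC ambiguity codes
  also never match — genomic sequence should not contain them. In the
  *IUPAC-aware* mode, used for every comparison in which one side is a
  consensus, two codes match when their base sets intersect (Y matches T,
  R matches A); N still matches nothing. The rationale: the consensus
  builder writes an ambiguity code wherever a column ties, so a
  two-member consensus of ~10%-divergent monomers is ~10% ambiguity
  codes. Scoring those as mismatches would make a member fail the very
  consensus built from it, and segmentation would shatter planted blocks
  (we observed 3 planted blocks reported as 8 before adopting this rule).
  Set intersection is the same semantics the degenerate-motif scanner
  uses.
* tie-breaks: on equal DP scores the aligner prefers the diagonal state,
  then the query-gap state; the best local cell is the first maximum in
  row-major order, which selects the leftmost copy among identical tandem
  hits. One caveat follows from co-optimality: for essentially random
  pairs, two optimal alignments can differ in identity (a 4-column
  perfect match and a 6-column 5/6 alignment can score equally), so
  identity is only guaranteed symmetric under argument swap when the
  optimum is unique — which it is, overwhelmingly, for the related
  sequences this package compares. Scores are always symmetric.

The multiple aligner is center-star: the member with the highest mean
pairwise identity anchors the merge (ties broken by input order). For
monomers that are ≥85% identical this is accurate, deterministic and
linear in the number of members; it is not a general-purpose MSA.

## Monomer scanning

`find_monomers()` greedily takes the best local alignment of the
reference monomer against the still-unmasked source (both strands), emits
it if identity ≥ `min_identity` (default 0.70) and reference coverage ≥
`min_coverage` (default 0.90, the operational definition of
"full-length"), masks the interval with N either way, and repeats until
the best score falls below
$L \cdot \mathrm{min\_coverage} \cdot (2\,\mathrm{min\_identity} - 1)$ —
the score of the weakest hit that could still pass. Masking non-passing
hits too matters: a high-scoring truncated edge copy must not shadow
lower-scoring diverged full monomers. Because a terminal run of
negatively-scoring columns can never be part of an optimal local
alignment, emitted intervals are strictly non-overlapping.

Monomer sequences are stored reference-oriented (minus-strand hits
reverse-complemented) so all downstream identity comparisons are
strand-free; the strand column preserves genomic orientation.

The source study reports specific monomer counts on real chromosomes
without stating the thresholds that produced them; such counts are
parameter-dependent and are deliberately not validation targets here.

## Block segmentation and provenance

`segment_blocks()` walks the monomer array left to right. A monomer
extends the current block iff (i) same strand, (ii) genomic gap to its
predecessor ≤ `max_intra_gap` (default 100 bp — larger gaps become
insertion records and end the block; the literature shows insertions
"interspersed" without a length rule, so the default is our choice), and
(iii) IUPAC-aware global identity to the block's *running consensus* ≥
`min_block_identity` (default 0.85, the conventional HOR criterion).
Testing against the running consensus rather than the previous monomer
makes the rule robust to a single divergent member and keeps the
procedure deterministic. Consensus ties become IUPAC codes (never an
arbitrary base), so the consensus is member-order independent;
gap-majority columns are dropped; singleton blocks are allowed.

`infer_provenance()` aligns each fused-block consensus against every
donor-block consensus on both strands and assigns the maximum-identity
donor, reporting the runner-up and flagging ties (identity difference
< 1e−9) instead of breaking them silently. Because all consensuses are
reference-oriented, the orientation relation records sequence sense;
genomic orientation lives in the block table.

## CENP-B box analysis

The canonical CENP-B box consensus `NTTCGNNNNANNCGGGN` carries nine
unambiguous positions — the core nucleotides required for DNA binding —
and the default core mask is exactly the set of plain-base positions.
Scanning reports every window (both strands) with at most `max_mismatch`
non-intersecting positions (default 4, the conventional allowance in
CENP-B-box surveys); overlapping hits are all reported. Differences are
classified transition/transversion only when every cross-pair of the two
IUPAC sets falls in one class, otherwise "ambiguous" — never guessed.
`compare_core()` applies the same logic at core positions only; on the
proposed bovine motif vs the canonical consensus it reports three
transitions (two G/A, one T/C), and one G/A transition for the relaxed
element comparison.

## Divergence, saturation, trees

* Substitution spectra count gap columns as deletions and exclude them
  (pairwise deletion, the MEGA-style default), likewise ambiguous
  columns; percentages are rounded half-up to two decimals.
* p-distance = differing columns / compared columns, pairwise deletion.
  Equal-length inputs are treated as already aligned (the simulator
  introduces no indels); unequal-length inputs go through the aligner.
* Saturation: for all sequence pairs, transition and transversion counts
  are regressed (OLS) on p-distance separately over the lower and upper
  halves of the pairs (median split); a class is flagged saturated when
  the upper-half slope is below `saturation_ratio_threshold` (default
  0.5) times the lower-half slope. This slope-ratio heuristic is
  deliberately simple; entropy-based tests are out of scope. Two
  subtleties are worth recording. First, the class that saturates is the
  *abundant* one: multiple hits pile up where substitutions are frequent.
  The source study observes transversion-dominated substitution with
  transversions saturating and transitions linear, so the validation
  ladder uses strong transversion excess; a transition-excess ladder
  would flag transitions instead. Second, a ladder must actually reach
  the saturated regime for the flag to be meaningful: at ~0.7 expected
  substitutions per site the observed transversion fraction is still far
  from its plateau and the ratio correctly stays high; the test ladder
  therefore runs to ~4.8 expected substitutions per site.
* Neighbor joining is the textbook algorithm with negative branch
  lengths clamped to zero, a trifurcation at the final join, and
  whitespace-to-underscore label sanitization. It reconstructs additive
  matrices exactly (machine precision), which the tests verify directly,
  and its topologies match an independent implementation on random
  additive-plus-noise matrices.

## The simulator and what a green test establishes

`simulate_array()` generates: one ancestral monomer (default 1400 bp,
GC 0.5) → per-block consensus mutated `divergence_from_ancestor` from it
(default 0.10 per site, giving ~19% expected divergence between blocks)
→ per-monomer mutation at `intra_block_divergence` (default 0.05,
i.e. ~10% between constituents — inside the 3–15% range reported for
these arrays and above the 85% within-block identity criterion) →
orientation per block → concatenation with uniform-random insertions
(default 200–500 bp; random sequence, so insertions can never pass the
identity threshold) and 500-bp non-satellite flanks. The substitution
model is i.i.d. per site with two parameters (divergence, Ts:Tv ratio R;
transition probability R/(R+1), default R = 2): expectations stay
closed-form, which is what the count-based statistics consume. No indels
inside monomers, no concerted-evolution dynamics (unequal crossover),
no GC heterogeneity — so recovery tests validate the *inference
machinery*, not robustness to every feature of real satellite DNA.

`simulate_fusion()` gives both donors one shared ancestor (they are the
same satellite family), copies planned donor blocks into the fused array
(default plan: donor B's terminal inverted blocks flanking donor A's
second, forward block), and mutates each copied monomer independently at
`post_fusion_divergence` (default 0.05). One consequence, visible in the
pipeline output: monomers of a fused block are then ~19% divergent
pairwise (intra + post-fusion), below the 85% block criterion, so
segmentation of the *fused* array splits blocks finer than the plan while
provenance per split block remains correct — and the block *consensus*
averages the independent post-fusion noise back out, which is why
provenance identities sit near 99% rather than 95%. Real fused
centromeres, whose members share their post-fusion history, would not
show this split; the simulator trades that realism for closed-form
per-monomer expectations.

Validation (acceptance suite): with intra ≤ 5%, inter ≥ 15%, insertions
≥ 200 bp, over 50 seeds, monomer recall is ≥ 95% and block partitions
are exactly recovered in ≥ 95% of replicates; donor labels are correctly
assigned in ≥ 95% of 100 simulated fusions at 5% post-fusion divergence.
These runs use 700-bp monomers to stay inside a minutes-scale CPU
budget; divergences, insertion sizes and replicate counts are unchanged
from the stated world, and monomer length does not enter the identity
thresholds.

## Degenerate inputs and other conventions

Coordinates are 1-based inclusive internally; BED output is 0-based
half-open. Empty monomer sets produce empty (not missing) outputs; a
reference longer than its source yields an empty scan, not an error.
`substitution_spectrum()` of identical sequences reports a 0/0 sentinel
(proportions 0) rather than NaN. Anchor-table rows that fail type or
coordinate checks are dropped with line-numbered warnings; a missing
column is an error. Syntenic segmentation by default uses scaffold order
only (segment count = chromosome-label changes + 1); the
`strict_collinearity` flag additionally breaks runs at target-coordinate
direction flips, which is the only way a 7-segment structure with five
runs to one chromosome and two to the other can arise — maximal label
runs alone cap such a split at 4+3.

## Known limitations

Memory for one alignment is O(nm) bytes of traceback, sized for arrays
up to a few hundred kb against a ~1.4-kb reference — not for genome-scale
scans. The center-star MSA degrades below ~70% identity. The saturation
statistic needs a spread of pairwise distances (degenerate designs where
half the pairs share one distance value give a zero-slope half and no
flag). Identity under co-optimal alignments is tie-dependent, as noted
above. The CLI is a thin wrapper over the exported functions; workflow
managers should call the functions directly.
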