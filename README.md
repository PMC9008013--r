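# cenfuse

Centromeric satellite architecture and Robertsonian-fusion provenance.

Robertsonian (centric) fusions join two acrocentric chromosomes at their
centromeres, producing a single metacentric chromosome whose centromere is
a mosaic of the two donor satellite arrays. The bovine lineage is the
classic playground: cattle-like genomes carry the ~1.4-kb satellite I
(1.715 family) repeat at every acrocentric centromere, and fusion
chromosomes retain recognizable higher-order blocks of it from each donor.
`cenfuse` provides the desk-scale toolchain for this analysis:

- **Monomer scan** — detect full-length satellite monomers in a sequence
  by greedy iterative masking with an affine-gap Smith–Waterman aligner
  (Rcpp), on both strands, against a reference repeat unit.
- **Block decomposition** — segment the ordered monomer array into
  HOR-like blocks (same orientation, gap ≤ `max_intra_gap`, identity to
  the running block consensus ≥ 85% by default), reporting interspersed
  insertions.
- **Fusion provenance** — assign each block of a fused array to the donor
  block whose consensus it matches best, testing both orientations, with
  runner-up identities and explicit tie flags.
- **CENP-B box analysis** — degenerate (IUPAC) motif scanning with
  per-position mismatch classification, and core-position comparison
  between motifs (transitions vs transversions at the nine core binding
  nucleotides of `NTTCGNNNNANNCGGGN`).
- **Divergence statistics** — transition/transversion substitution
  spectra, p-distances with pairwise deletion, a slope-ratio substitution
  saturation assessment, and neighbor-joining trees
  (exact on additive matrices).
- **Simulator** — a seeded generator of satellite arrays, donor
  centromeres and fusion chromosomes with full ground truth (planted
  monomers, blocks, insertions, donor labels), used throughout the test
  suite.

## Worked example

Simulate a fusion bundle (two donors sharing one ancestral monomer; the
fused chromosome carries donor B's terminal inverted blocks around a
forward donor-A block), then scan, segment and infer provenance:

```r
library(cenfuse)

cfgs <- default_donor_configs(monomer_length = 700, seed = 42)
sim  <- simulate_fusion(cfgs$A, cfgs$B, post_fusion_divergence = 0.05, seed = 42)

ref  <- setNames(sim$fused$truth$ancestor, "satI_ref")
scfg <- scan_config(ref, min_identity = 0.70, min_coverage = 0.90)
mono <- filter_full_length(find_monomers(sim$donorB$seq, scfg), scfg)
segment_blocks(mono)
#> <block_set> 4 blocks, 3 insertions
#>   block_id start  end orientation n_members mean_pairwise_identity ...
#> 1        1   501 2600           -         3              0.8939114
#> 2        2  3027 5126           +         3              0.9076190
#> 3        3  5374 7473           +         3              0.9028571
#> 4        4  7722 9821           -         3              0.9028156

infer_provenance(truth_block_set(sim$fused),
                 truth_block_set(sim$donorA), truth_block_set(sim$donorB))
#>   fused_block_id donor_label donor_block_id  identity orientation_relation
#> 1              1           B              1 0.9871429                 same
#> 2              2           A              2 0.9900000                 same
#> 3              3           B              4 0.9900000                 same
#>   runner_up_identity   tie
#> 1          0.7991392 FALSE
#> 2          0.7985714 FALSE
#> 3          0.8077475 FALSE
```

The fused array's flanking blocks come back to donor B's terminal
inverted blocks and its middle block to donor A, each at ~99% consensus
identity versus ~80% for the runner-up — the signature that identifies a
centric-fusion centromere.

Motif and spectrum analysis on the published motifs:

```r
compare_core("YTCCAGWYRARGCAGGR", "NTTCGNNNNANNCGGGN")
#> <core_comparison> 3/9 core positions differ (3 Ts, 0 Tv, 0 ambiguous)
#>   position canonical observed      class pair
#> 1        3         T        C transition  T/C
#> 2        5         G        A transition  G/A
#> 3       14         G        A transition  G/A
```

The proposed bovine CENP-B-box-like motif differs from the canonical core
at three positions, all transitions (two G/A, one T/C) — the conserved
binding positions drift only by the least disruptive substitution class.

```r
sp <- substitution_spectrum(a, b)   # a pair with 34 Ts and 71 Tv
sp$prop_transitions; sp$prop_transversions
#> [1] 32.38
#> [1] 67.62
```

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli","cenfuse.R",package="cenfuse"))') \
    scan --ref ref.fa --in seq.fa --min-identity 0.7 --min-coverage 0.9 --out-prefix mono
```

Subcommands: `simulate scan blocks provenance motifs spectrum saturation
tree candidates full`. A YAML/JSON config file (`--config`) can supply any
flag; explicit flags win. `full` runs the whole pipeline and writes
BED/TSV/FASTA/newick stage outputs plus a `summary.json`.

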