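# Block segmentation, consensus building, homology matrices and
# fusion-provenance inference.

make_monomer_table <- function(seqs, starts, strands, source = "s") {
  k <- length(seqs)
  structure(data.frame(
    source_id = rep(source, k), index = seq_len(k) - 1L,
    start = as.integer(starts),
    end = as.integer(starts) + nchar(seqs) - 1L, strand = strands,
    ref_identity = rep(1, k), ref_coverage = rep(1, k), seq = seqs,
    stringsAsFactors = FALSE),
    class = c("monomer_table", "data.frame"))
}

test_that("identical abutting monomers form one block", {
  set.seed(1)
  m <- random_dna(200)
  tab <- make_monomer_table(rep(m, 6), seq(1, by = 200, length.out = 6),
                            rep("+", 6))
  bs <- segment_blocks(tab)
  expect_equal(nrow(bs$blocks), 1)
  expect_equal(bs$blocks$n_members, 6)
  expect_equal(bs$blocks$mean_pairwise_identity, 1)
  expect_equal(nrow(bs$insertions), 0)
  expect_identical(bs$blocks$consensus, m)
})

test_that("an orientation flip splits blocks", {
  set.seed(2)
  m <- random_dna(200)
  tab <- make_monomer_table(rep(m, 6), seq(1, by = 200, length.out = 6),
                            c(rep("+", 3), rep("-", 3)))
  bs <- segment_blocks(tab)
  expect_equal(nrow(bs$blocks), 2)
  expect_identical(bs$blocks$orientation, c("+", "-"))
  expect_equal(bs$blocks$n_members, c(3, 3))
})

test_that("empty monomer input yields empty outputs", {
  empty <- make_monomer_table(character(0), integer(0), character(0))
  bs <- segment_blocks(empty)
  expect_equal(nrow(bs$blocks), 0)
  expect_equal(nrow(bs$insertions), 0)
})

test_that("simulated three-block array is segmented at planted boundaries", {
  cfg <- sim_config(monomer_length = 300, seed = 7,
                    blocks = data.frame(n_monomers = c(3L, 4L, 3L),
                                        orientation = c("-", "+", "-"),
                                        divergence_from_ancestor = rep(0.1, 3)),
                    intra_block_divergence = 0.02,
                    insertion_length_range = c(300L, 300L))
  sim <- simulate_array(cfg)
  scfg <- scan_config(setNames(sim$truth$ancestor, "ref"))
  mono <- filter_full_length(find_monomers(sim$seq, scfg), scfg)
  bs <- segment_blocks(mono)
  expect_equal(nrow(bs$blocks), 3)
  expect_equal(bs$blocks$n_members, c(3, 4, 3))
  expect_identical(bs$blocks$orientation, c("-", "+", "-"))
  expect_equal(nrow(bs$insertions), 2)
  expect_true(all(bs$insertions$length >= 290))  # trimmed edges at most
  # blocks partition the monomers in genomic order
  expect_identical(unlist(bs$members), seq_len(nrow(mono)))
  # member partition matches the planted one
  for (b in 1:3) {
    expect_true(all(sim$truth$monomers$block_id[bs$members[[b]]] == b))
  }
})

test_that("within every emitted block members stay near the identity bound", {
  cfg <- sim_config(monomer_length = 300, seed = 8,
                    blocks = data.frame(n_monomers = c(4L, 4L),
                                        orientation = c("+", "+"),
                                        divergence_from_ancestor = c(0.1, 0.1)),
                    intra_block_divergence = 0.05)
  sim <- simulate_array(cfg)
  scfg <- scan_config(setNames(sim$truth$ancestor, "ref"))
  mono <- filter_full_length(find_monomers(sim$seq, scfg), scfg)
  bs <- segment_blocks(mono, min_block_identity = 0.85)
  for (b in seq_along(bs$member_seqs)) {
    seqs <- bs$member_seqs[[b]]
    if (length(seqs) < 2) next
    pid <- apply(utils::combn(length(seqs), 2), 2, function(p)
      global_identity(seqs[p[1]], seqs[p[2]]))
    expect_true(all(pid >= 0.85 - 0.02))
  }
})

test_that("segmentation mirrors under reverse complement of the source", {
  cfg <- sim_config(monomer_length = 250, seed = 9,
                    blocks = data.frame(n_monomers = c(3L, 5L),
                                        orientation = c("+", "-"),
                                        divergence_from_ancestor = c(0.1, 0.1)),
                    intra_block_divergence = 0.02)
  sim <- simulate_array(cfg)
  scfg <- scan_config(setNames(sim$truth$ancestor, "ref"))
  fwd <- segment_blocks(filter_full_length(find_monomers(sim$seq, scfg), scfg))
  rcs <- setNames(reverse_complement(sim$seq), "rc")
  rev <- segment_blocks(filter_full_length(find_monomers(rcs, scfg), scfg))
  expect_equal(nrow(rev$blocks), nrow(fwd$blocks))
  expect_equal(rev$blocks$n_members, rev(fwd$blocks$n_members))
  expect_identical(rev$blocks$orientation,
                   rev(ifelse(fwd$blocks$orientation == "+", "-", "+")))
})

test_that("block_consensus majority and tie rules", {
  expect_identical(block_consensus(c("ACG", "ACG", "ATG")), "ACG")
  expect_identical(block_consensus(c("AAG", "AGG")), "ARG")   # A/G tie -> R
  expect_identical(block_consensus(c("ACT", "AAT", "AGT", "ACT")), "ACT")
  expect_identical(block_consensus("TTTT"), "TTTT")           # single member
  # order independence through IUPAC ties
  expect_identical(block_consensus(c("AAG", "AGG")),
                   block_consensus(c("AGG", "AAG")))
})

test_that("block homology matrix detects orientation relations", {
  set.seed(10)
  a <- random_dna(300)
  b <- mutate_seq(a, 0.15)$seq
  h <- block_homology_matrix(c(x = a), c(y = a))
  expect_equal(h$identity[1, 1], 1.0)
  expect_identical(h$orientation[1, 1], "same")

  h <- block_homology_matrix(c(x = a), c(y = revcomp_naive(a)))
  expect_equal(h$identity[1, 1], 1.0)
  expect_identical(h$orientation[1, 1], "inverted")

  h <- block_homology_matrix(c(x = a, y = b), c(x = a, y = b))
  expect_equal(dim(h$identity), c(2, 2))
  expect_true(all(diag(h$identity) == 1))
  expect_true(all(h$identity[upper.tri(h$identity)] < 1))
})

test_that("provenance is exact for verbatim copies and flags symmetric ties", {
  set.seed(12)
  donA <- c(a1 = random_dna(250), a2 = random_dna(250))
  donB <- c(b1 = random_dna(250), b2 = random_dna(250))
  fused <- c(donB["b1"], donA["a2"], donB["b2"])
  prov <- infer_provenance(fused, donA, donB)
  expect_identical(prov$donor_label, c("B", "A", "B"))
  expect_equal(prov$donor_block_id, c(1, 2, 2))
  expect_equal(prov$identity, rep(1, 3))
  expect_false(any(prov$tie))

  # identical donors: every assignment is a tie
  prov <- infer_provenance(fused, donA, donA)
  expect_true(all(prov$tie[c(2)]))  # the donor-A block ties across donors
  expect_error(infer_provenance(fused, character(0), donB), "at least one")
})

test_that("provenance recovers the fusion plan from simulated data", {
  ok <- 0
  for (s in 1:10) {
    cfgs <- default_donor_configs(monomer_length = 300, seed = s)
    sim <- simulate_fusion(cfgs$A, cfgs$B, seed = s)
    prov <- infer_provenance(truth_block_set(sim$fused),
                             truth_block_set(sim$donorA),
                             truth_block_set(sim$donorB))
    if (identical(prov$donor_label, sim$plan$donor_label) &&
        identical(as.integer(prov$donor_block_id),
                  as.integer(sim$plan$donor_block))) ok <- ok + 1
  }
  expect_gte(ok, 9)
})
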