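# Simulator: determinism, base composition, substitution model, truth
# consistency, and the fusion plan.

test_that("simulate_monomer is seed-reproducible with correct composition", {
  expect_identical(simulate_monomer(500, seed = 3), simulate_monomer(500, seed = 3))
  expect_false(identical(simulate_monomer(500, seed = 3),
                         simulate_monomer(500, seed = 4)))
  gc_only <- simulate_monomer(300, gc = 1.0, seed = 5)
  expect_false(grepl("[AT]", gc_only))
  m <- simulate_monomer(10000, gc = 0.4, seed = 6)
  gc_obs <- nchar(gsub("[AT]", "", m)) / 10000
  expect_lt(abs(gc_obs - 0.4), 3 * sqrt(0.4 * 0.6 / 10000))
})

test_that("mutate_seq follows the two-parameter substitution model", {
  set.seed(1)
  anc <- random_dna(2000)
  same <- mutate_seq(anc, 0)
  expect_identical(same$seq, anc)
  expect_equal(nrow(same$records), 0)

  # ts_tv_ratio -> infinity: every substitution a transition
  res <- mutate_seq(anc, 0.2, ts_tv_ratio = 1e9)
  expect_true(all(res$records$class == "transition"))
  expect_true(all(res$records$to ==
                    c(A = "G", G = "A", C = "T", T = "C")[res$records$from]))

  # divergence 0.1, R = 2, length 1e4: transition fraction near 2/3
  anc <- random_dna(10000)
  res <- mutate_seq(anc, 0.1, ts_tv_ratio = 2)
  frac <- mean(res$records$class == "transition")
  se <- sqrt((2 / 3) * (1 / 3) / nrow(res$records))
  expect_lt(abs(frac - 2 / 3), 3 * se)
  # substitution count near the planted rate
  expect_lt(abs(nrow(res$records) / 10000 - 0.1),
            3 * sqrt(0.1 * 0.9 / 10000))
  # records describe the edit exactly
  chars_in <- strsplit(anc, "")[[1]]
  chars_out <- strsplit(res$seq, "")[[1]]
  expect_identical(which(chars_in != chars_out), res$records$position)
  expect_identical(chars_out[res$records$position], res$records$to)
})

test_that("simulate_array is deterministic and truth-consistent", {
  cfg <- sim_config(monomer_length = 200, seed = 77)
  a <- simulate_array(cfg)
  b <- simulate_array(cfg)
  expect_identical(a$seq, b$seq)
  expect_identical(a$truth$monomers, b$truth$monomers)

  # extracting truth intervals (reverse-complementing "-" monomers)
  # reproduces the recorded reference-oriented sequences exactly
  tr <- a$truth$monomers
  arr_seq <- unname(a$seq)
  for (r in seq_len(nrow(tr))) {
    piece <- substr(arr_seq, tr$start[r], tr$end[r])
    if (tr$strand[r] == "-") piece <- unname(reverse_complement(piece))
    expect_identical(piece, tr$seq[r])
  }
  # monomers + insertions + flanks tile the emitted sequence
  covered <- sum(tr$end - tr$start + 1) +
    sum(a$truth$insertions$end - a$truth$insertions$start + 1) +
    2 * cfg$flank_length
  expect_equal(covered, nchar(arr_seq))
  # insertion lengths respect the configured range
  expect_true(all(a$truth$insertions$length >= 200 &
                    a$truth$insertions$length <= 500))
})

test_that("single zero-divergence block yields a perfect tandem array", {
  cfg <- sim_config(monomer_length = 150, flank_length = 0,
                    blocks = data.frame(n_monomers = 4L, orientation = "+",
                                        divergence_from_ancestor = 0),
                    intra_block_divergence = 0, seed = 2)
  sim <- simulate_array(cfg)
  expect_identical(unname(sim$seq), strrep(sim$truth$ancestor, 4))
  expect_equal(unique(sim$truth$monomers$seq), sim$truth$ancestor)
})

test_that("the default fusion plan mirrors the terminal-inverted-block model", {
  sim <- simulate_fusion(default_donor_configs(monomer_length = 150)$A,
                         default_donor_configs(monomer_length = 150)$B,
                         seed = 5)
  expect_identical(sim$plan$donor_label, c("B", "A", "B"))
  fb <- sim$fused$truth$blocks
  expect_identical(fb$donor_label, c("B", "A", "B"))
  expect_identical(fb$orientation, c("-", "+", "-"))
  # donor-B terminal blocks flank the forward donor-A block
  expect_equal(fb$donor_block_id, c(1, 2, nrow(sim$donorB$truth$blocks)))

  # zero post-fusion divergence: fused blocks identical to donors
  sim0 <- simulate_fusion(default_donor_configs(monomer_length = 150)$A,
                          default_donor_configs(monomer_length = 150)$B,
                          post_fusion_divergence = 0, seed = 5)
  prov <- infer_provenance(truth_block_set(sim0$fused),
                           truth_block_set(sim0$donorA),
                           truth_block_set(sim0$donorB))
  expect_equal(prov$identity, rep(1, 3))
  expect_identical(prov$donor_label, sim0$plan$donor_label)

  # a plan referencing a missing donor block is a usage error
  bad_plan <- data.frame(donor_label = "A", donor_block = 99L)
  expect_error(simulate_fusion(plan = bad_plan, seed = 1), "missing donor block")
})

test_that("fusion bundles are byte-identical under a repeated seed", {
  a <- simulate_fusion(default_donor_configs(monomer_length = 120)$A,
                       default_donor_configs(monomer_length = 120)$B, seed = 9)
  b <- simulate_fusion(default_donor_configs(monomer_length = 120)$A,
                       default_donor_configs(monomer_length = 120)$B, seed = 9)
  expect_identical(a$fused$seq, b$fused$seq)
  expect_identical(a$donorA$seq, b$donorA$seq)
  expect_identical(a$fused$truth$monomers, b$fused$truth$monomers)

  # written outputs are reproducible text
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_sim(a, d1); write_sim(b, d2)
  for (tag in c("fused", "donorA", "donorB")) {
    expect_identical(readLines(paste0(d1, ".", tag, ".fa")),
                     readLines(paste0(d2, ".", tag, ".fa")))
    expect_identical(readLines(paste0(d1, ".", tag, ".truth.tsv")),
                     readLines(paste0(d2, ".", tag, ".truth.tsv")))
  }
})

test_that("sim_config validates its inputs", {
  expect_error(sim_config(monomer_length = 0))
  expect_error(sim_config(intra_block_divergence = 0.9))
  expect_error(sim_config(blocks = data.frame(n_monomers = 1L,
                                              orientation = "x",
                                              divergence_from_ancestor = 0)))
  expect_error(sim_config(insertion_length_range = c(500, 200)))
})
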