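# Substitution spectra, p-distances, saturation assessment and
# neighbor-joining trees.

test_that("classify_substitution is correct and symmetric", {
  expect_identical(classify_substitution("A", "G"), "transition")
  expect_identical(classify_substitution("C", "T"), "transition")
  expect_identical(classify_substitution("C", "A"), "transversion")
  pairs <- expand.grid(a = c("A", "C", "G", "T"), b = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  for (r in seq_len(nrow(pairs))) {
    expect_identical(classify_substitution(pairs$a[r], pairs$b[r]),
                     classify_substitution(pairs$b[r], pairs$a[r]))
  }
  expect_error(classify_substitution("A", "A"), "differ")
  expect_error(classify_substitution("A", "N"), "bases")
})

test_that("substitution_spectrum matches per-column enumeration on a toy pair", {
  # columns: A/A match, C/C match, G/A substitution (Ts), T/T match,
  # -/T deletion, A/C substitution (Tv)
  sp <- substitution_spectrum("ACGT-A", "ACATTC")
  expect_equal(sp$n_substitutions, 2)
  expect_equal(sp$n_transitions, 1)
  expect_equal(sp$n_transversions, 1)
  expect_equal(sp$n_deletions, 1)
  expect_equal(unname(sp$by_type["AG"]), 1)
  expect_equal(unname(sp$by_type["AC"]), 1)
  expect_equal(sp$n_sites_compared, 5)
  expect_error(substitution_spectrum("ACG", "AC"), "length")
})

test_that("spectrum proportions use half-up rounding and sum to 100", {
  a <- paste(c(rep("A", 34), rep("C", 71), rep("G", 60)), collapse = "")
  b <- paste(c(rep("G", 34), rep("A", 71), rep("G", 60)), collapse = "")
  sp <- substitution_spectrum(a, b)
  expect_equal(sp$n_transitions, 34)
  expect_equal(sp$n_transversions, 71)
  expect_equal(sp$prop_transitions, 32.38)
  expect_equal(sp$prop_transversions, 67.62)
  expect_equal(sp$prop_transitions + sp$prop_transversions, 100,
               tolerance = 0.0101)

  ident <- substitution_spectrum("ACGT", "ACGT")
  expect_equal(ident$n_substitutions, 0)
  expect_equal(ident$prop_transitions, 0)

  set.seed(3)
  for (i in 1:20) {
    x <- random_dna(500)
    y <- mutate_seq(x, 0.2)$seq
    sp <- substitution_spectrum(x, y)
    if (sp$n_substitutions > 0) {
      expect_equal(sp$prop_transitions + sp$prop_transversions, 100,
                   tolerance = 0.0101)
      expect_equal(sum(sp$by_type), sp$n_substitutions)
    }
    # column accounting: subs + identical + deletions + ambiguous = length
    expect_equal(sp$n_sites_compared + sp$n_deletions + sp$n_ambiguous,
                 nchar(x))
  }
})

test_that("p_distance counts differing columns with pairwise deletion", {
  expect_equal(p_distance("ACGTACGTAC", "ACGTACGTAC"), 0)
  expect_equal(p_distance("ACGTACGTAC", "ACGAACGAAC"), 0.2)
  expect_equal(p_distance("ACGT-ACGTA", "ACGTTACGTA"), 0)  # gap excluded
  set.seed(4)
  a <- random_dna(100); b <- random_dna(100)
  expect_equal(p_distance(a, b), p_distance(b, a))
  # unequal lengths go through the aligner
  x <- random_dna(200)
  y <- paste0(substr(x, 1, 90), substr(x, 101, 200))
  expect_lt(p_distance(x, y), 0.05)
})

test_that("p_distance approximates the planted substitution rate", {
  set.seed(5)
  devs <- replicate(30, {
    anc <- random_dna(1000)
    p_distance(anc, mutate_seq(anc, 0.05)$seq)
  })
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_true(all(abs(devs - 0.05) < 3 * se + 0.01))
  expect_lt(abs(mean(devs) - 0.05), 3 * se)
})

test_that("distance_matrix is symmetric, zero-diagonal and matches p_distance", {
  set.seed(6)
  seqs <- setNames(replicate(4, random_dna(150)), paste0("s", 1:4))
  d <- distance_matrix(seqs)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_equal(d["s1", "s3"], p_distance(seqs["s1"], seqs["s3"]))
  expect_error(distance_matrix(seqs[1]), "at least 2")
})

test_that("nj_tree reconstructs additive matrices exactly", {
  # 4 taxa: d(A,B)=2, d(C,D)=2, cross distances 4
  d4 <- matrix(4, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d4) <- 0; d4["A", "B"] <- d4["B", "A"] <- 2
  d4["C", "D"] <- d4["D", "C"] <- 2
  nwk <- nj_tree(d4)
  got <- newick_leaf_distances(nwk)
  expect_equal(got[rownames(d4), colnames(d4)], d4, tolerance = 1e-12)

  # 5-taxon caterpillar, unequal branch lengths
  skip_if_not_installed("ape")
  tr <- ape::read.tree(text = "((A:1,B:2):1.5,(C:0.5,(D:2,E:1):1):0.5);")
  d5 <- ape::cophenetic.phylo(tr)
  nwk <- nj_tree(d5)
  got <- newick_leaf_distances(nwk)
  expect_equal(got[rownames(d5), colnames(d5)], d5, tolerance = 1e-10)

  # 3 taxa: closed-form three-point solution
  d3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  got <- newick_leaf_distances(nj_tree(d3))
  expect_equal(got[rownames(d3), colnames(d3)], d3, tolerance = 1e-12)

  expect_error(nj_tree(d3[1:2, 1:2]), "at least 3")
})

test_that("nj_tree topology agrees with ape::nj on random matrices", {
  skip_if_not_installed("ape")
  set.seed(8)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    # random tree-derived (hence additive) distances plus tiny noise
    tr <- ape::rtree(n, br = stats::runif)
    d <- ape::cophenetic.phylo(tr)
    d <- d + matrix(stats::runif(n * n, 0, 1e-4), n, n)
    d <- (d + t(d)) / 2; diag(d) <- 0
    mine <- ape::read.tree(text = nj_tree(d))
    theirs <- ape::nj(as.dist(d))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(theirs)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("nj labels are sanitized and appear exactly once", {
  d <- matrix(c(0, 1, 2, 1, 0, 2, 2, 2, 0), 3, 3)
  rownames(d) <- colnames(d) <- c("tax one", "tax\ttwo", "three")
  nwk <- nj_tree(d)
  expect_match(nwk, "tax_one")
  expect_match(nwk, "tax_two")
  expect_equal(lengths(regmatches(nwk, gregexpr("tax_one", nwk))), 1)
})

test_that("monomers from distinct arrays cluster by source", {
  skip_if_not_installed("ape")
  ok <- 0
  for (s in 1:10) {
    set.seed(s + 100)
    anc <- random_dna(300)
    sources <- lapply(1:3, function(b) {
      cons <- mutate_seq(anc, 0.15)$seq
      setNames(replicate(3, mutate_seq(cons, 0.02)$seq),
               paste0("src", b, "_", 1:3))
    })
    seqs <- unlist(sources)
    tr <- ape::read.tree(text = nj_tree(distance_matrix(seqs, aligned = TRUE)))
    mono <- vapply(1:3, function(b) {
      ape::is.monophyletic(tr, paste0("src", b, "_", 1:3))
    }, logical(1))
    if (all(mono)) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("saturation flags transversions on a saturating ladder and nothing at low divergence", {
  # chain of repeated mutation rounds produces multiple hits at the same
  # sites; strong transversion excess (R = 0.05, ~95% transversions, the
  # class the satellite consensus comparison is dominated by) drives the
  # transversion count to its plateau while transitions keep accumulating.
  # Depths up to 60 rounds of 0.08 => ~4.8 expected substitutions/site at
  # the deepest rung: unambiguously in the saturated regime.
  set.seed(9)
  cur <- random_dna(4000)
  ladder <- c(d0 = cur)
  last <- 0
  for (d in c(2, 4, 8, 12, 18, 26, 36, 48, 60)) {
    for (k in seq_len(d - last)) cur <- mutate_seq(cur, 0.08,
                                                   ts_tv_ratio = 0.05)$seq
    ladder[paste0("d", d)] <- cur
    last <- d
  }
  sat <- saturation_analysis(ladder, aligned = TRUE)
  expect_true(sat$tv_saturated)
  expect_false(sat$ts_saturated)

  # divergence <= 1%: neither class saturated
  set.seed(10)
  cur <- random_dna(4000)
  low <- c(s0 = cur)
  for (k in 1:4) {
    cur <- mutate_seq(cur, 0.0025, ts_tv_ratio = 0.2)$seq
    low[paste0("s", k)] <- cur
  }
  sat <- saturation_analysis(low, aligned = TRUE)
  expect_false(sat$tv_saturated)
  expect_false(sat$ts_saturated)

  # all-identical input: zero slopes, no flags
  same <- setNames(rep(random_dna(200), 4), paste0("s", 1:4))
  sat <- saturation_analysis(same, aligned = TRUE)
  expect_equal(sat$ts_slope, 0)
  expect_equal(sat$tv_slope, 0)
  expect_false(sat$ts_saturated || sat$tv_saturated)
  expect_error(saturation_analysis(same[1:3]), "at least 4")
})
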