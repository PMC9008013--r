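# Independent oracles and small fixture builders. The oracles are pure-R
# re-derivations (exhaustive DP, brute-force window enumeration) kept
# deliberately separate from the package implementation paths they check.

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

revcomp_naive <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

# Exhaustive affine-gap Smith-Waterman oracle: full three-state DP with
# traceback, same tie preferences as the implementation (M > X > Y, gap
# extension over opening, first row-major maximum). Returns score and the
# identity of the traced optimal alignment.
sw_oracle <- function(q, t, match = 1, mismatch = -1,
                      gap_open = -2, gap_extend = -1) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  tc <- strsplit(t, "", fixed = TRUE)[[1]]
  n <- length(qc); m <- length(tc)
  NEG <- -1e9
  go <- gap_open + gap_extend; ge <- gap_extend
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, ] <- 0; M[, 1] <- 0
  srcM <- matrix(0L, n + 1, m + 1)  # 0 start, 1 M, 2 X, 3 Y
  fromM_X <- matrix(FALSE, n + 1, m + 1)
  fromM_Y <- matrix(FALSE, n + 1, m + 1)
  best <- 0; bi <- 0; bj <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (qc[i - 1] == tc[j - 1] &&
               qc[i - 1] %in% c("A", "C", "G", "T")) match else mismatch
      cand <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      k <- which.max(cand)
      diag <- cand[k]; src <- k
      if (diag < 0) { diag <- 0; src <- 0L }
      M[i, j] <- diag + s; srcM[i, j] <- src
      xo <- M[i - 1, j] + go; xe <- X[i - 1, j] + ge
      if (xo > xe) { X[i, j] <- xo; fromM_X[i, j] <- TRUE } else X[i, j] <- xe
      yo <- M[i, j - 1] + go; ye <- Y[i, j - 1] + ge
      if (yo > ye) { Y[i, j] <- yo; fromM_Y[i, j] <- TRUE } else Y[i, j] <- ye
      if (M[i, j] > best) { best <- M[i, j]; bi <- i; bj <- j }
    }
  }
  if (best <= 0) return(list(score = 0, identity = NA_real_))
  # traceback for identity
  i <- bi; j <- bj; state <- 1L
  ncols <- 0L; nmatch <- 0L
  repeat {
    if (state == 1L) {
      ncols <- ncols + 1L
      if (qc[i - 1] == tc[j - 1] && qc[i - 1] %in% c("A", "C", "G", "T")) {
        nmatch <- nmatch + 1L
      }
      src <- srcM[i, j]
      i <- i - 1L; j <- j - 1L
      if (src == 0L) break
      state <- src
      if (state == 1L && (i == 1L || j == 1L)) break # boundary zero cell
    } else if (state == 2L) {
      ncols <- ncols + 1L
      state <- if (fromM_X[i, j]) 1L else 2L
      i <- i - 1L
    } else {
      ncols <- ncols + 1L
      state <- if (fromM_Y[i, j]) 1L else 3L
      j <- j - 1L
    }
  }
  list(score = best, identity = nmatch / ncols)
}

# Brute-force degenerate-motif scan: enumerate every window on the
# requested strands, count non-intersecting positions via raw set algebra.
iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

motif_scan_oracle <- function(src, motif, max_mismatch, both_strands = TRUE) {
  L <- nchar(motif)
  mc <- strsplit(motif, "", fixed = TRUE)[[1]]
  hits <- list()
  scan <- function(s, strand) {
    n <- nchar(s)
    for (w in seq_len(n - L + 1L)) {
      win <- substr(s, w, w + L - 1L)
      wc <- strsplit(win, "", fixed = TRUE)[[1]]
      mm <- sum(vapply(seq_len(L), function(p)
        length(intersect(iupac_sets[[mc[p]]], iupac_sets[[wc[p]]])) == 0,
        logical(1)))
      if (mm <= max_mismatch) {
        start <- if (strand == "+") w else n - (w + L - 1L) + 1L
        hits[[length(hits) + 1L]] <<- data.frame(
          start = start, strand = strand, window = win,
          total_mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  scan(src, "+")
  if (both_strands) scan(revcomp_naive(src), "-")
  if (!length(hits)) {
    return(data.frame(start = integer(0), strand = character(0),
                      window = character(0), total_mismatches = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}

# Path distances between leaves of a newick tree, via ape.
newick_leaf_distances <- function(nwk) {
  tr <- ape::read.tree(text = nwk)
  ape::cophenetic.phylo(tr)
}

write_tmp_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  cenfuse::write_fasta(seqs, path)
  path
}
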