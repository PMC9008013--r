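# Core sequence model: plain named character vectors over {A,C,G,T,N},
# FASTA I/O via Biostrings, and the affine-gap pairwise alignment engine.

VALID_BASES <- c("A", "C", "G", "T", "N")

#' Normalize a nucleotide sequence
#'
#' Uppercases, maps U to T (RNA input) and validates that only characters
#' from the alphabet A, C, G, T, N remain.
#'
#' @param x Character vector of sequences.
#' @param id Optional identifier(s) used in error messages.
#' @return The normalized character vector (names preserved).
#' @export
normalize_seq <- function(x, id = names(x)) {
  if (is.null(id)) id <- as.character(seq_along(x))
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("record '", id[which(bad)[1]],
         "': invalid characters after normalization (alphabet is A/C/G/T/N)")
  }
  empty <- !nzchar(x)
  if (any(empty)) {
    stop("record '", id[which(empty)[1]], "': empty sequence")
  }
  x
}

#' Read a FASTA file into a named character vector
#'
#' One element per record, in file order; sequences are normalized with
#' [normalize_seq()] (uppercased, U mapped to T).
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("malformed FASTA '", path, "': empty header")
  if (anyDuplicated(ids)) {
    stop("malformed FASTA '", path, "': duplicated record id '",
         ids[anyDuplicated(ids)], "'")
  }
  seqs <- as.character(set)
  names(seqs) <- ids
  normalize_seq(seqs)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement
#'
#' N maps to N; an involution (applying twice returns the input).
#'
#' @param s Character vector of sequences (names preserved).
#' @return Reverse-complemented sequences.
#' @export
reverse_complement <- function(s) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
  names(out) <- names(s)
  out
}

#' Alignment scoring parameters
#'
#' Affine-gap scoring: a gap of length L contributes
#' `gap_open + L * gap_extend`. Defaults (+1/-1, -2/-1) are a deliberate
#' package-level choice; the satellite-search literature rarely reports the
#' exact aligner settings, so they are exposed here rather than hard-coded.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< match).
#' @param gap_open Gap opening score (<= 0).
#' @param gap_extend Gap extension score (<= 0).
#' @return An object of class `align_params`.
#' @export
align_params <- function(match = 1L, mismatch = -1L,
                         gap_open = -2L, gap_extend = -1L) {
  stopifnot(match > 0, mismatch < match, gap_open <= 0, gap_extend <= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "align_params")
}

# Permissive normalization for alignment inputs: consensus sequences may
# carry IUPAC ambiguity codes, which the aligner scores as mismatches.
.norm_iupac <- function(x, id = "sequence") {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  if (grepl("[^ACGTNRYSWKMBDHV]", x)) {
    stop("sequence '", id, "': invalid nucleotide characters")
  }
  if (!nzchar(x)) stop("sequence '", id, "': empty sequence")
  x
}

#' Identity of a gapped alignment
#'
#' Matching columns divided by total alignment columns; gap columns count in
#' the denominator and N matches nothing (BLAST-style "identities/length").
#'
#' @param a,b Gapped rows of equal length.
#' @param iupac Count columns whose IUPAC base sets intersect as matches
#'   (N still matches nothing); used for consensus-involved comparisons.
#' @return Fraction in \[0, 1\] (NA for an empty alignment).
#' @export
alignment_identity <- function(a, b, iupac = FALSE) {
  if (nchar(a) != nchar(b)) stop("gapped rows differ in length")
  if (nchar(a) == 0L) return(NA_real_)
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  if (!iupac) {
    return(sum(ca == cb & ca %in% c("A", "C", "G", "T")) / length(ca))
  }
  ok <- ca != "-" & cb != "-" & ca != "N" & cb != "N"
  hits <- ok
  hits[ok] <- iupac_sets_intersect(ca[ok], cb[ok])
  sum(hits) / length(ca)
}

.pairwise_raw <- function(query, target, params, type, iupac = FALSE) {
  .align_affine_cpp(query, target, params$match, params$mismatch,
                    params$gap_open, params$gap_extend, type, iupac)
}

#' Best local alignment of two sequences
#'
#' Affine-gap Smith-Waterman. With `both_strands = TRUE` the query is also
#' aligned in reverse complement and the higher-scoring strand is returned
#' (forward preferred on ties); coordinates are always reported on the
#' forward strands of both input sequences, 1-based inclusive.
#'
#' @param query,target Sequences (single character strings, optionally named).
#' @param params An [align_params()] object.
#' @param both_strands Also try the reverse-complemented query.
#' @param iupac IUPAC-aware scoring (ambiguity codes match by base-set
#'   intersection; N still matches nothing).
#' @return An object of class `alignment`: list with `query_id`, `target_id`,
#'   `query_start/end`, `target_start/end`, `strand`, `aligned_query`,
#'   `aligned_target`, `score`, `identity`.
#' @export
local_align <- function(query, target, params = align_params(),
                        both_strands = FALSE, iupac = FALSE) {
  qid <- if (!is.null(names(query))) names(query)[1] else "query"
  tid <- if (!is.null(names(target))) names(target)[1] else "target"
  q <- .norm_iupac(unname(query[1]), qid)
  t <- .norm_iupac(unname(target[1]), tid)
  fwd <- .pairwise_raw(q, t, params, "local", iupac)
  strand <- "+"
  res <- fwd
  if (both_strands) {
    rev <- .pairwise_raw(unname(reverse_complement(q)), t, params, "local",
                         iupac)
    if (rev$score > fwd$score) {
      res <- rev
      strand <- "-"
      qlen <- nchar(q)
      qs <- qlen - res$q_end + 1L
      qe <- qlen - res$q_start + 1L
      res$q_start <- qs
      res$q_end <- qe
    }
  }
  structure(list(
    query_id = qid, target_id = tid,
    query_start = res$q_start, query_end = res$q_end,
    target_start = res$t_start, target_end = res$t_end,
    strand = strand,
    aligned_query = res$aligned_q, aligned_target = res$aligned_t,
    score = res$score,
    identity = if (nchar(res$aligned_q) > 0)
      alignment_identity(res$aligned_q, res$aligned_t, iupac) else NA_real_
  ), class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %s[%d-%d] vs %s[%d-%d] strand %s score %d identity %s\n",
              x$query_id, x$query_start, x$query_end,
              x$target_id, x$target_start, x$target_end,
              x$strand, x$score,
              ifelse(is.na(x$identity), "NA", sprintf("%.3f", x$identity))))
  invisible(x)
}

#' Global (Needleman-Wunsch) alignment of two sequences
#'
#' End gaps are penalized; used for monomer-vs-consensus comparisons where
#' both sequences are expected to span the same repeat unit.
#'
#' @inheritParams local_align
#' @return An `alignment` object (strand always "+").
#' @export
global_align <- function(query, target, params = align_params(),
                         iupac = FALSE) {
  qid <- if (!is.null(names(query))) names(query)[1] else "query"
  tid <- if (!is.null(names(target))) names(target)[1] else "target"
  q <- .norm_iupac(unname(query[1]), qid)
  t <- .norm_iupac(unname(target[1]), tid)
  res <- .pairwise_raw(q, t, params, "global", iupac)
  structure(list(
    query_id = qid, target_id = tid,
    query_start = res$q_start, query_end = res$q_end,
    target_start = res$t_start, target_end = res$t_end,
    strand = "+",
    aligned_query = res$aligned_q, aligned_target = res$aligned_t,
    score = res$score,
    identity = alignment_identity(res$aligned_q, res$aligned_t, iupac)
  ), class = "alignment")
}

#' Identity of the global alignment of two sequences
#' @inheritParams global_align
#' @return Fraction in \[0, 1\].
#' @export
global_identity <- function(query, target, params = align_params(),
                            iupac = FALSE) {
  global_align(query, target, params, iupac)$identity
}

# Merge helper: per-alignment insertion counts before each center position
# (length L+1; slot L+1 = insertions after the last center position).
.center_gap_profile <- function(aligned_center, center_len) {
  cc <- strsplit(aligned_center, "", fixed = TRUE)[[1]]
  ins <- integer(center_len + 1L)
  pos <- 1L
  run <- 0L
  for (ch in cc) {
    if (ch == "-") {
      run <- run + 1L
    } else {
      ins[pos] <- run
      run <- 0L
      pos <- pos + 1L
    }
  }
  ins[center_len + 1L] <- run
  ins
}

#' Center-star multiple sequence alignment
#'
#' The center is the member with the highest mean pairwise global identity
#' (ties broken by input order); every other member is aligned to the center
#' globally and the pairwise gap patterns are merged. Cheap, deterministic
#' and adequate for satellite monomers that share >= 85% identity.
#'
#' @param members Character vector (>= 2) of sequences; names become row names.
#' @param params An [align_params()] object.
#' @return Character vector of gapped rows, all equal length; removing gaps
#'   from row i recovers member i exactly.
#' @export
multi_align <- function(members, params = align_params()) {
  k <- length(members)
  if (k < 2L) stop("multi_align needs at least 2 sequences")
  ids <- names(members)
  members <- vapply(seq_len(k), function(i)
    .norm_iupac(unname(members[i]),
                if (is.null(ids)) as.character(i) else ids[i]),
    character(1))
  if (k == 2L) {
    aln <- global_align(members[1], members[2], params)
    out <- c(aln$aligned_query, aln$aligned_target)
    names(out) <- ids
    return(out)
  }
  idm <- matrix(1, k, k)
  pair_alns <- vector("list", k * k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      a <- global_align(members[i], members[j], params)
      idm[i, j] <- idm[j, i] <- a$identity
    }
  }
  center <- which.max(colMeans(idm))
  clen <- nchar(members[center])
  others <- setdiff(seq_len(k), center)
  alns <- lapply(others, function(i)
    global_align(members[center], members[i], params))
  profiles <- lapply(alns, function(a) .center_gap_profile(a$aligned_query, clen))
  master <- Reduce(pmax, profiles)

  cchars <- strsplit(members[center], "", fixed = TRUE)[[1]]
  center_row <- character(clen + 1L)
  for (p in seq_len(clen)) {
    center_row[p] <- paste0(strrep("-", master[p]), cchars[p])
  }
  center_row[clen + 1L] <- strrep("-", master[clen + 1L])
  rows <- vector("list", k)
  rows[[center]] <- paste(center_row, collapse = "")
  for (z in seq_along(others)) {
    a <- alns[[z]]
    prof <- profiles[[z]]
    mc <- strsplit(a$aligned_query, "", fixed = TRUE)[[1]]
    mm <- strsplit(a$aligned_target, "", fixed = TRUE)[[1]]
    pieces <- character(clen + 1L)
    pos <- 1L   # next center position
    buf <- character(0)
    for (col in seq_along(mc)) {
      if (mc[col] == "-") {
        buf <- c(buf, mm[col])
      } else {
        pad <- master[pos] - prof[pos]
        pieces[pos] <- paste0(strrep("-", pad), paste(buf, collapse = ""), mm[col])
        buf <- character(0)
        pos <- pos + 1L
      }
    }
    pieces[clen + 1L] <- paste0(strrep("-", master[clen + 1L] - prof[clen + 1L]),
                                paste(buf, collapse = ""))
    rows[[others[z]]] <- paste(pieces, collapse = "")
  }
  out <- unlist(rows)
  names(out) <- ids
  out
}

#' Mean pairwise identity of an alignment
#'
#' @param rows Gapped rows of equal length (e.g. from [multi_align()]).
#' @return Mean over all row pairs of [alignment_identity()].
#' @export
msa_mean_identity <- function(rows) {
  k <- length(rows)
  if (k < 2L) return(NA_real_)
  ids <- utils::combn(k, 2)
  mean(apply(ids, 2, function(p) alignment_identity(rows[p[1]], rows[p[2]])))
}
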