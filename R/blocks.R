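# HOR-like block decomposition of a monomer array, block consensus
# building, and fusion-provenance inference by strand-aware consensus
# homology between a fused array and two candidate donor arrays.

#' Column-majority consensus of a set of sequences
#'
#' Members are multiply aligned ([multi_align()]); each column contributes
#' its majority base. A tie among bases yields the IUPAC ambiguity code of
#' the tied set (never an arbitrary base), so the consensus is independent
#' of member order. A column in which gaps hold a strict majority is
#' dropped; when gaps tie with bases the bases win.
#'
#' @param block_members Character vector (>= 1) of sequences.
#' @param params An [align_params()] object.
#' @return Consensus sequence (single character string, possibly containing
#'   IUPAC ambiguity codes).
#' @export
block_consensus <- function(block_members, params = align_params()) {
  if (length(block_members) == 0L) stop("no members")
  if (length(block_members) == 1L) return(unname(block_members[1]))
  rows <- multi_align(block_members, params)
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(ch) colSums(mat == ch),
                   numeric(ncol(mat)))          # L x 4
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  gaps <- colSums(mat == "-")
  nbase <- rowSums(counts)
  mx <- pmax(counts[, 1], counts[, 2], counts[, 3], counts[, 4])
  n_top <- rowSums(counts == mx & mx > 0)
  drop <- gaps > nbase                          # gap-majority columns vanish
  cons <- character(ncol(mat))
  single <- !drop & n_top == 1L
  cons[single] <- bases[max.col(counts, ties.method = "first")[single]]
  for (p in which(!drop & n_top > 1L)) {
    cons[p] <- iupac_union(bases[counts[p, ] == mx[p]])
  }
  cons[!drop & nbase == 0L] <- "N"              # all-N columns
  paste(cons[!drop], collapse = "")
}

#' Segment a monomer array into HOR-like blocks
#'
#' Deterministic left-to-right greedy segmentation: a monomer extends the
#' current block iff it shares the block's strand, its genomic gap to the
#' previous monomer is at most `max_intra_gap`, and its global-alignment
#' identity to the block's running consensus is at least
#' `min_block_identity`. Otherwise a new block starts. Inter-monomer gaps
#' longer than `max_intra_gap` are reported as insertions.
#'
#' @param monomers A `monomer_table` from [find_monomers()] (single source,
#'   sorted, non-overlapping).
#' @param min_block_identity Within-block identity threshold (default 0.85,
#'   the conventional HOR-array criterion).
#' @param max_intra_gap Largest genomic gap (bp) tolerated inside a block
#'   (default 100); larger gaps terminate the block and become `insertions`
#'   records.
#' @param params An [align_params()] object.
#' @return An object of class `block_set`: list with
#'   \describe{
#'     \item{blocks}{`data.frame`: `block_id`, `start`, `end`, `orientation`,
#'       `n_members`, `mean_pairwise_identity`, `divergence_min`,
#'       `divergence_max`, `consensus`.}
#'     \item{members}{list of integer vectors of monomer row indices.}
#'     \item{member_seqs}{list of character vectors (reference-oriented).}
#'     \item{insertions}{`data.frame`: `source_id`, `start`, `end`, `length`.}
#'   }
#' @export
segment_blocks <- function(monomers, min_block_identity = 0.85,
                           max_intra_gap = 100, params = align_params()) {
  empty <- structure(list(
    blocks = data.frame(block_id = integer(0), start = integer(0),
                        end = integer(0), orientation = character(0),
                        n_members = integer(0),
                        mean_pairwise_identity = numeric(0),
                        divergence_min = numeric(0),
                        divergence_max = numeric(0),
                        consensus = character(0), stringsAsFactors = FALSE),
    members = list(), member_seqs = list(),
    insertions = data.frame(source_id = character(0), start = integer(0),
                            end = integer(0), length = integer(0),
                            stringsAsFactors = FALSE)), class = "block_set")
  n <- nrow(monomers)
  if (n == 0L) return(empty)
  if (length(unique(monomers$source_id)) > 1L) {
    stop("segment_blocks expects monomers from a single source")
  }
  if (is.unsorted(monomers$start)) stop("monomers must be sorted by start")

  blocks <- list()
  insertions <- list()
  cur <- 1L           # row indices of current block
  cur_seqs <- monomers$seq[1]
  cur_cons <- monomers$seq[1]
  for (i in seq_len(n)[-1]) {
    gap <- monomers$start[i] - monomers$end[i - 1L] - 1L
    if (gap > max_intra_gap) {
      insertions[[length(insertions) + 1L]] <- data.frame(
        source_id = monomers$source_id[i], start = monomers$end[i - 1L] + 1L,
        end = monomers$start[i] - 1L, length = gap, stringsAsFactors = FALSE)
    }
    same_strand <- monomers$strand[i] == monomers$strand[cur[1]]
    # IUPAC-aware identity: a member whose base falls inside a consensus
    # ambiguity set is consistent with the block, not divergent from it
    joins <- same_strand && gap <= max_intra_gap &&
      global_identity(monomers$seq[i], cur_cons, params,
                      iupac = TRUE) >= min_block_identity
    if (joins) {
      cur <- c(cur, i)
      cur_seqs <- c(cur_seqs, monomers$seq[i])
      cur_cons <- block_consensus(cur_seqs, params)
    } else {
      blocks[[length(blocks) + 1L]] <- list(rows = cur, seqs = cur_seqs,
                                            consensus = cur_cons)
      cur <- i
      cur_seqs <- monomers$seq[i]
      cur_cons <- monomers$seq[i]
    }
  }
  blocks[[length(blocks) + 1L]] <- list(rows = cur, seqs = cur_seqs,
                                        consensus = cur_cons)

  btab <- do.call(rbind, lapply(seq_along(blocks), function(b) {
    bl <- blocks[[b]]
    k <- length(bl$rows)
    if (k >= 2L) {
      pid <- apply(utils::combn(k, 2), 2, function(p)
        global_identity(bl$seqs[p[1]], bl$seqs[p[2]], params))
      mpi <- mean(pid)
      dmin <- 1 - max(pid)
      dmax <- 1 - min(pid)
    } else {
      mpi <- 1; dmin <- 0; dmax <- 0
    }
    data.frame(block_id = b,
               start = monomers$start[bl$rows[1]],
               end = monomers$end[bl$rows[k]],
               orientation = monomers$strand[bl$rows[1]],
               n_members = k,
               mean_pairwise_identity = mpi,
               divergence_min = dmin, divergence_max = dmax,
               consensus = bl$consensus, stringsAsFactors = FALSE)
  }))
  ins <- if (length(insertions)) do.call(rbind, insertions) else
    empty$insertions
  structure(list(blocks = btab,
                 members = lapply(blocks, `[[`, "rows"),
                 member_seqs = lapply(blocks, `[[`, "seqs"),
                 insertions = ins), class = "block_set")
}

#' @export
print.block_set <- function(x, ...) {
  cat("<block_set>", nrow(x$blocks), "blocks,",
      nrow(x$insertions), "insertions\n")
  print(x$blocks[, setdiff(names(x$blocks), "consensus")], ...)
  invisible(x)
}

.consensus_list <- function(blocks) {
  if (inherits(blocks, "block_set")) {
    stats::setNames(blocks$blocks$consensus,
                    paste0("block", blocks$blocks$block_id))
  } else if (is.character(blocks)) {
    if (length(blocks) && is.null(names(blocks))) {
      names(blocks) <- paste0("block", seq_along(blocks))
    }
    blocks
  } else stop("expected a block_set or a character vector of consensuses")
}

#' Pairwise homology matrix between two sets of block consensuses
#'
#' Every consensus pair is locally aligned on both strands; the better
#' orientation wins and is recorded (`"same"` when the forward alignment
#' wins, `"inverted"` otherwise). Consensuses are stored
#' reference-oriented, so the orientation relation is about sequence sense,
#' not genomic strand.
#'
#' @param blocks_x,blocks_y `block_set` objects or character vectors of
#'   consensus sequences.
#' @param params An [align_params()] object.
#' @return List with `identity` (|x| by |y| numeric matrix) and
#'   `orientation` (character matrix, "same"/"inverted").
#' @export
block_homology_matrix <- function(blocks_x, blocks_y,
                                  params = align_params()) {
  cx <- .consensus_list(blocks_x)
  cy <- .consensus_list(blocks_y)
  idm <- matrix(NA_real_, length(cx), length(cy),
                dimnames = list(names(cx), names(cy)))
  orm <- matrix(NA_character_, length(cx), length(cy),
                dimnames = list(names(cx), names(cy)))
  for (i in seq_along(cx)) {
    for (j in seq_along(cy)) {
      a <- local_align(cx[i], cy[j], params, both_strands = TRUE,
                       iupac = TRUE)
      idm[i, j] <- a$identity
      orm[i, j] <- if (a$strand == "+") "same" else "inverted"
    }
  }
  list(identity = idm, orientation = orm)
}

#' Infer donor provenance of fused-array blocks
#'
#' Each block of the fused array is assigned to the donor block (across
#' both donors) whose consensus it matches with highest identity; the
#' runner-up identity (best among all remaining donor blocks) and the
#' orientation relation of the winning alignment are reported. Ties within
#' `tie_tol` are flagged, never silently broken.
#'
#' @param fused_blocks,donorA_blocks,donorB_blocks `block_set` objects or
#'   consensus vectors.
#' @param params An [align_params()] object.
#' @param tie_tol Identity difference below which winner and runner-up are
#'   considered tied.
#' @return `data.frame` with `fused_block_id`, `donor_label` ("A"/"B"),
#'   `donor_block_id`, `identity`, `orientation_relation`,
#'   `runner_up_identity`, `tie`.
#' @export
infer_provenance <- function(fused_blocks, donorA_blocks, donorB_blocks,
                             params = align_params(), tie_tol = 1e-9) {
  cf <- .consensus_list(fused_blocks)
  ca <- .consensus_list(donorA_blocks)
  cb <- .consensus_list(donorB_blocks)
  if (length(ca) == 0L || length(cb) == 0L) {
    stop("each donor must contribute at least one block")
  }
  ha <- block_homology_matrix(cf, ca, params)
  hb <- block_homology_matrix(cf, cb, params)
  donors <- c(rep("A", length(ca)), rep("B", length(cb)))
  donor_ids <- c(seq_along(ca), seq_along(cb))
  out <- lapply(seq_along(cf), function(i) {
    ids <- c(ha$identity[i, ], hb$identity[i, ])
    ors <- c(ha$orientation[i, ], hb$orientation[i, ])
    best <- which.max(ids)
    rest <- ids[-best]
    runner <- if (length(rest)) max(rest) else NA_real_
    data.frame(fused_block_id = i,
               donor_label = donors[best],
               donor_block_id = donor_ids[best],
               identity = ids[best],
               orientation_relation = ors[best],
               runner_up_identity = runner,
               tie = !is.na(runner) && (ids[best] - runner) < tie_tol,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a block table as TSV
#' @param block_set A `block_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_block_table <- function(block_set, path) {
  write.table(block_set$blocks, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
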