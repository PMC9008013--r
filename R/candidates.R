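# Candidate fusion scaffolds from gene-anchor tables: scaffolds whose
# genes align to both donor chromosomes, and run-length segmentation of a
# scaffold's anchors into syntenic segments.

ANCHOR_COLS <- c("gene_id", "scaffold_id", "scaffold_start", "scaffold_end",
                 "target_chrom", "target_start", "target_end", "identity",
                 "strand")

#' Load a gene-anchor table
#'
#' Tab-separated with a header naming the columns `gene_id`, `scaffold_id`,
#' `scaffold_start`, `scaffold_end`, `target_chrom`, `target_start`,
#' `target_end`, `identity` (percentage), `strand`. Rows with inverted
#' coordinates, identities outside \[0, 100\] or unparseable numbers are
#' dropped with a warning naming their line numbers.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` of anchors.
#' @export
load_anchors <- function(path) {
  if (!file.exists(path)) stop("anchor table not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(ANCHOR_COLS, names(tab))
  if (length(missing)) {
    stop("anchor table '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  tab <- tab[ANCHOR_COLS]
  num_cols <- c("scaffold_start", "scaffold_end", "target_start",
                "target_end", "identity")
  for (cl in num_cols) tab[[cl]] <- suppressWarnings(as.numeric(tab[[cl]]))
  bad <- rowSums(is.na(tab[num_cols])) > 0 |
    tab$scaffold_start > tab$scaffold_end |
    tab$target_start > tab$target_end |
    tab$scaffold_start <= 0 | tab$target_start <= 0 |
    tab$identity < 0 | tab$identity > 100
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    warning("dropping ", sum(bad), " malformed anchor row(s) at line(s): ",
            paste(which(bad) + 1L, collapse = ", "))
    tab <- tab[!bad, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Write an anchor table as TSV
#' @param anchors Anchor `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_anchors <- function(anchors, path) {
  write.table(anchors[ANCHOR_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Candidate fusion scaffolds
#'
#' Scaffolds with at least `min_each` gene anchors to each of two donor
#' chromosomes are putative fusion regions.
#'
#' @param anchors Anchor `data.frame` (see [load_anchors()]).
#' @param chrom_a,chrom_b Donor chromosome names.
#' @param min_each Minimum anchors per donor chromosome (default 1).
#' @return `data.frame` with `scaffold_id`, `n_genes_a`, `n_genes_b`,
#'   `min_identity`, `mean_identity` (summaries over the scaffold's anchors
#'   to the two donors).
#' @export
candidate_scaffolds <- function(anchors, chrom_a, chrom_b, min_each = 1L) {
  if (nrow(anchors) == 0L) stop("empty anchor table")
  rel <- anchors[anchors$target_chrom %in% c(chrom_a, chrom_b), , drop = FALSE]
  out <- lapply(split(rel, rel$scaffold_id), function(g) {
    na <- sum(g$target_chrom == chrom_a)
    nb <- sum(g$target_chrom == chrom_b)
    if (na < min_each || nb < min_each) return(NULL)
    data.frame(scaffold_id = g$scaffold_id[1], n_genes_a = na, n_genes_b = nb,
               min_identity = min(g$identity),
               mean_identity = mean(g$identity), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(scaffold_id = character(0), n_genes_a = integer(0),
                      n_genes_b = integer(0), min_identity = numeric(0),
                      mean_identity = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res[order(res$scaffold_id), , drop = FALSE]
}

#' Segment a scaffold's anchors into syntenic runs
#'
#' Anchors are sorted by scaffold position; maximal runs of consecutive
#' anchors sharing a target chromosome become segments, so the segment
#' count equals the number of chromosome-label changes plus one.
#' Continuity is defined purely by scaffold order; with
#' `strict_collinearity = TRUE` a run is additionally broken when the
#' target coordinates of consecutive anchors are not monotone.
#'
#' @param anchors Anchors of a single scaffold.
#' @param strict_collinearity Also require target-coordinate monotonicity.
#' @return `data.frame` with `segment_id`, `target_chrom`, `n_genes`,
#'   `scaffold_start`, `scaffold_end`, `target_start`, `target_end`, and a
#'   list-column `gene_ids` (ordered member genes).
#' @export
segment_anchors <- function(anchors, strict_collinearity = FALSE) {
  if (nrow(anchors) == 0L) {
    out <- data.frame(segment_id = integer(0), target_chrom = character(0),
                      n_genes = integer(0), scaffold_start = numeric(0),
                      scaffold_end = numeric(0), target_start = numeric(0),
                      target_end = numeric(0), stringsAsFactors = FALSE)
    out$gene_ids <- list()
    return(out)
  }
  if (length(unique(anchors$scaffold_id)) > 1L) {
    stop("segment_anchors expects anchors of a single scaffold")
  }
  a <- anchors[order(anchors$scaffold_start), , drop = FALSE]
  n <- nrow(a)
  breaks <- logical(n)
  breaks[1] <- TRUE
  for (i in seq_len(n)[-1]) {
    breaks[i] <- a$target_chrom[i] != a$target_chrom[i - 1]
    if (!breaks[i] && strict_collinearity && i > 2) {
      prev_dir <- sign(a$target_start[i - 1] - a$target_start[i - 2])
      cur_dir <- sign(a$target_start[i] - a$target_start[i - 1])
      if (prev_dir != 0 && cur_dir != 0 && prev_dir != cur_dir &&
          !breaks[i - 1]) breaks[i] <- TRUE
    }
  }
  seg_id <- cumsum(breaks)
  out <- lapply(split(seq_len(n), seg_id), function(rows) {
    g <- a[rows, , drop = FALSE]
    data.frame(segment_id = seg_id[rows[1]], target_chrom = g$target_chrom[1],
               n_genes = nrow(g),
               scaffold_start = min(g$scaffold_start),
               scaffold_end = max(g$scaffold_end),
               target_start = min(g$target_start),
               target_end = max(g$target_end), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$gene_ids <- unname(lapply(split(seq_len(n), seg_id),
                                function(rows) a$gene_id[rows]))
  rownames(res) <- NULL
  res
}
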