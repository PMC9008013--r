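# Detection of full-length satellite monomers by greedy iterative masking:
# repeatedly take the best local alignment of the reference monomer against
# the still-unmasked source (both strands), emit passing hits, mask, repeat.

#' Monomer scan configuration
#'
#' @param reference Reference satellite monomer (single sequence, e.g. the
#'   bovine satellite I / 1.715-family ~1.4-kb unit).
#' @param min_identity Minimum alignment identity to the reference for a
#'   retained monomer (default 0.70; the satellite-search threshold is not
#'   standardized, so it is exposed here).
#' @param min_coverage Fraction of the reference length that must be aligned
#'   for a monomer to count as "full length" (default 0.90).
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(reference, min_identity = 0.70, min_coverage = 0.90) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1)
  reference <- normalize_seq(reference[1],
                             if (is.null(names(reference))) "reference"
                             else names(reference))
  structure(list(reference = reference, min_identity = min_identity,
                 min_coverage = min_coverage),
            class = "scan_config")
}

#' Find satellite monomers in a source sequence
#'
#' Greedy best-hit masking: the best-scoring local alignment of the
#' reference against the unmasked source (both strands) is taken; if it
#' passes the identity and coverage thresholds it is emitted as a monomer;
#' its interval is masked with N (which matches nothing) either way, and
#' scanning continues until the best remaining score drops below a floor
#' derived from the thresholds. Because terminal mismatch columns can never
#' belong to an optimal local alignment, emitted monomers are strictly
#' non-overlapping.
#'
#' @param source Single named sequence to scan.
#' @param cfg A [scan_config()].
#' @param params An [align_params()] object.
#' @return A `data.frame` (class `monomer_table`) with columns `source_id`,
#'   `index` (0-based rank by start), `start`, `end` (1-based inclusive),
#'   `strand`, `ref_identity`, `ref_coverage`, `seq`. Monomer sequences are
#'   stored reference-oriented (reverse-complemented for "-" hits).
#' @export
find_monomers <- function(source, cfg, params = align_params()) {
  stopifnot(inherits(cfg, "scan_config"))
  src_id <- if (!is.null(names(source))) names(source)[1] else "source"
  src <- unname(normalize_seq(source[1], src_id))
  ref <- unname(cfg$reference)
  L <- nchar(ref)
  empty <- data.frame(source_id = character(0), index = integer(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), ref_identity = numeric(0),
                      ref_coverage = numeric(0), seq = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("monomer_table", "data.frame")
  if (L > nchar(src)) return(empty)

  # Stop once no hit could plausibly pass: a passing gap-free hit spans at
  # least min_coverage * L columns at identity min_identity, hence score at
  # least L * min_coverage * (2 * min_identity - 1) under +m/-m-style scoring.
  per_col <- cfg$min_identity * params$match +
    (1 - cfg$min_identity) * params$mismatch
  stop_score <- max(10, floor(L * cfg$min_coverage * per_col))

  masked <- src
  hits <- list()
  repeat {
    aln <- local_align(ref, masked, params, both_strands = TRUE)
    if (aln$score < stop_score) break
    ts <- aln$target_start
    te <- aln$target_end
    cov <- (aln$query_end - aln$query_start + 1) / L
    pass <- !is.na(aln$identity) && aln$identity >= cfg$min_identity &&
      cov >= cfg$min_coverage
    if (pass) {
      sq <- substr(src, ts, te)
      if (aln$strand == "-") sq <- unname(reverse_complement(sq))
      hits[[length(hits) + 1L]] <- data.frame(
        source_id = src_id, index = NA_integer_, start = ts, end = te,
        strand = aln$strand, ref_identity = aln$identity,
        ref_coverage = cov, seq = sq, stringsAsFactors = FALSE)
    }
    substr(masked, ts, te) <- strrep("N", te - ts + 1L)
  }
  if (length(hits) == 0L) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$start), , drop = FALSE]
  out$index <- seq_len(nrow(out)) - 1L
  rownames(out) <- NULL
  class(out) <- c("monomer_table", "data.frame")
  out
}

#' Keep only full-length monomers
#'
#' @param monomers A `monomer_table`.
#' @param cfg A [scan_config()] supplying `min_coverage`.
#' @return Monomers with `ref_coverage >= min_coverage`, order preserved,
#'   0-based indices reassigned.
#' @export
filter_full_length <- function(monomers, cfg) {
  out <- monomers[monomers$ref_coverage >= cfg$min_coverage, , drop = FALSE]
  out$index <- seq_len(nrow(out)) - 1L
  rownames(out) <- NULL
  class(out) <- c("monomer_table", "data.frame")
  out
}

#' Write monomers as BED
#'
#' BED is 0-based half-open; internal coordinates are 1-based inclusive.
#' Name is `source_id.index`, score is identity scaled to 0-1000.
#'
#' @param monomers A `monomer_table`.
#' @param path Optional output path; when NULL the BED `data.frame` is
#'   returned without writing.
#' @return The BED `data.frame`, invisibly when written.
#' @export
monomers_to_bed <- function(monomers, path = NULL) {
  bed <- data.frame(
    chrom = monomers$source_id,
    start = monomers$start - 1L,
    end = monomers$end,
    name = if (nrow(monomers)) paste0(monomers$source_id, ".",
                                      monomers$index) else character(0),
    score = as.integer(round(monomers$ref_identity * 1000)),
    strand = monomers$strand,
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#chrom\tstart\tend\tname\tscore\tstrand", con)
    if (nrow(bed) > 0) {
      write.table(bed, con, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    }
    return(invisible(bed))
  }
  bed
}

#' Read a BED file written by [monomers_to_bed()]
#'
#' @param path Path to a 6-column BED file (comment lines ignored).
#' @return `data.frame` with chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  dat <- tryCatch(
    read.delim(path, header = FALSE, comment.char = "#",
               col.names = cols, stringsAsFactors = FALSE),
    error = function(e) {
      setNames(data.frame(character(0), integer(0), integer(0),
                          character(0), integer(0), character(0),
                          stringsAsFactors = FALSE), cols)
    })
  dat
}

#' Write the monomer table as TSV
#'
#' @param monomers A `monomer_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_monomer_table <- function(monomers, path) {
  write.table(monomers, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
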