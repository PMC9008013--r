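# Degenerate (IUPAC) motif scanning for CENP-B box analysis, and
# core-position comparison between motifs with transition/transversion
# classification of the differences.

#' Construct a degenerate motif
#'
#' @param iupac Motif text over IUPAC nucleotide codes.
#' @param name Motif name.
#' @param core_mask Logical vector marking "core" positions (those required
#'   for protein binding). Defaults to the unambiguous positions, i.e. those
#'   carrying a plain A/C/G/T — for the canonical CENP-B consensus
#'   NTTCGNNNNANNCGGGN these are exactly the nine core binding positions.
#' @return An object of class `degenerate_motif`.
#' @export
degenerate_motif <- function(iupac, name = "motif", core_mask = NULL) {
  iupac <- toupper(iupac)
  chars <- strsplit(iupac, "", fixed = TRUE)[[1]]
  .iupac_mask(chars) # validates
  if (is.null(core_mask)) core_mask <- chars %in% c("A", "C", "G", "T")
  if (length(core_mask) != length(chars)) {
    stop("core_mask length must equal motif length")
  }
  structure(list(name = name, iupac = iupac, core_mask = core_mask),
            class = "degenerate_motif")
}

.as_motif <- function(x, name = "motif") {
  if (inherits(x, "degenerate_motif")) x else degenerate_motif(x, name)
}

#' Built-in motif catalogue
#'
#' Ships the motifs used in CENP-B box analysis of bovine satellite I:
#' the canonical human CENP-B box, its consensus with the nine core
#' binding positions, the relaxed 7-bp CENP-B element, and the proposed
#' bovine motif.
#'
#' @return Named list of [degenerate_motif()] objects.
#' @export
motif_catalogue <- function() {
  path <- system.file("extdata", "motifs.tsv", package = "cenfuse")
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  out <- lapply(seq_len(nrow(tab)), function(i)
    degenerate_motif(tab$iupac[i], tab$name[i]))
  names(out) <- tab$name
  out
}

#' Scan a sequence for a degenerate motif
#'
#' Every window (both strands when requested) whose number of
#' non-intersecting positions is at most `max_mismatch` is reported. A
#' position matches when the IUPAC base sets of motif and window intersect.
#' Overlapping hits are all reported.
#'
#' @param source Single (named) sequence.
#' @param motif A [degenerate_motif()] or IUPAC text.
#' @param max_mismatch Maximum mismatching positions per hit (default 4,
#'   the conventional CENP-B-box search allowance).
#' @param both_strands Scan the reverse strand too.
#' @param core_max_mismatch Separate cap on core-position mismatches
#'   (default `Inf`, i.e. unconstrained).
#' @return `data.frame` with `source_id`, `start` (1-based, forward strand),
#'   `strand`, `window` (motif-oriented), `total_mismatches`,
#'   `core_mismatches`, and a list-column `diffs` of per-position difference
#'   tables (`position`, `expected`, `observed`, `class`).
#' @export
scan_motif <- function(source, motif, max_mismatch = 4, both_strands = TRUE,
                       core_max_mismatch = Inf) {
  motif <- .as_motif(motif)
  src_id <- if (!is.null(names(source))) names(source)[1] else "source"
  src <- .norm_iupac(unname(source[1]), src_id)
  L <- nchar(motif$iupac)
  if (L >= nchar(src)) stop("motif must be shorter than the source")
  mchars <- strsplit(motif$iupac, "", fixed = TRUE)[[1]]
  mmask <- .iupac_mask(mchars)

  scan_one <- function(seqtext, strand) {
    n <- nchar(seqtext)
    chars <- strsplit(seqtext, "", fixed = TRUE)[[1]]
    cmask <- .iupac_mask(chars)
    nwin <- n - L + 1L
    # windows x positions logical mismatch matrix, vectorized per position
    mism <- matrix(FALSE, nwin, L)
    for (p in seq_len(L)) {
      mism[, p] <- bitwAnd(cmask[p:(p + nwin - 1L)], mmask[p]) == 0L
    }
    tot <- rowSums(mism)
    core <- if (any(motif$core_mask))
      rowSums(mism[, motif$core_mask, drop = FALSE]) else 0L
    keep <- which(tot <= max_mismatch & core <= core_max_mismatch)
    if (!length(keep)) return(NULL)
    data.frame(source_id = src_id,
               start = if (strand == "+") keep else n - (keep + L - 1L) + 1L,
               strand = strand,
               window = vapply(keep, function(w)
                 substr(seqtext, w, w + L - 1L), character(1)),
               total_mismatches = tot[keep],
               core_mismatches = core[keep],
               win_index = keep,
               stringsAsFactors = FALSE)
  }

  res <- scan_one(src, "+")
  if (both_strands) {
    res <- rbind(res, scan_one(unname(reverse_complement(src)), "-"))
  }
  if (is.null(res) || nrow(res) == 0L) {
    out <- data.frame(source_id = character(0), start = integer(0),
                      strand = character(0), window = character(0),
                      total_mismatches = integer(0),
                      core_mismatches = integer(0), stringsAsFactors = FALSE)
    out$diffs <- list()
    return(out)
  }
  res <- res[order(res$start, res$strand), , drop = FALSE]
  res$diffs <- lapply(seq_len(nrow(res)), function(i) {
    wchars <- strsplit(res$window[i], "", fixed = TRUE)[[1]]
    pos <- which(!iupac_sets_intersect(mchars, wchars))
    if (!length(pos)) {
      return(data.frame(position = integer(0), expected = character(0),
                        observed = character(0), class = character(0),
                        stringsAsFactors = FALSE))
    }
    data.frame(position = pos, expected = mchars[pos], observed = wchars[pos],
               class = vapply(pos, function(p)
                 .classify_iupac_diff(mchars[p], wchars[p]), character(1)),
               stringsAsFactors = FALSE)
  })
  res$win_index <- NULL
  rownames(res) <- NULL
  res
}

#' Compare an observed motif with a canonical motif at core positions
#'
#' The canonical motif supplies the core mask. A core position matches when
#' the two IUPAC sets intersect; otherwise the difference is classified as
#' transition/transversion (when unambiguous) or "ambiguous". Differences
#' are labelled "canonical/observed", e.g. "G/A" for canonical G vs
#' observed A.
#'
#' @param observed,canonical [degenerate_motif()] objects or IUPAC texts of
#'   equal length.
#' @return List of class `core_comparison`: `differences` (`data.frame`
#'   with `position`, `canonical`, `observed`, `class`, `pair`),
#'   `n_core`, `n_differences`, `n_transitions`, `n_transversions`,
#'   `n_ambiguous`.
#' @export
compare_core <- function(observed, canonical) {
  observed <- .as_motif(observed, "observed")
  canonical <- .as_motif(canonical, "canonical")
  oc <- strsplit(observed$iupac, "", fixed = TRUE)[[1]]
  cc <- strsplit(canonical$iupac, "", fixed = TRUE)[[1]]
  if (length(oc) != length(cc)) stop("motif lengths differ")
  core <- which(canonical$core_mask)
  diff_pos <- core[!iupac_sets_intersect(cc[core], oc[core])]
  cls <- vapply(diff_pos, function(p)
    .classify_iupac_diff(cc[p], oc[p]), character(1))
  differences <- data.frame(
    position = diff_pos, canonical = cc[diff_pos], observed = oc[diff_pos],
    class = cls,
    pair = if (length(diff_pos)) paste0(cc[diff_pos], "/", oc[diff_pos])
           else character(0),
    stringsAsFactors = FALSE)
  structure(list(differences = differences,
                 n_core = length(core),
                 n_differences = length(diff_pos),
                 n_transitions = sum(cls == "transition"),
                 n_transversions = sum(cls == "transversion"),
                 n_ambiguous = sum(cls == "ambiguous")),
            class = "core_comparison")
}

#' @export
print.core_comparison <- function(x, ...) {
  cat(sprintf("<core_comparison> %d/%d core positions differ (%d Ts, %d Tv, %d ambiguous)\n",
              x$n_differences, x$n_core, x$n_transitions, x$n_transversions,
              x$n_ambiguous))
  if (x$n_differences > 0) print(x$differences)
  invisible(x)
}

#' Derive a degenerate consensus motif from matched windows
#'
#' Per column: the base itself if unanimous, otherwise the minimal IUPAC
#' code covering every observed base.
#'
#' @param hit_windows Character vector (>= 2) of equal-length window texts.
#' @param name Name for the derived motif.
#' @return A [degenerate_motif()].
#' @export
derive_consensus_motif <- function(hit_windows, name = "consensus") {
  if (length(hit_windows) < 2L) stop("need at least 2 windows")
  hit_windows <- toupper(hit_windows)
  lens <- nchar(hit_windows)
  if (length(unique(lens)) != 1L) stop("windows must have equal length")
  mat <- do.call(rbind, strsplit(hit_windows, "", fixed = TRUE))
  cons <- apply(mat, 2, function(col) {
    u <- unique(col)
    if (length(u) == 1L) u else iupac_union(u)
  })
  degenerate_motif(paste(cons, collapse = ""), name)
}

#' Write a motif hit table as TSV (difference lists flattened)
#' @param hits Output of [scan_motif()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_hits <- function(hits, path) {
  flat <- hits
  flat$diffs <- vapply(hits$diffs, function(d) {
    if (nrow(d) == 0) return("")
    paste(sprintf("%d:%s>%s(%s)", d$position, d$expected, d$observed,
                  substr(d$class, 1, 2)), collapse = ",")
  }, character(1))
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
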