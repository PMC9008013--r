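# Transition/transversion substitution spectra, p-distances with pairwise
# deletion, a slope-ratio substitution-saturation assessment, and
# neighbor-joining trees.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Classify a substitution as transition or transversion
#'
#' @param a,b Distinct bases in A/C/G/T (vectorized; recycled).
#' @return "transition" (within purines or within pyrimidines) or
#'   "transversion"; symmetric in its arguments.
#' @export
classify_substitution <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (any(!a %in% c(PURINES, PYRIMIDINES)) ||
      any(!b %in% c(PURINES, PYRIMIDINES))) {
    stop("bases must be A, C, G or T")
  }
  if (any(a == b)) stop("bases must differ")
  ifelse((a %in% PURINES) == (b %in% PURINES), "transition", "transversion")
}

.round2 <- function(x) floor(x * 100 + 0.5) / 100 # round half-up, 2 decimals

# Split two gapped rows into per-column classification.
.pair_columns <- function(a, b) {
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb)) stop("aligned rows differ in length")
  list(ca = ca, cb = cb,
       gap = ca == "-" | cb == "-",
       ambig = (!ca %in% c("A", "C", "G", "T") & ca != "-") |
               (!cb %in% c("A", "C", "G", "T") & cb != "-"))
}

#' Substitution spectrum of an aligned sequence pair
#'
#' Gap columns count as deletions and are excluded from substitution
#' counting, as are columns containing N or another ambiguity code.
#' Proportions are percentages of the substitution total, rounded half-up
#' to two decimals.
#'
#' @param aligned_a,aligned_b Gapped rows of equal length.
#' @return Object of class `substitution_spectrum`: `n_sites_compared`,
#'   `n_substitutions`, `n_transitions`, `n_transversions`, `n_deletions`,
#'   `n_ambiguous`, `by_type` (named counts for A/G, C/T and the four
#'   transversion pairs), `prop_transitions`, `prop_transversions` (0 when
#'   there are no substitutions).
#' @export
substitution_spectrum <- function(aligned_a, aligned_b) {
  cols <- .pair_columns(aligned_a, aligned_b)
  usable <- !cols$gap & !cols$ambig
  ca <- cols$ca[usable]; cb <- cols$cb[usable]
  sub <- ca != cb
  pairs <- vapply(which(sub), function(i)
    paste(sort(c(ca[i], cb[i])), collapse = ""), character(1))
  type_names <- c("AG", "CT", "AC", "AT", "CG", "GT")
  by_type <- setNames(integer(6), type_names)
  if (length(pairs)) {
    tab <- table(factor(pairs, levels = type_names))
    by_type[] <- as.integer(tab)
  }
  n_ts <- sum(by_type[c("AG", "CT")])
  n_tv <- sum(by_type[c("AC", "AT", "CG", "GT")])
  n_sub <- n_ts + n_tv
  structure(list(
    n_sites_compared = sum(usable),
    n_substitutions = n_sub,
    n_transitions = n_ts,
    n_transversions = n_tv,
    n_deletions = sum(cols$gap),
    n_ambiguous = sum(cols$ambig & !cols$gap),
    by_type = by_type,
    prop_transitions = if (n_sub > 0) .round2(100 * n_ts / n_sub) else 0,
    prop_transversions = if (n_sub > 0) .round2(100 * n_tv / n_sub) else 0
  ), class = "substitution_spectrum")
}

#' @export
print.substitution_spectrum <- function(x, ...) {
  cat(sprintf("<substitution_spectrum> %d substitutions over %d sites (%d deletion columns)\n",
              x$n_substitutions, x$n_sites_compared, x$n_deletions))
  cat(sprintf("  Ts %d (%.2f%%)  Tv %d (%.2f%%)\n", x$n_transitions,
              x$prop_transitions, x$n_transversions, x$prop_transversions))
  invisible(x)
}

# Align a pair unless both inputs are equal-length (then treated as
# already-aligned rows, which covers simulator output and consensus rows).
.pair_rows <- function(a, b, params, aligned = NULL) {
  if (is.null(aligned)) aligned <- nchar(a) == nchar(b)
  if (aligned) c(unname(a), unname(b)) else
    unname(multi_align(c(a = unname(a), b = unname(b)), params))
}

#' p-distance between two sequences
#'
#' Differing columns over compared columns with pairwise deletion: gap and
#' ambiguous columns are excluded. Unequal-length inputs are aligned
#' internally; equal-length inputs are treated as already aligned (set
#' `aligned = FALSE` to force alignment).
#'
#' @param a,b Sequences or aligned rows.
#' @param params An [align_params()] object.
#' @param aligned NULL (auto), TRUE or FALSE.
#' @return Fraction in \[0, 1\].
#' @export
p_distance <- function(a, b, params = align_params(), aligned = NULL) {
  rows <- .pair_rows(a, b, params, aligned)
  cols <- .pair_columns(rows[1], rows[2])
  usable <- !cols$gap & !cols$ambig
  if (!sum(usable)) stop("no comparable columns between the two sequences")
  sum(cols$ca[usable] != cols$cb[usable]) / sum(usable)
}

#' Pairwise p-distance matrix
#'
#' @param seqs Named character vector (>= 2).
#' @param params An [align_params()] object.
#' @param aligned NULL (auto: equal-length input treated as aligned rows),
#'   TRUE or FALSE.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(seqs, params = align_params(), aligned = NULL) {
  k <- length(seqs)
  if (k < 2L) stop("need at least 2 sequences")
  labs <- if (is.null(names(seqs))) paste0("seq", seq_len(k)) else names(seqs)
  d <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d[i, j] <- d[j, i] <- p_distance(seqs[i], seqs[j], params, aligned)
    }
  }
  d
}

#' Substitution-saturation assessment
#'
#' All sequence pairs are tabulated as (p-distance, transition count,
#' transversion count). For each class an ordinary-least-squares slope of
#' count against p-distance is fitted over the lower and upper halves of
#' the distance range (median split). A class is flagged saturated when its
#' upper-half slope falls below `saturation_ratio_threshold` times its
#' lower-half slope — multiple hits flatten the accumulation of a class at
#' high divergence. This slope-ratio heuristic is deliberately simple;
#' entropy-based saturation tests are out of scope.
#'
#' @param seqs Named character vector (>= 4 sequences).
#' @param params An [align_params()] object.
#' @param saturation_ratio_threshold Upper/lower slope ratio below which a
#'   class is called saturated (default 0.5).
#' @param aligned NULL (auto), TRUE or FALSE; see [p_distance()].
#' @return Object of class `saturation_report`: `pairs` (`data.frame` with
#'   `a`, `b`, `p_distance`, `ts_count`, `tv_count`), `ts_slope`,
#'   `tv_slope` (full-range OLS), `ts_saturation_ratio`,
#'   `tv_saturation_ratio`, `ts_saturated`, `tv_saturated`.
#' @export
saturation_analysis <- function(seqs, params = align_params(),
                                saturation_ratio_threshold = 0.5,
                                aligned = NULL) {
  k <- length(seqs)
  if (k < 4L) stop("saturation analysis needs at least 4 sequences")
  labs <- if (is.null(names(seqs))) paste0("seq", seq_len(k)) else names(seqs)
  idx <- utils::combn(k, 2)
  rows <- apply(idx, 2, function(p) {
    r <- .pair_rows(seqs[p[1]], seqs[p[2]], params, aligned)
    cols <- .pair_columns(r[1], r[2])
    usable <- !cols$gap & !cols$ambig
    ca <- cols$ca[usable]; cb <- cols$cb[usable]
    sub <- which(ca != cb)
    ts <- if (length(sub))
      sum(classify_substitution(ca[sub], cb[sub]) == "transition") else 0L
    data.frame(a = labs[p[1]], b = labs[p[2]],
               p_distance = if (sum(usable)) length(sub) / sum(usable) else NA,
               ts_count = ts, tv_count = length(sub) - ts,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)

  ols_slope <- function(x, y) {
    if (length(unique(x)) < 2L) return(0)
    unname(coef(lm(y ~ x))[2])
  }
  half_ratio <- function(y) {
    x <- pairs$p_distance
    lower <- x <= median(x)
    upper <- !lower
    lo <- ols_slope(x[lower], y[lower])
    hi <- ols_slope(x[upper], y[upper])
    if (lo <= 0) return(NA_real_)
    hi / lo
  }
  ts_ratio <- half_ratio(pairs$ts_count)
  tv_ratio <- half_ratio(pairs$tv_count)
  structure(list(
    pairs = pairs,
    ts_slope = ols_slope(pairs$p_distance, pairs$ts_count),
    tv_slope = ols_slope(pairs$p_distance, pairs$tv_count),
    ts_saturation_ratio = ts_ratio,
    tv_saturation_ratio = tv_ratio,
    ts_saturated = !is.na(ts_ratio) && ts_ratio < saturation_ratio_threshold,
    tv_saturated = !is.na(tv_ratio) && tv_ratio < saturation_ratio_threshold
  ), class = "saturation_report")
}

#' @export
print.saturation_report <- function(x, ...) {
  cat(sprintf("<saturation_report> %d pairs; Ts slope %.2f (%s), Tv slope %.2f (%s)\n",
              nrow(x$pairs), x$ts_slope,
              if (x$ts_saturated) "SATURATED" else "linear",
              x$tv_slope,
              if (x$tv_saturated) "SATURATED" else "linear"))
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining; recovers any additive matrix's topology and
#' branch lengths exactly. Negative branch lengths are clamped to zero.
#' The result is an unrooted tree written with a trifurcation at the last
#' join; labels have whitespace replaced by underscores.
#'
#' @param d Symmetric distance matrix with labelled rows (>= 3 taxa).
#' @return Newick text (terminated by ";").
#' @export
nj_tree <- function(d) {
  n <- nrow(d)
  if (is.null(n) || n < 3L) stop("neighbor-joining needs at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d)))) stop("distance matrix must be symmetric")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  labs <- gsub("\\s+", "_", labs)
  nodes <- labs # newick fragment per active node
  D <- d
  while (length(nodes) > 3L) {
    m <- length(nodes)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- min(best); j <- max(best)
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    merged <- sprintf("(%s:%.10g,%s:%.10g)", nodes[i], li, nodes[j], lj)
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    du <- pmax(du, 0)
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- matrix(0, m - 1, m - 1)
    D2[seq_along(keep), seq_along(keep)] <- D[keep, keep]
    D2[m - 1, seq_along(keep)] <- D2[seq_along(keep), m - 1] <- du[keep]
    D <- D2
    nodes <- c(nodes[keep], merged)
  }
  la <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
  lb <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
  lc <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
  sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
          nodes[1], la, nodes[2], lb, nodes[3], lc)
}

#' Write a pair table / spectrum report as TSV
#' @param report A `saturation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(report, path) {
  write.table(report$pairs, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
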