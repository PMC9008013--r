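# IUPAC nucleotide ambiguity codes as bitmasks (A=1, C=2, G=4, T=8).

IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # C/G
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, # C/G/T
  D = 13L, # A/G/T
  H = 11L, # A/C/T
  V = 7L,  # A/C/G
  N = 15L
)

MASK_TO_CODE <- setNames(names(IUPAC_MASK)[order(IUPAC_MASK)],
                         sort(IUPAC_MASK))

PURINE_MASK <- 5L      # A|G
PYRIMIDINE_MASK <- 10L # C|T

.iupac_mask <- function(codes) {
  m <- IUPAC_MASK[codes]
  if (anyNA(m)) {
    stop("invalid IUPAC code(s): ",
         paste(unique(codes[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Do two IUPAC codes denote intersecting base sets?
#'
#' N intersects everything; e.g. Y ({C,T}) intersects C but not R ({A,G}).
#'
#' @param code_a,code_b IUPAC nucleotide codes (vectorized).
#' @return Logical vector.
#' @export
iupac_sets_intersect <- function(code_a, code_b) {
  bitwAnd(.iupac_mask(toupper(code_a)), .iupac_mask(toupper(code_b))) > 0L
}

#' Minimal IUPAC code covering a set of bases
#'
#' @param bases Character vector of bases/codes whose union is wanted.
#' @return A single IUPAC code.
#' @export
iupac_union <- function(bases) {
  m <- Reduce(bitwOr, .iupac_mask(toupper(bases)))
  MASK_TO_CODE[[as.character(m)]]
}

# Classify the difference between two non-intersecting IUPAC sets:
# "transition" when every cross-pair is within purines or within
# pyrimidines, "transversion" when every cross-pair crosses the boundary,
# otherwise "ambiguous" (never silently guessed).
.classify_iupac_diff <- function(code_a, code_b) {
  ma <- .iupac_mask(toupper(code_a))
  mb <- .iupac_mask(toupper(code_b))
  a_pur <- bitwAnd(ma, PURINE_MASK) > 0L
  a_pyr <- bitwAnd(ma, PYRIMIDINE_MASK) > 0L
  b_pur <- bitwAnd(mb, PURINE_MASK) > 0L
  b_pyr <- bitwAnd(mb, PYRIMIDINE_MASK) > 0L
  # all cross-pairs transitions: both sets homogeneous and on the same side
  if ((a_pur && !a_pyr && b_pur && !b_pyr) ||
      (a_pyr && !a_pur && b_pyr && !b_pur)) return("transition")
  # all cross-pairs transversions: homogeneous sets on opposite sides
  if ((a_pur && !a_pyr && b_pyr && !b_pur) ||
      (a_pyr && !a_pur && b_pur && !b_pyr)) return("transversion")
  "ambiguous"
}
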