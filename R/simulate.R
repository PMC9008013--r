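# Seeded simulator of satellite arrays, donor centromeres and fusion
# chromosomes with full ground truth: ancestral monomer -> per-block
# diverged consensus -> per-monomer intra-block mutation -> orientation per
# block -> concatenation with random insertions and non-satellite flanks.

#' Simulator configuration
#'
#' Defaults describe a desk-scale bovine-satellite-like array: a 1.4-kb
#' monomer, blocks whose constituents stay above 85% mutual identity
#' (intra-block per-site divergence 0.05 from the block consensus, i.e.
#' roughly 10% between constituents, inside the 3-15% range typical of
#' these arrays), block consensuses diverged 10% per site from the common
#' ancestor (roughly 19% between blocks), and 200-500 bp random insertions
#' between blocks.
#'
#' @param monomer_length Monomer length in bp (default 1400).
#' @param gc_content GC fraction of the ancestral monomer (default 0.5).
#' @param blocks `data.frame` with one row per block: `n_monomers`,
#'   `orientation` ("+"/"-") and `divergence_from_ancestor` (per-site).
#'   Default: three blocks of four monomers, inverted flanks around a
#'   forward middle block (the arrangement seen in fusion centromeres).
#' @param intra_block_divergence Per-site divergence of each monomer from
#'   its block consensus (default 0.05).
#' @param ts_tv_ratio Transition:transversion ratio R; a substitution is a
#'   transition with probability R/(R+1) (default 2).
#' @param insertion_length_range Min/max bp of the random insertions placed
#'   between blocks (default c(200, 500)).
#' @param flank_length Non-satellite flanking sequence on each side
#'   (default 500 bp) so edge effects are exercised.
#' @param edge_truncation Fraction of the outermost monomers clipped at the
#'   array edges (default 0 = no truncation); use e.g. 0.5 to plant
#'   half-monomers that full-length filtering must remove.
#' @param seed Integer seed; identical configuration implies identical
#'   output.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(monomer_length = 1400, gc_content = 0.5,
                       blocks = data.frame(
                         n_monomers = c(4L, 4L, 4L),
                         orientation = c("-", "+", "-"),
                         divergence_from_ancestor = c(0.10, 0.10, 0.10),
                         stringsAsFactors = FALSE),
                       intra_block_divergence = 0.05,
                       ts_tv_ratio = 2,
                       insertion_length_range = c(200L, 500L),
                       flank_length = 500L,
                       edge_truncation = 0,
                       seed = 1L) {
  stopifnot(monomer_length >= 1, gc_content >= 0, gc_content <= 1,
            nrow(blocks) >= 1, all(blocks$n_monomers >= 1),
            all(blocks$orientation %in% c("+", "-")),
            all(blocks$divergence_from_ancestor >= 0),
            all(blocks$divergence_from_ancestor <= 0.75),
            intra_block_divergence >= 0, intra_block_divergence <= 0.75,
            ts_tv_ratio > 0, length(insertion_length_range) == 2,
            insertion_length_range[1] <= insertion_length_range[2],
            flank_length >= 0, edge_truncation >= 0, edge_truncation < 1)
  structure(list(monomer_length = as.integer(monomer_length),
                 gc_content = gc_content, blocks = blocks,
                 intra_block_divergence = intra_block_divergence,
                 ts_tv_ratio = ts_tv_ratio,
                 insertion_length_range = as.integer(insertion_length_range),
                 flank_length = as.integer(flank_length),
                 edge_truncation = edge_truncation,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.random_seq <- function(length, gc = 0.5) {
  if (length == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

#' Simulate a random ancestral monomer
#'
#' @param length Monomer length (>= 1).
#' @param gc GC fraction.
#' @param seed Optional seed (NULL draws from the current RNG stream).
#' @return Single sequence string.
#' @export
simulate_monomer <- function(length, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .random_seq(length, gc)
}

TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSION_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                              C = c("A", "G"), T = c("A", "G"))

#' Mutate a sequence under an i.i.d. two-parameter substitution model
#'
#' Each site is substituted independently with probability `divergence`;
#' a substitution is a transition with probability `R/(R+1)` where R is
#' `ts_tv_ratio`, otherwise one of the two transversion partners chosen
#' uniformly. No indels are introduced, so input and output stay aligned
#' positionally. N sites are left untouched.
#'
#' @param seq Single sequence string.
#' @param divergence Per-site substitution probability in \[0, 0.75\].
#' @param ts_tv_ratio Transition:transversion ratio R (> 0).
#' @param seed Optional seed (NULL draws from the current RNG stream).
#' @return List with `seq` (mutated sequence) and `records` (`data.frame`
#'   with `position`, `from`, `to`, `class`).
#' @export
mutate_seq <- function(seq, divergence, ts_tv_ratio = 2, seed = NULL) {
  stopifnot(divergence >= 0, divergence <= 0.75, ts_tv_ratio > 0)
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  empty <- data.frame(position = integer(0), from = character(0),
                      to = character(0), class = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0L || divergence == 0) return(list(seq = seq, records = empty))
  hit <- which(stats::runif(n) < divergence & chars %in% c("A", "C", "G", "T"))
  if (!length(hit)) return(list(seq = seq, records = empty))
  p_ts <- ts_tv_ratio / (ts_tv_ratio + 1)
  is_ts <- stats::runif(length(hit)) < p_ts
  from <- chars[hit]
  to <- character(length(hit))
  to[is_ts] <- TRANSITION_PARTNER[from[is_ts]]
  if (any(!is_ts)) {
    pick <- stats::runif(sum(!is_ts)) < 0.5
    partners <- TRANSVERSION_PARTNERS[from[!is_ts]]
    to[!is_ts] <- vapply(seq_along(partners), function(i)
      partners[[i]][if (pick[i]) 1L else 2L], character(1))
  }
  chars[hit] <- to
  list(seq = paste(chars, collapse = ""),
       records = data.frame(position = hit, from = from, to = to,
                            class = ifelse(is_ts, "transition",
                                           "transversion"),
                            stringsAsFactors = FALSE))
}

#' Simulate a satellite array with ground truth
#'
#' @param cfg A [sim_config()].
#' @param ancestor Optional ancestral monomer sequence (shared between
#'   donors when simulating a fusion); default is drawn from the seed.
#' @param id Sequence identifier of the emitted array.
#' @return List of class `sim_array` with `seq` (named sequence) and
#'   `truth`: \describe{
#'     \item{monomers}{`data.frame`: `monomer_id`, `block_id`, `start`,
#'       `end`, `strand`, `n_substitutions`, `truncated`, `seq`
#'       (reference-oriented).}
#'     \item{insertions}{`data.frame`: `start`, `end`, `length`.}
#'     \item{blocks}{`data.frame`: `block_id`, `orientation`, `n_monomers`,
#'       `consensus` (the planted block consensus, reference-oriented).}
#'     \item{ancestor}{the ancestral monomer (scan reference).}
#'   }
#' @export
simulate_array <- function(cfg, ancestor = NULL, id = "sim_array") {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  if (is.null(ancestor)) {
    ancestor <- .random_seq(cfg$monomer_length, cfg$gc_content)
  }
  nb <- nrow(cfg$blocks)
  block_cons <- character(nb)
  monomers <- list()
  pieces <- character(0)
  insertions <- list()
  pos <- 1L
  mono_id <- 0L

  push <- function(piece) {
    pieces[[length(pieces) + 1L]] <<- piece
    pos <<- pos + nchar(piece)
  }
  if (cfg$flank_length > 0) push(.random_seq(cfg$flank_length))

  total_monomers <- sum(cfg$blocks$n_monomers)
  for (b in seq_len(nb)) {
    cons <- mutate_seq(ancestor, cfg$blocks$divergence_from_ancestor[b],
                       cfg$ts_tv_ratio)$seq
    block_cons[b] <- cons
    for (k in seq_len(cfg$blocks$n_monomers[b])) {
      mono_id <- mono_id + 1L
      mut <- mutate_seq(cons, cfg$intra_block_divergence, cfg$ts_tv_ratio)
      ref_seq <- mut$seq
      strand <- cfg$blocks$orientation[b]
      genomic <- if (strand == "-") unname(reverse_complement(ref_seq))
                 else ref_seq
      truncated <- FALSE
      if (cfg$edge_truncation > 0 &&
          (mono_id == 1L || mono_id == total_monomers)) {
        keep <- nchar(genomic) - floor(cfg$edge_truncation * nchar(genomic))
        genomic <- if (mono_id == 1L) {
          substr(genomic, nchar(genomic) - keep + 1L, nchar(genomic))
        } else {
          substr(genomic, 1L, keep)
        }
        ref_seq <- if (strand == "-") unname(reverse_complement(genomic))
                   else genomic
        truncated <- TRUE
      }
      monomers[[mono_id]] <- data.frame(
        monomer_id = mono_id, block_id = b, start = pos,
        end = pos + nchar(genomic) - 1L, strand = strand,
        n_substitutions = nrow(mut$records), truncated = truncated,
        seq = ref_seq, stringsAsFactors = FALSE)
      push(genomic)
    }
    if (b < nb) {
      ilen <- cfg$insertion_length_range[1] - 1L +
        sample.int(diff(cfg$insertion_length_range) + 1L, 1L)
      insertions[[length(insertions) + 1L]] <- data.frame(
        start = pos, end = pos + ilen - 1L, length = ilen,
        stringsAsFactors = FALSE)
      push(.random_seq(ilen))
    }
  }
  if (cfg$flank_length > 0) push(.random_seq(cfg$flank_length))

  seq <- paste(pieces, collapse = "")
  names(seq) <- id
  ins <- if (length(insertions)) do.call(rbind, insertions) else
    data.frame(start = integer(0), end = integer(0), length = integer(0))
  structure(list(
    seq = seq,
    truth = list(
      monomers = do.call(rbind, monomers),
      insertions = ins,
      blocks = data.frame(block_id = seq_len(nb),
                          orientation = cfg$blocks$orientation,
                          n_monomers = cfg$blocks$n_monomers,
                          consensus = block_cons, stringsAsFactors = FALSE),
      ancestor = ancestor),
    config = cfg), class = "sim_array")
}

#' Default donor configurations for fusion simulation
#'
#' Donor A mimics a two-block forward-oriented centromere; donor B mimics a
#' centromere whose first and last blocks are inverted arrays.
#'
#' @param monomer_length,n_monomers,seed Passed through to [sim_config()].
#' @return List with elements `A` and `B` (two `sim_config`s).
#' @export
default_donor_configs <- function(monomer_length = 1400, n_monomers = 3L,
                                  seed = 1L) {
  list(
    A = sim_config(monomer_length = monomer_length,
                   blocks = data.frame(
                     n_monomers = rep(n_monomers, 2),
                     orientation = c("+", "+"),
                     divergence_from_ancestor = c(0.10, 0.10),
                     stringsAsFactors = FALSE),
                   seed = seed),
    B = sim_config(monomer_length = monomer_length,
                   blocks = data.frame(
                     n_monomers = rep(n_monomers, 4),
                     orientation = c("-", "+", "+", "-"),
                     divergence_from_ancestor = rep(0.10, 4),
                     stringsAsFactors = FALSE),
                   seed = seed + 1L))
}

#' Simulate a centric-fusion chromosome from two donor arrays
#'
#' Both donors descend from one shared ancestral monomer. The fused array
#' is assembled from copies of planned donor blocks (default plan: the
#' donor-B terminal inverted blocks flanking a forward donor-A block, the
#' arrangement reported for Robertsonian fusion centromeres), each copied
#' monomer then mutated by `post_fusion_divergence`.
#'
#' @param donorA_cfg,donorB_cfg [sim_config()]s (defaults:
#'   [default_donor_configs()]).
#' @param plan `data.frame` with `donor_label` ("A"/"B") and `donor_block`
#'   (block index within that donor) per fused block, in fused order.
#' @param post_fusion_divergence Per-site divergence applied to the fused
#'   copies (default 0.05).
#' @param seed Integer seed controlling everything (donor seeds are drawn
#'   from it).
#' @return List of class `sim_fusion` with `fused`, `donorA`, `donorB`
#'   (`sim_array` objects; `fused$truth$monomers` carries `donor_label` and
#'   `donor_block_id`) and `plan`.
#' @export
simulate_fusion <- function(donorA_cfg = NULL, donorB_cfg = NULL,
                            plan = NULL, post_fusion_divergence = 0.05,
                            seed = 1L) {
  set.seed(seed)
  if (is.null(donorA_cfg) || is.null(donorB_cfg)) {
    defaults <- default_donor_configs(seed = seed)
    if (is.null(donorA_cfg)) donorA_cfg <- defaults$A
    if (is.null(donorB_cfg)) donorB_cfg <- defaults$B
  }
  if (is.null(plan)) {
    plan <- data.frame(donor_label = c("B", "A", "B"),
                       donor_block = c(1L, 2L, nrow(donorB_cfg$blocks)),
                       stringsAsFactors = FALSE)
  }
  sub_seeds <- sample.int(.Machine$integer.max, 3L)
  ancestor <- simulate_monomer(donorA_cfg$monomer_length,
                               donorA_cfg$gc_content, sub_seeds[1])
  donorA_cfg$seed <- sub_seeds[2]
  donorB_cfg$seed <- sub_seeds[3]
  donorA <- simulate_array(donorA_cfg, ancestor = ancestor, id = "donorA")
  donorB <- simulate_array(donorB_cfg, ancestor = ancestor, id = "donorB")
  set.seed(sub_seeds[1] %% 1000000L + 7L)

  for (i in seq_len(nrow(plan))) {
    lab <- plan$donor_label[i]
    blk <- plan$donor_block[i]
    donor <- if (lab == "A") donorA else donorB
    if (!lab %in% c("A", "B") || !blk %in% donor$truth$blocks$block_id) {
      stop("fusion plan row ", i, " references a missing donor block")
    }
  }

  cfgF <- donorA_cfg # carries monomer length, ratio, insertion range, flank
  monomers <- list()
  pieces <- character(0)
  insertions <- list()
  pos <- 1L
  mono_id <- 0L
  push <- function(piece) {
    pieces[[length(pieces) + 1L]] <<- piece
    pos <<- pos + nchar(piece)
  }
  if (cfgF$flank_length > 0) push(.random_seq(cfgF$flank_length))
  for (i in seq_len(nrow(plan))) {
    lab <- plan$donor_label[i]
    blk <- plan$donor_block[i]
    donor <- if (lab == "A") donorA else donorB
    src <- donor$truth$monomers
    src <- src[src$block_id == blk, , drop = FALSE]
    for (r in seq_len(nrow(src))) {
      mono_id <- mono_id + 1L
      mut <- mutate_seq(src$seq[r], post_fusion_divergence, cfgF$ts_tv_ratio)
      strand <- src$strand[r]
      genomic <- if (strand == "-") unname(reverse_complement(mut$seq))
                 else mut$seq
      monomers[[mono_id]] <- data.frame(
        monomer_id = mono_id, block_id = i, start = pos,
        end = pos + nchar(genomic) - 1L, strand = strand,
        n_substitutions = nrow(mut$records), truncated = FALSE,
        seq = mut$seq, donor_label = lab, donor_block_id = blk,
        stringsAsFactors = FALSE)
      push(genomic)
    }
    if (i < nrow(plan)) {
      ilen <- cfgF$insertion_length_range[1] - 1L +
        sample.int(diff(cfgF$insertion_length_range) + 1L, 1L)
      insertions[[length(insertions) + 1L]] <- data.frame(
        start = pos, end = pos + ilen - 1L, length = ilen,
        stringsAsFactors = FALSE)
      push(.random_seq(ilen))
    }
  }
  if (cfgF$flank_length > 0) push(.random_seq(cfgF$flank_length))
  seq <- paste(pieces, collapse = "")
  names(seq) <- "fused"

  fused_blocks <- data.frame(
    block_id = seq_len(nrow(plan)),
    orientation = vapply(seq_len(nrow(plan)), function(i) {
      donor <- if (plan$donor_label[i] == "A") donorA else donorB
      donor$truth$blocks$orientation[plan$donor_block[i]]
    }, character(1)),
    n_monomers = vapply(seq_len(nrow(plan)), function(i) {
      donor <- if (plan$donor_label[i] == "A") donorA else donorB
      donor$truth$blocks$n_monomers[plan$donor_block[i]]
    }, integer(1)),
    donor_label = plan$donor_label,
    donor_block_id = plan$donor_block,
    stringsAsFactors = FALSE)

  fused <- structure(list(
    seq = seq,
    truth = list(monomers = do.call(rbind, monomers),
                 insertions = if (length(insertions))
                   do.call(rbind, insertions) else
                     data.frame(start = integer(0), end = integer(0),
                                length = integer(0)),
                 blocks = fused_blocks,
                 ancestor = ancestor),
    config = cfgF), class = "sim_array")
  structure(list(fused = fused, donorA = donorA, donorB = donorB,
                 plan = plan), class = "sim_fusion")
}

#' Block set from simulator ground truth
#'
#' Builds the `block_set` a perfect analysis would produce: members taken
#' from the planted monomer records, consensuses computed with
#' [block_consensus()]. Useful for validating downstream stages
#' independently of the scanner.
#'
#' @param arr A `sim_array`.
#' @param params An [align_params()] object.
#' @return A character vector of block consensuses named
#'   `block<block_id>`, usable wherever a `block_set` is accepted.
#' @export
truth_block_set <- function(arr, params = align_params()) {
  stopifnot(inherits(arr, "sim_array"))
  m <- arr$truth$monomers
  cons <- vapply(arr$truth$blocks$block_id, function(b)
    block_consensus(m$seq[m$block_id == b], params), character(1))
  setNames(cons, paste0("block", arr$truth$blocks$block_id))
}

#' Write simulator output (FASTA + truth tables)
#'
#' @param sim A `sim_array` or `sim_fusion`.
#' @param out_prefix Path prefix for the output files.
#' @return Character vector of written paths, invisibly.
#' @export
write_sim <- function(sim, out_prefix) {
  paths <- character(0)
  write_one <- function(arr, tag) {
    fa <- paste0(out_prefix, ".", tag, ".fa")
    write_fasta(arr$seq, fa)
    tsv <- paste0(out_prefix, ".", tag, ".truth.tsv")
    write.table(arr$truth$monomers, tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    bed <- paste0(out_prefix, ".", tag, ".truth.bed")
    m <- arr$truth$monomers
    bedtab <- data.frame(chrom = names(arr$seq), start = m$start - 1L,
                         end = m$end, name = paste0("monomer", m$monomer_id),
                         score = m$block_id, strand = m$strand)
    con <- file(bed, "w")
    writeLines("#chrom\tstart\tend\tname\tblock\tstrand", con)
    if (nrow(bedtab)) write.table(bedtab, con, sep = "\t", quote = FALSE,
                                  row.names = FALSE, col.names = FALSE)
    close(con)
    c(fa, tsv, bed)
  }
  if (inherits(sim, "sim_fusion")) {
    paths <- c(write_one(sim$fused, "fused"), write_one(sim$donorA, "donorA"),
               write_one(sim$donorB, "donorB"))
  } else {
    paths <- write_one(sim, "array")
  }
  invisible(paths)
}
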