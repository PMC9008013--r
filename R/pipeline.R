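# Full-analysis orchestration: scan -> blocks -> provenance -> motifs ->
# spectrum/saturation -> tree -> candidates, with per-stage outputs, a
# machine-readable JSON summary and deterministic file naming.

#' Pipeline run configuration
#'
#' @param reference Path to the reference monomer FASTA (required).
#' @param sequences Path to the FASTA of sequences to analyse. For
#'   provenance inference supply `fused`, `donor_a`, `donor_b` instead (or
#'   in addition).
#' @param fused,donor_a,donor_b Optional FASTA paths for a fused array and
#'   its two candidate donors.
#' @param anchors Optional gene-anchor TSV for candidate-scaffold
#'   reporting.
#' @param chrom_a,chrom_b Donor chromosome names for the anchor stage.
#' @param out_dir Output directory (created if absent).
#' @param min_identity,min_coverage Monomer scan thresholds
#'   ([scan_config()]).
#' @param min_block_identity,max_intra_gap Block segmentation thresholds
#'   ([segment_blocks()]).
#' @param max_mismatch Motif-scan mismatch allowance ([scan_motif()]).
#' @param saturation_ratio_threshold See [saturation_analysis()].
#' @param seed Seed recorded and set before the run (the analysis itself is
#'   deterministic; the seed matters when the pipeline is pointed at
#'   simulator output generated in the same session).
#' @param verbose Emit stage timing messages to stderr.
#' @return Object of class `run_config`.
#' @export
run_config <- function(reference, sequences = NULL, fused = NULL,
                       donor_a = NULL, donor_b = NULL, anchors = NULL,
                       chrom_a = "chrA", chrom_b = "chrB",
                       out_dir = "cenfuse_out",
                       min_identity = 0.70, min_coverage = 0.90,
                       min_block_identity = 0.85, max_intra_gap = 100,
                       max_mismatch = 4, saturation_ratio_threshold = 0.5,
                       seed = 1L, verbose = TRUE) {
  if (is.null(reference)) stop("a reference monomer FASTA is required")
  if (is.null(sequences) && is.null(fused)) {
    stop("supply 'sequences' and/or 'fused'/'donor_a'/'donor_b' inputs")
  }
  structure(list(reference = reference, sequences = sequences, fused = fused,
                 donor_a = donor_a, donor_b = donor_b, anchors = anchors,
                 chrom_a = chrom_a, chrom_b = chrom_b, out_dir = out_dir,
                 min_identity = min_identity, min_coverage = min_coverage,
                 min_block_identity = min_block_identity,
                 max_intra_gap = max_intra_gap, max_mismatch = max_mismatch,
                 saturation_ratio_threshold = saturation_ratio_threshold,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

.stage_msg <- function(cfg, fmt, ...) {
  if (cfg$verbose) {
    message(sprintf("[cenfuse %s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }
}

.analyse_one <- function(seqs, id, scfg, cfg, params) {
  t0 <- Sys.time()
  mono <- find_monomers(seqs[id], scfg, params)
  full <- filter_full_length(mono, scfg)
  bset <- segment_blocks(full, cfg$min_block_identity, cfg$max_intra_gap,
                         params)
  .stage_msg(cfg, "%s: %d monomers (%d full-length), %d blocks [%.1fs]",
             id, nrow(mono), nrow(full), nrow(bset$blocks),
             as.numeric(Sys.time() - t0, units = "secs"))
  list(monomers = mono, full_length = full, blocks = bset)
}

#' Run the full centromere-fusion analysis
#'
#' Stages: monomer scan and full-length filtering for every input
#' sequence; block segmentation; provenance inference when fused and donor
#' inputs are present; CENP-B-box motif scan of the block consensuses;
#' substitution spectrum of the fused overall consensus against each donor
#' overall consensus; saturation analysis and a neighbor-joining tree over
#' all full-length monomers; candidate-scaffold reporting when an anchor
#' table is given. Writes per-stage TSV/BED/FASTA/newick outputs plus
#' `summary.json` and a verbatim `config.json` echo into `out_dir`.
#'
#' @param cfg A [run_config()].
#' @param params An [align_params()] object.
#' @return The summary list, invisibly.
#' @export
run_full_analysis <- function(cfg, params = align_params()) {
  stopifnot(inherits(cfg, "run_config"))
  if (!file.exists(cfg$reference)) {
    stop("reference monomer FASTA not found: ", cfg$reference)
  }
  set.seed(cfg$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(cfg), file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  ref <- read_fasta(cfg$reference)
  if (length(ref) != 1L) stop("reference FASTA must contain exactly one record")
  scfg <- scan_config(ref, cfg$min_identity, cfg$min_coverage)

  inputs <- character(0)
  roles <- character(0)
  add_input <- function(path, role) {
    if (!is.null(path)) {
      inputs <<- c(inputs, path)
      roles <<- c(roles, role)
    }
  }
  add_input(cfg$fused, "fused")
  add_input(cfg$donor_a, "donor_a")
  add_input(cfg$donor_b, "donor_b")
  add_input(cfg$sequences, "sequences")

  seqs <- character(0)
  seq_role <- character(0)
  for (z in seq_along(inputs)) {
    s <- read_fasta(inputs[z])
    if (length(s) == 0L) stop("input FASTA has no records: ", inputs[z])
    seqs <- c(seqs, s)
    seq_role <- c(seq_role, rep(roles[z], length(s)))
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence ids across input FASTA files")
  }

  results <- lapply(names(seqs), function(id)
    .analyse_one(seqs, id, scfg, cfg, params))
  names(results) <- names(seqs)

  summary <- list(package = "cenfuse",
                  version = as.character(utils::packageVersion("cenfuse")),
                  seed = cfg$seed,
                  reference_id = names(ref),
                  reference_length = nchar(ref[[1]]))
  summary$sequences <- lapply(names(results), function(id) {
    r <- results[[id]]
    monomers_to_bed(r$full_length,
                    file.path(cfg$out_dir, paste0(id, ".monomers.bed")))
    write_monomer_table(r$full_length,
                        file.path(cfg$out_dir, paste0(id, ".monomers.tsv")))
    write_block_table(r$blocks,
                      file.path(cfg$out_dir, paste0(id, ".blocks.tsv")))
    if (nrow(r$blocks$blocks) > 0) {
      write_fasta(setNames(r$blocks$blocks$consensus,
                           paste0(id, ".block", r$blocks$blocks$block_id)),
                  file.path(cfg$out_dir, paste0(id, ".consensus.fa")))
    }
    list(id = id, role = seq_role[match(id, names(seqs))],
         length = nchar(seqs[[id]]),
         n_monomers = nrow(r$monomers),
         n_full_length = nrow(r$full_length),
         n_blocks = nrow(r$blocks$blocks),
         n_insertions = nrow(r$blocks$insertions),
         block_table = r$blocks$blocks[, c("block_id", "start", "end",
                                           "orientation", "n_members",
                                           "mean_pairwise_identity")])
  })

  # provenance
  if (!is.null(cfg$fused) && !is.null(cfg$donor_a) && !is.null(cfg$donor_b)) {
    fid <- names(seqs)[seq_role == "fused"]
    aid <- names(seqs)[seq_role == "donor_a"]
    bid <- names(seqs)[seq_role == "donor_b"]
    prov <- infer_provenance(results[[fid[1]]]$blocks,
                             results[[aid[1]]]$blocks,
                             results[[bid[1]]]$blocks, params)
    write.table(prov, file.path(cfg$out_dir, "provenance.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary$provenance <- prov
    .stage_msg(cfg, "provenance: %d fused blocks assigned", nrow(prov))
  }

  # motif scan over block consensuses
  motifs <- motif_catalogue()
  hit_rows <- list()
  for (id in names(results)) {
    bt <- results[[id]]$blocks$blocks
    for (b in seq_len(nrow(bt))) {
      cons <- setNames(bt$consensus[b], paste0(id, ".block", b))
      for (mt in c("cenpb_consensus", "cenpb_element")) {
        h <- scan_motif(cons, motifs[[mt]], cfg$max_mismatch)
        if (nrow(h)) {
          h$motif <- mt
          hit_rows[[length(hit_rows) + 1L]] <- h
        }
      }
    }
  }
  if (length(hit_rows)) {
    hits <- do.call(rbind, hit_rows)
    write_motif_hits(hits, file.path(cfg$out_dir, "motif_hits.tsv"))
    summary$motif_hits <- nrow(hits)
    summary$motif_best <- hits[which.min(hits$total_mismatches),
                               c("source_id", "start", "strand", "window",
                                 "total_mismatches", "core_mismatches")]
  } else {
    summary$motif_hits <- 0L
  }
  .stage_msg(cfg, "motifs: %d hits", summary$motif_hits)

  # spectra between overall consensuses, saturation + tree over monomers
  overall <- lapply(results, function(r) {
    if (nrow(r$full_length) >= 2) block_consensus(r$full_length$seq, params)
    else if (nrow(r$full_length) == 1) r$full_length$seq
    else NA_character_
  })
  if (!is.null(summary$provenance)) {
    fid <- names(seqs)[seq_role == "fused"][1]
    spectra <- list()
    for (did in names(seqs)[seq_role %in% c("donor_a", "donor_b")]) {
      if (is.na(overall[[fid]]) || is.na(overall[[did]])) next
      rows <- multi_align(c(a = overall[[fid]], b = overall[[did]]), params)
      sp <- substitution_spectrum(rows[1], rows[2])
      spectra[[did]] <- list(against = did,
                             n_substitutions = sp$n_substitutions,
                             n_transitions = sp$n_transitions,
                             n_transversions = sp$n_transversions,
                             n_deletions = sp$n_deletions,
                             prop_transitions = sp$prop_transitions,
                             prop_transversions = sp$prop_transversions)
    }
    summary$spectra <- unname(spectra)
  }

  all_mono <- do.call(rbind, lapply(names(results), function(id) {
    m <- results[[id]]$full_length
    if (nrow(m)) data.frame(id = paste0(id, ".", m$index), seq = m$seq,
                            stringsAsFactors = FALSE) else NULL
  }))
  if (!is.null(all_mono) && nrow(all_mono) >= 4) {
    mono_seqs <- setNames(all_mono$seq, all_mono$id)
    sat <- saturation_analysis(mono_seqs, params,
                               cfg$saturation_ratio_threshold,
                               aligned = FALSE)
    write_pair_table(sat, file.path(cfg$out_dir, "pairs.tsv"))
    summary$saturation <- list(ts_slope = sat$ts_slope,
                               tv_slope = sat$tv_slope,
                               ts_saturated = sat$ts_saturated,
                               tv_saturated = sat$tv_saturated)
    d <- distance_matrix(mono_seqs, params, aligned = FALSE)
    nwk <- nj_tree(d)
    writeLines(nwk, file.path(cfg$out_dir, "tree.nwk"))
    summary$tree = nwk
    .stage_msg(cfg, "tree/saturation over %d monomers", nrow(all_mono))
  }

  # candidates
  if (!is.null(cfg$anchors)) {
    anch <- load_anchors(cfg$anchors)
    cand <- candidate_scaffolds(anch, cfg$chrom_a, cfg$chrom_b)
    write.table(cand, file.path(cfg$out_dir, "candidates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    segs <- lapply(cand$scaffold_id, function(sid) {
      s <- segment_anchors(anch[anch$scaffold_id == sid, , drop = FALSE])
      s$gene_ids <- vapply(s$gene_ids, paste, character(1), collapse = ",")
      s$scaffold_id <- sid
      s
    })
    if (length(segs)) {
      write.table(do.call(rbind, segs),
                  file.path(cfg$out_dir, "segments.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    summary$candidates <- cand
    .stage_msg(cfg, "candidates: %d scaffold(s)", nrow(cand))
  }

  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows", pretty = TRUE)
  invisible(summary)
}
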