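# Shared simulation fixtures, built once per test session.

.fixture_env <- new.env(parent = emptyenv())

# A small two-implant tumour simulation run through the full pipeline:
# one plus-strand TPRT insertion with TSD and poly-A, one minus-strand
# endonuclease-independent insertion with a 550 nt site deletion.
mini_run <- function() {
  if (!is.null(.fixture_env$mini)) return(.fixture_env$mini)
  ref <- makeReference(1, 150000, 0.41, n_decoy_te = 2, seed = 7)
  truth <- rbind(
    implantTruth("tprt1", "TPRT", "contig01", 40000, "+", 4000, 6018,
                 polya_len = 40, tsd_len = 15, en_motif_state = "canonical"),
    implantTruth("eni1", "ENi", "contig01", 80000, "-", 5108, 6018,
                 deletion_len = 550, en_motif_state = "absent"))
  imp <- implantInsertions(ref, truth, seed = 3)
  probes <- probesFromTruth(imp$truth, 300)
  rd <- simulateReads(imp$genome, probes,
                      ReadSimConfig(coverage = 4, enrichment_factor = 12,
                                    error_rate = 0.001, seed = 11))
  names(rd$r1) <- paste0(names(rd$r1), "/1")
  names(rd$r2) <- paste0(names(rd$r2), "/2")
  res <- callInsertions(list(T1 = c(rd$r1, rd$r2)), imp$reference,
                        ref$decoys)
  .fixture_env$mini <- list(ref = ref, truth = imp$truth, imp = imp,
                            reads = c(rd$r1, rd$r2), res = res)
  .fixture_env$mini
}

# Minimal cluster row for pairing tests, bypassing read alignment.
make_cluster_row <- function(contig, breakpoint, clip_side, element_strand,
                             n_support = 5L, consensus_clip = NULL,
                             family = "L1-Ta", cons_start = 4000L,
                             cons_end = 6018L, clip_end = NA_integer_,
                             filters = "") {
  l1 <- as.character(consensusSequence(l1Consensus("L1-Ta")))
  if (is.null(consensus_clip)) {
    consensus_clip <- if (clip_side == "right")
      substr(l1, cons_start, cons_start + 59L)
    else substr(l1, cons_end - 59L, cons_end)
    if (is.na(clip_end)) clip_end <- nchar(consensus_clip)
  }
  te_side <- if ((clip_side == "right") == (element_strand == "+")) "5p"
    else "3p"
  df <- data.frame(contig = contig, breakpoint = as.integer(breakpoint),
                   te_side = te_side, clip_side = clip_side,
                   element_strand = element_strand,
                   n_support = as.integer(n_support),
                   consensus_clip = consensus_clip, family = family,
                   cons_start = cons_start, cons_end = cons_end,
                   identity = 1, aligned_len = nchar(consensus_clip),
                   clip_start = 1L, clip_end = clip_end,
                   hit_strand = "+", genome_identity = 1,
                   strand_confidence = 1, family_confidence = 1,
                   position_confidence = 1, filters = filters,
                   stringsAsFactors = FALSE)
  df$support <- I(list(sprintf("r%03d", seq_len(n_support))))
  df$support_samples <- I(list(rep("T1", n_support)))
  df$cluster_id <- paste0("jc_", contig, "_", breakpoint, "_", clip_side)
  df
}

# Minimal call row for somatic-criteria tests.
make_call_row <- function(support = c(T1 = 12, N1 = 0),
                          bp_right = 10000L, bp_left = 10001L,
                          element_len = 5000L, has_3p = TRUE,
                          strand_conf = 1, family_conf = 1, pos_conf = 1,
                          mh = 0L, contig = "contig01") {
  call <- data.frame(contig = contig, bp5 = bp_right, bp3 = bp_left,
                     bp_right = bp_right, bp_left = bp_left, strand = "+",
                     family = "L1-Ta", tsd_len = 0L, tsd_seq = "",
                     deletion_len = 0L, polya_len = 30L, extra_3p = "",
                     cons_start = 1000L, cons_end = 6018L,
                     element_len = element_len, microhomology = mh,
                     strand_confidence = strand_conf,
                     family_confidence = family_conf,
                     position_confidence = pos_conf,
                     support_5p = 10L, support_3p = if (has_3p) 10L else 0L,
                     cluster_5p = "a", cluster_3p = "b", filters = "",
                     call_id = "call0001", stringsAsFactors = FALSE)
  if (!has_3p) { call$bp3 <- NA_integer_; call$bp_left <- NA_integer_ }
  for (s in names(support)) call[[paste0("support.", s)]] <- support[[s]]
  call
}
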