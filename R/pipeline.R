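# End-to-end orchestration: per-sample alignment, clustering, filtering,
# pairing, support counting; plus study-patterned fixtures and randomized
# implant sets for simulation experiments.

#' Run the insertion-calling pipeline on per-sample read sets
#'
#' Aligns each sample's reads against the reference, marks duplicates,
#' extracts and realigns soft clips, clusters junctions, applies the
#' cluster filters, pairs junctions into calls and counts per-sample
#' support.
#'
#' @param read_sets Named list (one element per sample) of named character
#'   vectors of reads, or a single data.frame of precomputed alignments
#'   (with a \code{sample} column).
#' @param reference Reference genome [Biostrings::DNAStringSet].
#' @param te_annotation [GenomicRanges::GRanges] of reference TE intervals.
#' @param consensus_set Consensus set for clip realignment.
#' @param minclip Minimum soft-clip length (nt).
#' @param mincluster Minimum reads per junction cluster.
#' @param window Breakpoint clustering window (nt).
#' @param pairing_window Maximum 5'/3' junction offset (nt).
#' @return List with \code{calls}, \code{clusters}, \code{clips} and
#'   \code{alignments}.
#' @export
callInsertions <- function(read_sets, reference, te_annotation,
                           consensus_set = consensusSet(), minclip = 30L,
                           mincluster = 2L, window = 10L,
                           pairing_window = 700L) {
  if (is.data.frame(read_sets)) {
    aln <- read_sets
  } else {
    stopifnot(!is.null(names(read_sets)))
    aln <- do.call(rbind, lapply(names(read_sets), function(s)
      alignReads(read_sets[[s]], reference, sample = s)))
  }
  aln <- markDuplicates(aln)
  clips <- buildClipTable(aln, consensus_set, minclip = minclip)
  clusters <- clusterJunctions(clips, mincluster = mincluster,
                               window = window,
                               consensus_set = consensus_set)
  clusters <- filterClusters(clusters, reference, te_annotation)
  calls <- pairAndAnnotate(clusters, reference,
                           pairing_window = pairing_window,
                           consensus_set = consensus_set)
  calls <- countSupport(calls, clips, window = window)
  list(calls = calls, clusters = clusters, clips = clips, alignments = aln)
}

#' Randomized implant set of the four mechanistic classes
#'
#' Draws integration sites across the reference (well away from contig
#' ends, each other, and any annotated TE interval) and parameterises each
#' class with the typical ranges used throughout the package: TPRT with
#' 4-16 nt TSDs and 15-60 nt poly-A tails, endonuclease-independent events
#' with 50-600 nt site deletions, transductions carrying a 30-60 nt unique
#' 3' flank, and recombination-class events with an L1PA2 donor, an
#' Alu-derived flank and a short deletion.
#'
#' @param reference Output of [makeReference()].
#' @param n_tprt,n_eni,n_transduction,n_recombination Events per class.
#' @param seed Integer seed.
#' @param consensus_set Consensus set (element lengths and Alu source).
#' @return Data.frame of [implantTruth()] rows.
#' @export
simulateTruthSet <- function(reference, n_tprt = 4L, n_eni = 4L,
                             n_transduction = 2L, n_recombination = 2L,
                             seed = 1L, consensus_set = consensusSet()) {
  genome <- reference$genome
  n_tot <- n_tprt + n_eni + n_transduction + n_recombination
  l1 <- as.character(consensusSequence(consensus_set[["L1-Ta"]]))
  pa2 <- as.character(consensusSequence(consensus_set[["L1PA2"]]))
  alu <- as.character(consensusSequence(consensus_set[["Alu"]]))
  Lc <- nchar(l1)
  with_seed(seed, {
    # spread sites over contigs, keeping clear of ends, decoys, each other
    lens <- nchar(as.character(genome))
    avail <- lapply(names(genome), function(ci) {
      lo <- 3000L; hi <- lens[[ci]] - 3000L
      seq(lo, hi, by = 3500L)
    })
    cand <- data.frame(
      contig = rep(names(genome), lengths(avail)),
      site = unlist(avail), stringsAsFactors = FALSE)
    if (length(reference$decoys)) {
      dg <- GenomicRanges::GRanges(cand$contig,
        IRanges::IRanges(cand$site - 1500L, cand$site + 1500L))
      cand <- cand[GenomicRanges::countOverlaps(dg, reference$decoys) == 0L, ]
    }
    if (nrow(cand) < n_tot) stop("reference too small for requested implants")
    pick <- cand[sort(sample.int(nrow(cand), n_tot)), ]
    pick <- pick[sample.int(n_tot), ]          # shuffle class assignment
    classes <- rep(c("TPRT", "ENi", "TRANSDUCTION", "RECOMBINATION"),
                   c(n_tprt, n_eni, n_transduction, n_recombination))
    rows <- list()
    # 5' truncation points giving crisp junctions: the donor base at the
    # truncation must not be A, and for minus-strand TPRT-type events the
    # first six donor bases must be A-free (their complement would otherwise
    # collide with the TTTT of the reverse-strand EN motif at the junction)
    pick_start <- function(donor_seq, strand = "+") {
      repeat {
        a <- sample(2500:5200, 1L)
        win <- substr(donor_seq, a, a + 5L)
        if (strand == "-" && !grepl("A", win, fixed = TRUE)) return(a)
        if (strand == "+" && substr(win, 1L, 1L) != "A") return(a)
      }
    }
    for (i in seq_len(n_tot)) {
      cls <- classes[i]
      strand <- sample(c("+", "-"), 1L)
      id <- sprintf("imp%02d_%s", i, cls)
      if (cls == "TPRT") {
        rows[[i]] <- implantTruth(id, "TPRT", pick$contig[i], pick$site[i],
          strand, pick_start(l1, strand), Lc,
          polya_len = sample(15:60, 1L), tsd_len = sample(4:16, 1L),
          en_motif_state = sample(c("canonical", "degenerate"), 1L))
      } else if (cls == "ENi") {
        rows[[i]] <- implantTruth(id, "ENi", pick$contig[i], pick$site[i],
          strand, pick_start(l1), Lc, deletion_len = sample(50:600, 1L),
          en_motif_state = "absent")
      } else if (cls == "TRANSDUCTION") {
        # flanks open with a non-A anchor so the poly-A tail boundary is
        # well defined in the truth; tail + flank stay well inside a read
        # length so the 3' junction remains observable
        fl <- paste0("GTC", random_dna(sample(26:46, 1L), 0.5), "G")
        rows[[i]] <- implantTruth(id, "TRANSDUCTION", pick$contig[i],
          pick$site[i], strand, pick_start(l1, strand), Lc,
          polya_len = sample(15:35, 1L), tsd_len = sample(4:16, 1L),
          en_motif_state = "canonical", transduced_flank = fl,
          flank_source = "donor_3p")
      } else {
        a <- sample.int(nchar(alu) - 40L, 1L)
        fl <- substr(alu, a, a + sample(29:39, 1L))
        if (substr(fl, nchar(fl), nchar(fl)) == "A")
          fl <- paste0(substr(fl, 1L, nchar(fl) - 1L), "G")
        vf <- strsplit(fl, "")[[1L]]
        vf[1:3][vf[1:3] == "A"] <- "C"
        fl <- paste(vf, collapse = "")
        rows[[i]] <- implantTruth(id, "RECOMBINATION", pick$contig[i],
          pick$site[i], strand, pick_start(pa2), Lc, deletion_len =
          sample(30:100, 1L), en_motif_state = "absent",
          transduced_flank = fl, flank_source = "Alu",
          donor_family = "L1PA2")
      }
    }
    do.call(rbind, rows)
  })
}

#' The three study-patterned archetype implants
#'
#' Deterministic fixtures reproducing the anatomies of the three
#' characterised glioma L1 mutations: a recombination-class event (5'
#' truncated L1PA2 antisense insertion carrying a 37 nt Alu-derived 3'
#' flank, a 58 nt site deletion, no poly-A, no TSD, no EN motif,
#' integrated into an annotated Alu); an endonuclease-independent event
#' (truncated L1-Ta, 550 nt site deletion, no poly-A/TSD/motif); and a
#' TPRT-type event (L1-Ta with a 102 nt poly-A tail and a degenerate EN
#' motif).
#'
#' @param seed Integer seed for the background reference.
#' @return List with \code{reference} (genome + decoys), \code{truth},
#'   \code{implanted} (result of [implantInsertions()]) and
#'   \code{te_annotation} (decoys plus the Alu element at the
#'   recombination target site).
#' @export
archetypeFixtures <- function(seed = 42L) {
  ref <- makeReference(1L, 150000L, 0.41, n_decoy_te = 0L, seed = seed)
  l1 <- consensusSet()
  Lc <- length(consensusSequence(l1[["L1-Ta"]]))
  alu <- as.character(consensusSequence(l1[["Alu"]]))
  # place an Alu copy at the recombination target so the integration site
  # lies within an annotated element of the transduced flank's family
  g <- as.character(ref$genome)[[1L]]
  alu_at <- 39900L
  g <- paste0(substr(g, 1L, alu_at - 1L), alu,
              substr(g, alu_at + nchar(alu), nchar(g)))
  ref$genome <- Biostrings::DNAStringSet(stats::setNames(g, "contig01"))
  alu_gr <- GenomicRanges::GRanges("contig01",
    IRanges::IRanges(alu_at, alu_at + nchar(alu) - 1L), strand = "+",
    name = "alu_target", family = "Alu", trunc_start = 1L, divergence = 0)
  te_annotation <- alu_gr
  flank37 <- substr(alu, 101L, 137L)
  if (substr(flank37, 37L, 37L) == "A")
    flank37 <- paste0(substr(flank37, 1L, 36L), "G")
  v37 <- strsplit(flank37, "")[[1L]]
  v37[1:3][v37[1:3] == "A"] <- "C"     # non-A anchor after the element end
  flank37 <- paste(v37, collapse = "")
  truth <- rbind(
    implantTruth("mecp2_like", "RECOMBINATION", "contig01", 40000L, "-",
                 Lc - 899L, Lc, deletion_len = 58L,
                 en_motif_state = "absent", transduced_flank = flank37,
                 flank_source = "Alu", donor_family = "L1PA2"),
    implantTruth("egfr_like", "ENi", "contig01", 80000L, "-",
                 5108L, Lc, deletion_len = 550L, en_motif_state = "absent"),
    implantTruth("cep112_like", "TPRT", "contig01", 120000L, "+",
                 4200L, Lc, polya_len = 102L, tsd_len = 14L,
                 en_motif_state = "degenerate"))
  implanted <- implantInsertions(ref, truth, seed = seed + 1L)
  # te_annotation excludes the implant loci themselves: only the Alu target
  list(reference = ref, truth = implanted$truth, implanted = implanted,
       te_annotation = te_annotation)
}

#' Build call rows directly from a simulation truth table
#'
#' Bypasses read simulation and alignment: constructs, for each implanted
#' insertion, the call a perfect caller would emit (junction coordinates
#' from the truth, the element-oriented 3' junction clip cut from the
#' inserted sequence). Used to exercise hallmark detection and
#' classification deterministically.
#'
#' @param implanted Result of [implantInsertions()].
#' @param consensus_set Consensus set used at implant time.
#' @param clip_len Length of the synthesized 3' junction clip (nt).
#' @return Data.frame with the same columns as [pairAndAnnotate()].
#' @export
truthCalls <- function(implanted, consensus_set = consensusSet(),
                       clip_len = 150L) {
  tt <- implanted$truth
  rows <- vector("list", nrow(tt))
  for (i in seq_len(nrow(tt))) {
    tr <- tt[i, , drop = FALSE]
    donor <- consensus_set[[tr$donor_family]]
    core <- substr(as.character(consensusSequence(donor)),
                   tr$cons_start, tr$cons_end)
    ins_fwd <- paste0(core, strrep("A", tr$polya_len), tr$transduced_flank)
    clip <- substr(ins_fwd, max(1L, nchar(ins_fwd) - clip_len + 1L),
                   nchar(ins_fwd))
    core_in_clip <- max(0L, nchar(clip) - tr$polya_len -
                          nchar(tr$transduced_flank))
    pa <- detectPolyA(clip, element_end = core_in_clip)
    extra <- substr(clip, core_in_clip + pa$run_len + 1L, nchar(clip))
    bpR <- tr$bpR_ref; bpL <- tr$bpL_ref
    rows[[i]] <- data.frame(
      contig = tr$contig,
      bp5 = if (tr$strand == "+") bpR else bpL,
      bp3 = if (tr$strand == "+") bpL else bpR,
      bp_right = bpR, bp_left = bpL,
      strand = tr$strand, family = tr$donor_family,
      tsd_len = tr$tsd_len, tsd_seq = tr$tsd_seq,
      deletion_len = tr$deletion_len,
      polya_len = pa$polya_len, extra_3p = extra,
      cons_start = tr$cons_start, cons_end = tr$cons_end,
      element_len = tr$cons_end - tr$cons_start + 1L,
      microhomology = 0L, strand_confidence = 1, family_confidence = 1,
      position_confidence = 1, support_5p = 10L, support_3p = 10L,
      cluster_5p = NA_character_, cluster_3p = NA_character_,
      filters = "", call_id = tr$insertion_id, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
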