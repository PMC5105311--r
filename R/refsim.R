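# Synthetic-data simulator: reference genomes with decoy L1 copies,
# mechanistically distinct implanted insertions, capture-enriched paired-end
# reads, and bisulfite amplicon reads.

#' Generate a synthetic reference genome with decoy TE copies
#'
#' Builds one or more random contigs and optionally places "decoy" copies of
#' the TE consensus: possibly 5'-truncated, 2-10 % mutated copies that stand
#' in for the reference TE complement (the loci the caller must exclude, and
#' the reference cohort used for sensitivity metrics). Decoy 3' ends are
#' always intact.
#'
#' @param n_contigs Number of contigs.
#' @param contig_len Length of each contig (bp). Must be at least 20 times
#'   the consensus length when decoys are requested.
#' @param gc_fraction GC content of the random background.
#' @param n_decoy_te Total number of decoy TE copies to place.
#' @param consensus A [TEConsensus-class] used for the decoys.
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @param decoy_full_length If TRUE decoys are never truncated.
#' @param decoy_divergence Length-2 numeric, range of per-base substitution
#'   divergence of decoys from the consensus.
#' @return A list with \code{genome} ([Biostrings::DNAStringSet]) and
#'   \code{decoys} ([GenomicRanges::GRanges] with mcols \code{name},
#'   \code{family}, \code{trunc_start}, \code{divergence}).
#' @export
makeReference <- function(n_contigs, contig_len, gc_fraction = 0.41,
                          n_decoy_te = 0L, consensus = l1Consensus("L1-Ta"),
                          seed = 1L, decoy_full_length = FALSE,
                          decoy_divergence = c(0.02, 0.10)) {
  Lc <- length(consensusSequence(consensus))
  if (n_decoy_te > 0L && contig_len < 20L * Lc)
    stop("contig_len too short to host decoys: need >= 20x consensus length")
  with_seed(seed, {
    contigs <- vapply(seq_len(n_contigs), function(i)
      random_dna(contig_len, gc_fraction), character(1L))
    names(contigs) <- sprintf("contig%02d", seq_len(n_contigs))
    dec <- NULL
    if (n_decoy_te > 0L) {
      cons <- as.character(consensusSequence(consensus))
      # round-robin placement across contigs, non-overlapping with margins
      assign_to <- rep(seq_len(n_contigs), length.out = n_decoy_te)
      rows <- list()
      for (ci in seq_len(n_contigs)) {
        k <- sum(assign_to == ci)
        if (k == 0L) next
        # evenly spaced anchor slots with jitter keep placements disjoint
        slot <- floor(seq(2000, contig_len - Lc - 2000, length.out = k + 1L))
        starts <- integer(k)
        for (j in seq_len(k)) {
          lo <- slot[j]; hi <- max(lo, slot[j + 1L] - Lc - 1000L)
          if (hi < lo) stop("contig too short to host requested decoys")
          starts[j] <- sample(seq(lo, hi), 1L)
        }
        for (j in seq_len(k)) {
          a <- if (decoy_full_length || runif(1) < 0.4) 1L else
            sample.int(Lc - 1000L, 1L)
          dseq <- substr(cons, a, Lc)
          dv <- runif(1L, decoy_divergence[1L], decoy_divergence[2L])
          npos <- max(1L, round(dv * nchar(dseq)))
          dseq <- mutate_positions(dseq, sample.int(nchar(dseq), npos))
          strand <- sample(c("+", "-"), 1L)
          if (strand == "-") dseq <- revcomp(dseq)
          s0 <- starts[j]
          contigs[ci] <- paste0(substr(contigs[ci], 1L, s0 - 1L), dseq,
                                substr(contigs[ci], s0 + nchar(dseq),
                                       contig_len))
          rows[[length(rows) + 1L]] <- data.frame(
            contig = names(contigs)[ci], start = s0,
            end = s0 + nchar(dseq) - 1L, strand = strand,
            trunc_start = a, divergence = dv)
        }
      }
      df <- do.call(rbind, rows)
      dec <- GenomicRanges::GRanges(df$contig,
        IRanges::IRanges(df$start, df$end), strand = df$strand,
        name = sprintf("decoy%03d", seq_len(nrow(df))),
        family = teFamily(consensus),
        trunc_start = df$trunc_start, divergence = df$divergence)
    } else {
      dec <- GenomicRanges::GRanges()
    }
    list(genome = Biostrings::DNAStringSet(contigs), decoys = dec)
  })
}

#' Specify one insertion to implant
#'
#' Constructs a one-row truth record describing a single simulated
#' L1-associated mutation of one of four mechanistic classes:
#' \describe{
#'   \item{TPRT}{canonical target-primed reverse transcription: EN motif,
#'     optional TSD, mandatory poly-A tail, no site deletion.}
#'   \item{ENi}{endonuclease-independent integration: no motif, no TSD, no
#'     poly-A, with a genomic deletion at the site.}
#'   \item{TRANSDUCTION}{TPRT-type insertion carrying a 3' transduced flank
#'     from its donor locus.}
#'   \item{RECOMBINATION}{rearrangement-type event: older-subfamily (L1PA2)
#'     donor, no motif, no poly-A, site deletion, optional non-L1 flank.}
#' }
#'
#' @param insertion_id Identifier.
#' @param mech_class One of TPRT, ENi, TRANSDUCTION, RECOMBINATION.
#' @param contig,site Integration locus: the insertion lands immediately
#'   after 1-based reference position \code{site}.
#' @param strand "+" or "-".
#' @param cons_start,cons_end 1-based closed interval of the donor consensus
#'   carried by the insertion (cons_start > 1 means 5' truncation).
#' @param polya_len,tsd_len,deletion_len Non-negative integers; TSD and
#'   deletion are mutually exclusive.
#' @param en_motif_state "canonical", "degenerate" or "absent".
#' @param transduced_flank Optional nucleotide string appended 3' of the
#'   poly-A (element orientation), or "".
#' @param flank_source Annotation of the flank's origin (e.g. "Alu",
#'   "donor_3p"); used to register the donor-flank database.
#' @param donor_family "L1-Ta" or "L1PA2".
#' @return A one-row data.frame.
#' @export
implantTruth <- function(insertion_id, mech_class, contig, site, strand = "+",
                         cons_start, cons_end, polya_len = 0L, tsd_len = 0L,
                         deletion_len = 0L, en_motif_state = "absent",
                         transduced_flank = "", flank_source = "",
                         donor_family = "L1-Ta") {
  stopifnot(mech_class %in% c("TPRT", "ENi", "TRANSDUCTION", "RECOMBINATION"),
            en_motif_state %in% c("canonical", "degenerate", "absent"),
            strand %in% c("+", "-"),
            donor_family %in% c("L1-Ta", "L1PA2"))
  if (tsd_len > 0L && deletion_len > 0L)
    stop("tsd_len and deletion_len are mutually exclusive")
  if (mech_class == "TPRT" &&
      (polya_len <= 0L || en_motif_state == "absent"))
    stop("TPRT requires polya_len > 0 and an EN motif")
  if (mech_class == "ENi" && (tsd_len != 0L || polya_len != 0L))
    stop("ENi requires tsd_len = 0 and polya_len = 0")
  if (mech_class == "RECOMBINATION" &&
      (donor_family != "L1PA2" || en_motif_state != "absent"))
    stop("RECOMBINATION requires donor_family L1PA2 and no EN motif")
  data.frame(insertion_id = insertion_id, mech_class = mech_class,
             contig = contig, site = as.integer(site), strand = strand,
             cons_start = as.integer(cons_start),
             cons_end = as.integer(cons_end),
             polya_len = as.integer(polya_len),
             tsd_len = as.integer(tsd_len),
             deletion_len = as.integer(deletion_len),
             en_motif_state = en_motif_state,
             transduced_flank = transduced_flank,
             flank_source = flank_source,
             donor_family = donor_family,
             stringsAsFactors = FALSE)
}

# Top-strand EN motif window for an insertion point s (1-based, insert after
# s). Plus strand: TT at [s-1,s], AAAA at [s+1,s+4]; minus strand mirrored.
en_motif_window <- function(site, strand) {
  if (strand == "+") (site - 1L):(site + 4L) else (site - 3L):(site + 2L)
}

en_site_from_context <- function(ctx, strand) {
  # ctx is the 6 nt top-strand window; returns the motif-oriented 6-mer
  if (strand == "+") ctx else revcomp(ctx)
}

# Rewrite the motif window of reference string `ref` at `site` to the state
# requested. `avoid` is an optional named character vector (names = absolute
# reference positions) of bases the rewrite must not introduce there: the
# insert bases adjacent across the junctions, which would otherwise let
# alignment slide over the breakpoint. Returns the modified string.
rewrite_en_site <- function(ref, site, strand, state, avoid = character()) {
  w <- en_motif_window(site, strand)
  motif_top <- if (strand == "+") "TTAAAA" else revcomp("TTAAAA")
  avoid_at <- function(p) {
    a <- avoid[as.character(p)]
    if (length(a) == 1L && !is.na(a)) a else NA_character_
  }
  if (state %in% c("canonical", "degenerate")) {
    ref <- paste0(substr(ref, 1L, w[1L] - 1L), motif_top,
                  substr(ref, w[6L] + 1L, nchar(ref)))
    if (state == "degenerate") {
      k <- sample(1:2, 1L)
      # substitute towards C/G only: an A written next to the insertion
      # point would blur the tail/junction boundary
      v <- strsplit(ref, "", fixed = TRUE)[[1L]]
      for (p in sample(w, k)) {
        v[p] <- sample(rep(setdiff(c("C", "G"), c(v[p], avoid_at(p))), 2L),
                       1L)
      }
      ref <- paste(v, collapse = "")
    }
  } else {
    # ensure the site is NOT motif-like (Hamming distance >= 3 from
    # TTAAAA), without writing a base that matches the pattern slot or the
    # junction-adjacent insert base
    pat <- strsplit(motif_top, "")[[1L]]   # top-strand pattern at w
    repeat {
      site6 <- en_site_from_context(substr(ref, w[1L], w[6L]), strand)
      d <- hamming(site6, "TTAAAA")
      if (d >= 3L) break
      agree <- which(utf8ToInt(substr(ref, w[1L], w[6L])) == utf8ToInt(motif_top))
      i <- sample(rep(agree, 2L), 1L)
      p <- w[i]
      v <- substr(ref, p, p)
      choices <- setdiff(DNA_BASES4, c(v, pat[i], avoid_at(p)))
      repl <- sample(rep(choices, 2L), 1L)
      ref <- paste0(substr(ref, 1L, p - 1L), repl,
                    substr(ref, p + 1L, nchar(ref)))
    }
    # independent of the motif state, window positions adjacent to the
    # junctions must not equal the corresponding insert bases
    for (p in w) {
      a <- avoid_at(p)
      if (!is.na(a) && substr(ref, p, p) == a) {
        site6 <- en_site_from_context(substr(ref, w[1L], w[6L]), strand)
        i <- which(w == p)
        choices <- setdiff(DNA_BASES4, c(a, pat[i]))
        repl <- sample(rep(choices, 2L), 1L)
        ref <- paste0(substr(ref, 1L, p - 1L), repl,
                      substr(ref, p + 1L, nchar(ref)))
      }
    }
  }
  ref
}

# Build the plus-strand inserted sequence for one truth row.
build_insert <- function(tr, consensus_set) {
  donor <- consensus_set[[tr$donor_family]]
  core <- substr(as.character(consensusSequence(donor)),
                 tr$cons_start, tr$cons_end)
  ins <- paste0(core, strrep("A", tr$polya_len), tr$transduced_flank)
  if (tr$strand == "-") ins <- revcomp(ins)
  ins
}

#' Implant insertions into a reference genome
#'
#' Writes each specified insertion into the genome: left flank (with TSD copy
#' when \code{tsd_len > 0}), the (possibly reverse-complemented) consensus
#' segment, poly-A run, optional transduced flank, then the right flank with
#' \code{deletion_len} reference bases removed. Sites with a canonical or
#' degenerate EN state have the TT/AAAA recognition motif written into the
#' \emph{reference} around the cleavage point first (EN selects such sites,
#' so tumour and normal genomes share them); "absent" sites are guaranteed
#' non-motif-like. Single reference bases adjacent to each junction are
#' adjusted so that no chance microhomology blurs the junction coordinates
#' (see the methods vignette).
#'
#' @param reference Output of [makeReference()] (or a list with
#'   \code{genome} and \code{decoys}).
#' @param truth A data.frame of rows from [implantTruth()].
#' @param seed Integer seed (controls degenerate-motif choices etc.).
#' @param consensus_set Named list of consensus objects, as
#'   [consensusSet()].
#' @return List with \code{genome} (mutated [Biostrings::DNAStringSet]),
#'   \code{reference} (site-prepared reference genome), \code{truth}
#'   (finalized table with junction coordinates \code{bpR_ref},
#'   \code{bpL_ref} in reference coordinates and \code{bpR_mut},
#'   \code{bpL_mut} in mutated coordinates), and \code{donor_flanks}
#'   ([Biostrings::DNAStringSet] of registered transduced flanks with
#'   \code{source} metadata).
#' @export
implantInsertions <- function(reference, truth, seed = 1L,
                              consensus_set = consensusSet()) {
  genome <- reference$genome
  stopifnot(all(truth$contig %in% names(genome)))
  for (cs in c("cons_start", "cons_end")) {
    Lc <- vapply(truth$donor_family, function(f)
      length(consensusSequence(consensus_set[[f]])), integer(1L))
    if (any(truth[[cs]] < 1L | truth[[cs]] > Lc))
      stop("consensus_interval outside consensus bounds")
  }
  with_seed(seed, {
    ref_out <- as.character(genome)
    mut_out <- character(length(genome)); names(mut_out) <- names(genome)
    truth$bpR_ref <- NA_integer_; truth$bpL_ref <- NA_integer_
    truth$bpR_mut <- NA_integer_; truth$bpL_mut <- NA_integer_
    truth$ins_len <- NA_integer_; truth$tsd_seq <- ""
    flanks <- character(); flank_src <- character()
    for (ci in names(genome)) {
      rows <- which(truth$contig == ci)
      ref <- ref_out[[ci]]
      L <- nchar(ref)
      if (length(rows) == 0L) { mut_out[ci] <- ref; next }
      ord <- rows[order(truth$site[rows])]
      sites <- truth$site[ord]
      if (any(sites < 2000L | sites > L - 2000L))
        stop("implant sites must be >= 2 kb from contig ends")
      if (length(sites) > 1L && any(diff(sites) < 2000L))
        stop("implant sites must be >= 2 kb apart")
      # pass 1: site preparation on the reference
      inserts <- character(length(ord))
      for (k in seq_along(ord)) {
        tr <- truth[ord[k], ]
        ins <- build_insert(tr, consensus_set)
        inserts[k] <- ins
        ni0 <- nchar(ins)
        bpR <- tr$site + tr$tsd_len
        bpL <- tr$site + tr$deletion_len + 1L
        # junction-adjacent insert bases, keyed by reference position: the
        # motif rewrite must not place these bases there
        avoid <- character()
        for (q in 1:10) {
          avoid[as.character(bpR + q)] <- substr(ins, q, q)
          avoid[as.character(bpL - q)] <- substr(ins, ni0 - q + 1L,
                                                 ni0 - q + 1L)
        }
        ref <- rewrite_en_site(ref, tr$site, tr$strand, tr$en_motif_state,
                               avoid = avoid)
        # the motif window is owned by the rewrite; the junction guard below
        # never touches it
        forced <- en_motif_window(tr$site, tr$strand)
        # crisp junctions: the 10 reference bases continuing past each
        # junction are forced to differ from the corresponding insert bases,
        # so maximal-extension alignment cannot slide across the breakpoint
        # by chance microhomology
        ni <- nchar(ins)
        for (q in 1:10) {
          # junction R: reference continuation vs insert 5' end
          p <- bpR + q
          insb <- substr(ins, q, q)
          if (p <= L && nzchar(insb) && substr(ref, p, p) == insb &&
              !p %in% forced) {
            repl <- sample(setdiff(DNA_BASES4, insb), 1L)
            ref <- paste0(substr(ref, 1L, p - 1L), repl,
                          substr(ref, p + 1L, L))
          }
          # junction L: reference lead-in vs insert 3' end
          p <- bpL - q
          insb <- substr(ins, ni - q + 1L, ni - q + 1L)
          if (p >= 1L && nzchar(insb) && substr(ref, p, p) == insb &&
              !p %in% forced) {
            repl <- sample(setdiff(DNA_BASES4, insb), 1L)
            ref <- paste0(substr(ref, 1L, p - 1L), repl,
                          substr(ref, p + 1L, L))
          }
        }
        truth$bpR_ref[ord[k]] <- bpR
        truth$bpL_ref[ord[k]] <- bpL
        truth$ins_len[ord[k]] <- nchar(ins)
        if (tr$tsd_len > 0L)
          truth$tsd_seq[ord[k]] <- substr(ref, tr$site + 1L, tr$site + tr$tsd_len)
        if (nzchar(tr$transduced_flank)) {
          flanks <- c(flanks, stats::setNames(tr$transduced_flank, tr$insertion_id))
          flank_src <- c(flank_src,
            if (nzchar(tr$flank_source)) tr$flank_source else "donor_3p")
        }
      }
      # pass 2: build the mutated contig left to right
      pieces <- character(); cursor <- 1L; offset <- 0L
      for (k in seq_along(ord)) {
        tr <- truth[ord[k], ]
        bpR <- truth$bpR_ref[ord[k]]; bpL <- truth$bpL_ref[ord[k]]
        pieces <- c(pieces, substr(ref, cursor, bpR), inserts[k])
        truth$bpR_mut[ord[k]] <- offset + bpR
        truth$bpL_mut[ord[k]] <- offset + bpR + nchar(inserts[k]) + 1L
        offset <- offset + nchar(inserts[k]) + tr$tsd_len - tr$deletion_len
        cursor <- bpL
      }
      pieces <- c(pieces, substr(ref, cursor, L))
      mut_out[ci] <- paste(pieces, collapse = "")
      ref_out[[ci]] <- ref
    }
    df <- if (length(flanks)) Biostrings::DNAStringSet(flanks) else
      Biostrings::DNAStringSet()
    if (length(flanks)) S4Vectors::mcols(df)$source <- flank_src
    list(genome = Biostrings::DNAStringSet(mut_out),
         reference = Biostrings::DNAStringSet(ref_out),
         truth = truth, donor_flanks = df)
  })
}

#' Capture-probe regions around implanted junctions
#'
#' Emulates the junction-targeting capture design: probe intervals flanking
#' each implanted element terminus, in mutated-genome coordinates.
#'
#' @param truth Finalized truth table from [implantInsertions()].
#' @param flank Half-width of each probe interval (bp).
#' @return A reduced [GenomicRanges::GRanges].
#' @export
probesFromTruth <- function(truth, flank = 300L) {
  gr <- GenomicRanges::GRanges(rep(truth$contig, 2L),
    IRanges::IRanges(
      start = pmax(1L, c(truth$bpR_mut - flank + 1L, truth$bpL_mut - flank)),
      end = c(truth$bpR_mut + flank, truth$bpL_mut + flank - 1L)))
  GenomicRanges::reduce(gr)
}

#' Capture-probe regions at the termini of reference TE intervals
#'
#' @param ranges [GenomicRanges::GRanges] of reference TE copies.
#' @param flank Half-width (bp).
#' @param ends Probe both element termini, or only the (strand-aware) 3'
#'   terminus, as in a single 3'-probe capture design.
#' @return A reduced [GenomicRanges::GRanges].
#' @export
probesFromRanges <- function(ranges, flank = 300L, ends = c("both", "3p")) {
  ends <- match.arg(ends)
  s <- GenomicRanges::start(ranges); e <- GenomicRanges::end(ranges)
  if (ends == "both") {
    gr <- GenomicRanges::GRanges(rep(GenomicRanges::seqnames(ranges), 2L),
      IRanges::IRanges(start = pmax(1L, c(s - flank, e - flank + 1L)),
                       end = c(s + flank - 1L, e + flank)))
  } else {
    neg <- as.character(GenomicRanges::strand(ranges)) == "-"
    jx <- ifelse(neg, s, e)   # 3' junction position
    gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(ranges),
      IRanges::IRanges(start = pmax(1L, jx - flank), end = jx + flank))
  }
  GenomicRanges::reduce(gr)
}

#' Simulate capture-enriched paired-end reads
#'
#' Sonication fragments are drawn uniformly along the genome with lengths
#' uniform in \code{[fragment_min, fragment_max]}; fragments overlapping a
#' probe region are sampled \code{enrichment_factor} times more densely.
#' Each fragment is sequenced from a random strand as an inward-facing read
#' pair: R1 is the first \code{read_len} nt of the fragment, R2 the reverse
#' complement of its last \code{read_len} nt. Base substitution errors are
#' i.i.d. at \code{error_rate}. Read names encode the fragment coordinates
#' (\code{frag<i>:<contig>:<start>:<end>:<strand>}).
#'
#' @param genome A [Biostrings::DNAStringSet] (e.g. a mutated genome).
#' @param probes [GenomicRanges::GRanges] of probe regions in \code{genome}
#'   coordinates, or NULL/empty for whole-genome mode.
#' @param config A [ReadSimConfig-class].
#' @return List with \code{r1} and \code{r2}, named character vectors.
#' @export
simulateReads <- function(genome, probes = NULL, config = ReadSimConfig()) {
  if (length(genome) == 0L || sum(nchar(as.character(genome))) == 0L)
    stop("empty genome")
  gs <- as.character(genome)
  lens <- nchar(gs)
  rl <- config@read_len
  with_seed(config@seed, {
    n_uni <- round(config@coverage * sum(lens) / (2 * rl))
    ctg <- sample(names(gs), n_uni, replace = TRUE, prob = lens)
    flen <- sample(seq(config@fragment_min, config@fragment_max),
                   n_uni, replace = TRUE)
    start <- floor(runif(n_uni) * (lens[ctg] - flen + 1L)) + 1L
    if (!is.null(probes) && length(probes) > 0L &&
        config@enrichment_factor > 1) {
      fmean <- (config@fragment_min + config@fragment_max) / 2
      pw <- GenomicRanges::width(probes) + fmean
      dens <- (config@enrichment_factor - 1) * config@coverage / (2 * rl)
      n_extra <- round(dens * pw)
      for (i in seq_along(probes)) {
        k <- n_extra[i]
        if (k == 0L) next
        pc <- as.character(GenomicRanges::seqnames(probes))[i]
        ps <- GenomicRanges::start(probes)[i]
        pe <- GenomicRanges::end(probes)[i]
        fl <- sample(seq(config@fragment_min, config@fragment_max), k,
                     replace = TRUE)
        lo <- pmax(1L, ps - fl + 1L)
        hi <- pmin(pe, lens[pc] - fl + 1L)
        st <- lo + floor(runif(k) * (hi - lo + 1L))
        ctg <- c(ctg, rep(pc, k)); flen <- c(flen, fl); start <- c(start, st)
      }
    }
    n <- length(start)
    end <- start + flen - 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    frag <- substr(rep(gs[ctg], 1L), start, end)
    neg <- strand == "-"
    if (any(neg)) frag[neg] <- revcomp(frag[neg])
    r1 <- substr(frag, 1L, rl)
    r2 <- revcomp(substr(frag, flen - rl + 1L, flen))
    r1 <- apply_substitution_errors(r1, config@error_rate)
    r2 <- apply_substitution_errors(r2, config@error_rate)
    nm <- sprintf("frag%07d:%s:%d:%d:%s", seq_len(n), ctg, start, end, strand)
    names(r1) <- nm; names(r2) <- nm
    list(r1 = r1, r2 = r2)
  })
}

#' Simulate bisulfite amplicon read pairs over the promoter island
#'
#' Each molecule is the consensus promoter amplicon after bisulfite
#' chemistry: island CpG cytosines are retained as C with their per-CpG
#' methylation probability (else read T); all other cytosines convert to T
#' with probability \code{conversion_efficiency}. Molecules are emitted as
#' overlapping inward read pairs covering the amplicon.
#'
#' @param consensus A [TEConsensus-class] with \code{bis_amplicon} and
#'   \code{promoter_cpg_island} landmarks.
#' @param config A [BisulfiteSimConfig-class]; \code{per_cpg_methylation}
#'   must have length 1 or match the island CpG count.
#' @return List with \code{r1}, \code{r2} (named character vectors),
#'   \code{cpg_positions} (consensus coordinates) and \code{amplicon}
#'   (the untreated amplicon string).
#' @export
simulateBisulfiteReads <- function(consensus, config) {
  lm <- landmarks(consensus)
  amp <- lm["bis_amplicon"]
  a0 <- IRanges::start(amp)
  s <- substr(as.character(consensusSequence(consensus)),
              a0, IRanges::end(amp))
  cpg_abs <- islandCpGs(consensus)
  cpg <- cpg_abs - a0 + 1L
  m <- config@per_cpg_methylation
  if (length(m) == 1L) m <- rep(m, length(cpg))
  if (length(m) != length(cpg))
    stop(sprintf("per_cpg_methylation length %d does not match island CpG count %d",
                 length(m), length(cpg)))
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  c_all <- which(v == "C")
  c_non <- setdiff(c_all, cpg)
  rl <- config@read_len
  n <- config@n_read_pairs
  with_seed(config@seed, {
    r1 <- character(n); r2 <- character(n)
    La <- length(v)
    for (i in seq_len(n)) {
      w <- v
      w[c_non] <- ifelse(runif(length(c_non)) < config@conversion_efficiency,
                         "T", "C")
      w[cpg] <- ifelse(runif(length(cpg)) < m, "C", "T")
      mol <- paste(w, collapse = "")
      r1[i] <- substr(mol, 1L, rl)
      r2[i] <- substr(mol, La - rl + 1L, La)
    }
    r2 <- revcomp(r2)
    r1 <- apply_substitution_errors(r1, config@error_rate)
    r2 <- apply_substitution_errors(r2, config@error_rate)
    nm <- sprintf("mol%06d", seq_len(n))
    names(r1) <- nm; names(r2) <- nm
    list(r1 = r1, r2 = r2, cpg_positions = cpg_abs, amplicon = s)
  })
}

#' Write reads as FASTQ (fixed quality)
#'
#' @param reads Named character vector of sequences.
#' @param path Output file path (".gz" enables compression).
#' @return Invisibly, \code{path}.
#' @export
writeFastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep("I", n), character(1L)))
  xq <- Biostrings::QualityScaledDNAStringSet(
    x, Biostrings::PhredQuality(q))
  Biostrings::writeXStringSet(xq, path, format = "fastq",
                              compress = grepl("\\.gz$", path),
                              qualities = Biostrings::quality(xq))
  invisible(path)
}

#' Read a FASTQ file as a named character vector
#'
#' @param path FASTQ file path.
#' @return Named character vector of read sequences.
#' @export
readFastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

#' Write a truth table as TSV plus a junction BED
#'
#' @param truth Finalized truth table.
#' @param tsv_path,bed_path Output paths (BED is 0-based half-open, one
#'   record per junction in mutated coordinates).
#' @return Invisibly NULL.
#' @export
writeTruth <- function(truth, tsv_path, bed_path = NULL) {
  write.table(truth, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(
      chrom = rep(truth$contig, 2L),
      start = c(truth$bpR_mut - 1L, truth$bpL_mut - 1L),
      end = c(truth$bpR_mut, truth$bpL_mut),
      name = paste0(rep(truth$insertion_id, 2L),
                    rep(c(":R", ":L"), each = nrow(truth))))
    bed <- bed[order(bed$chrom, bed$start), ]
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(NULL)
}
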