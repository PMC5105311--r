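# TPRT hallmark scoring and mechanism classification: endonuclease motif,
# target-site duplication, poly-A tail, 3' transduction.

#' Classify the L1 endonuclease recognition site at a cleavage point
#'
#' The motif is read as TT/AAAA across the bottom-strand cleavage point:
#' the TT ends at the cleavage position and the AAAA follows it on the
#' cleaved strand. \code{canonical} requires exactly TTAAAA, \code{degenerate}
#' allows a Hamming distance of up to 2, anything further is \code{absent}.
#'
#' @param site_context Nucleotide string covering at least 10 nt on each
#'   side of the cleavage point.
#' @param cleavage 1-based position within \code{site_context} of the last
#'   base before the insertion point.
#' @param strand Element strand ("+" or "-"); orients the motif search to
#'   the cleaved strand.
#' @param max_degenerate Maximum Hamming distance still called degenerate.
#' @return List with \code{state} and \code{site_seq} (motif-oriented 6-mer).
#' @export
enMotif <- function(site_context, cleavage, strand = "+",
                    max_degenerate = 2L) {
  n <- nchar(site_context)
  if (cleavage < 10L || n - cleavage < 10L)
    stop("site_context must cover >= 10 nt each side of the cleavage point")
  win <- if (strand == "+")
    substr(site_context, cleavage - 1L, cleavage + 4L)
  else
    revcomp(substr(site_context, cleavage - 3L, cleavage + 2L))
  d <- hamming(win, "TTAAAA")
  state <- if (d == 0L) "canonical" else
    if (d <= max_degenerate) "degenerate" else "absent"
  list(state = state, site_seq = win)
}

# Convenience wrapper reading the context from a reference genome.
enMotifAt <- function(reference, contig, cleavage, strand = "+") {
  gs <- as.character(reference)
  L <- nchar(gs[contig])
  lo <- max(1L, cleavage - 20L); hi <- min(L, cleavage + 20L)
  enMotif(substr(gs[contig], lo, hi), cleavage - lo + 1L, strand)
}

#' Detect a target-site duplication from junction flanks
#'
#' Returns the longest exact string duplicated at both junction
#' boundaries: a suffix of the left flank equal to a prefix of the right
#' flank. Duplications of up to \code{min_report - 1} nt are reported as 0
#' to avoid chance micro-duplications.
#'
#' @param left_flank Genome sequence immediately left of the 5'-side
#'   junction (its last base abuts the junction).
#' @param right_flank Genome sequence starting at the first base after the
#'   insertion.
#' @param min_report Minimum duplication length reported (default 4).
#' @return List with \code{tsd_len} and \code{tsd_seq}.
#' @export
detectTsd <- function(left_flank, right_flank, min_report = 4L) {
  kmax <- min(nchar(left_flank), nchar(right_flank))
  nl <- nchar(left_flank)
  for (k in rev(seq_len(kmax))) {
    if (substr(left_flank, nl - k + 1L, nl) == substr(right_flank, 1L, k)) {
      if (k < min_report) break
      return(list(tsd_len = k,
                  tsd_seq = substr(right_flank, 1L, k)))
    }
  }
  list(tsd_len = 0L, tsd_seq = "")
}

#' Measure the poly-A tail adjacent to the element 3' end
#'
#' Scans the element-oriented 3'-junction clip from the end of its
#' consensus-matching part: the reported run must be at least 90 % A with
#' no non-A interruption longer than 2 nt, and at least \code{min_len} nt
#' long to be reported.
#'
#' @param junction_clip Element-oriented 3'-junction clip sequence.
#' @param element_end Position in the clip where the consensus match ends
#'   (0 if the clip starts at the tail).
#' @param min_len Minimum reportable tail length.
#' @param min_purity Minimum A fraction of the run.
#' @param max_interruption Longest tolerated non-A run inside the tail.
#' @return List with \code{polya_len} (reported length, 0 if below
#'   \code{min_len}) and \code{run_len} (nt of clip consumed by the tail).
#' @export
detectPolyA <- function(junction_clip, element_end = 0L, min_len = 10L,
                        min_purity = 0.9, max_interruption = 2L) {
  v <- strsplit(junction_clip, "", fixed = TRUE)[[1L]]
  n <- length(v)
  s <- element_end + 1L
  if (s > n) return(list(polya_len = 0L, run_len = 0L))
  # the tail starts at the first A within max_interruption + 1 positions of
  # the element end (leading non-A bases are residual element sequence, not
  # tail, and do not count toward its length)
  s0 <- NA_integer_
  for (j in s:min(n, s + max_interruption)) {
    if (v[j] == "A") { s0 <- j; break }
  }
  if (is.na(s0)) return(list(polya_len = 0L, run_len = 0L))
  best_end <- s0 - 1L
  n_a <- 0L; gap <- 0L
  for (j in s0:n) {
    if (v[j] == "A") {
      n_a <- n_a + 1L; gap <- 0L
      if (n_a / (j - s0 + 1L) >= min_purity) best_end <- j
    } else {
      gap <- gap + 1L
      if (gap > max_interruption) break
    }
  }
  run <- best_end - s0 + 1L
  if (run < min_len) list(polya_len = 0L, run_len = 0L)
  else list(polya_len = run, run_len = best_end - s + 1L)
}

#' Detect a 3' transduced flank
#'
#' The post-consensus, pre-genome segment of the inserted sequence is
#' aligned against a database of registered donor flanks; a local hit of
#' at least \code{min_len} nt at \code{min_identity} or better is reported
#' with its source annotation.
#'
#' @param segment The element-oriented inserted segment beyond the
#'   consensus 3' end and poly-A tail (e.g. the \code{extra_3p} column of a
#'   call).
#' @param donor_flanks [Biostrings::DNAStringSet] with a \code{source}
#'   metadata column (as returned by [implantInsertions()]).
#' @param min_len Minimum aligned length (nt).
#' @param min_identity Minimum alignment identity.
#' @return List with \code{sequence}, \code{donor} (db entry name) and
#'   \code{source}, or NULL when nothing matches.
#' @export
detectTransduction <- function(segment, donor_flanks, min_len = 20L,
                               min_identity = 0.9) {
  if (is.null(segment) || is.na(segment) || nchar(segment) < min_len ||
      is.null(donor_flanks) || length(donor_flanks) == 0L) return(NULL)
  best <- NULL
  src <- S4Vectors::mcols(donor_flanks)$source %||%
    rep(NA_character_, length(donor_flanks))
  for (i in seq_along(donor_flanks)) {
    for (strand in c("+", "-")) {
      qs <- if (strand == "+") segment else revcomp(segment)
      pa <- Biostrings::pairwiseAlignment(qs,
        as.character(donor_flanks[[i]]), type = "local",
        substitutionMatrix = sw_submat(),
        gapOpening = SW_GAP_OPEN, gapExtension = SW_GAP_EXT)
      cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
      if (cols >= min_len && Biostrings::nmatch(pa) / cols >= min_identity) {
        sc <- Biostrings::score(pa)
        if (is.null(best) || sc > best$score) {
          best <- list(score = sc,
                       sequence = as.character(Biostrings::pattern(pa)),
                       donor = names(donor_flanks)[i], source = src[i])
        }
      }
    }
  }
  if (is.null(best)) NULL else best[c("sequence", "donor", "source")]
}

#' Classify the integration mechanism from hallmark states
#'
#' Decision rules, applied in order:
#' \enumerate{
#'   \item RECOMBINATION_CANDIDATE: no EN motif, and either an
#'     older-subfamily (L1PA2) donor or a transduced flank matching the
#'     same repeat family as the integration target.
#'   \item TPRT: poly-A tail present, EN motif canonical or degenerate,
#'     and no genomic deletion.
#'   \item ENi: no EN motif, no TSD, no poly-A, with a genomic deletion.
#'   \item AMBIGUOUS otherwise.
#' }
#'
#' @param polya_len,tsd_len,deletion_len Hallmark lengths (nt).
#' @param en_motif_state "canonical", "degenerate" or "absent".
#' @param donor_family Subfamily of the inserted element.
#' @param flank_family Repeat family of a detected transduced flank
#'   (NA if none).
#' @param target_family Repeat family annotated at the integration site
#'   (NA if none).
#' @return One of "TPRT", "ENi", "RECOMBINATION_CANDIDATE", "AMBIGUOUS".
#' @export
classifyMechanism <- function(polya_len, tsd_len, deletion_len,
                              en_motif_state, donor_family,
                              flank_family = NA_character_,
                              target_family = NA_character_) {
  en_absent <- en_motif_state == "absent"
  flank_target_match <- !is.na(flank_family) && !is.na(target_family) &&
    flank_family == target_family
  if (en_absent && (identical(donor_family, "L1PA2") || flank_target_match))
    return("RECOMBINATION_CANDIDATE")
  if (polya_len > 0L && !en_absent && deletion_len == 0L)
    return("TPRT")
  if (en_absent && tsd_len == 0L && polya_len == 0L && deletion_len > 0L)
    return("ENi")
  "AMBIGUOUS"
}

#' Annotate insertion calls with TPRT hallmarks and a mechanism class
#'
#' For each call: reads the EN site from the reference around the inferred
#' cleavage point, re-detects the TSD from the reference junction flanks,
#' carries the poly-A measurement from the 3' clip, searches the
#' post-poly-A segment against the donor-flank database, looks up the
#' repeat family annotated at the integration site, and applies
#' [classifyMechanism()].
#'
#' @param calls Data.frame from [pairAndAnnotate()].
#' @param reference Reference genome [Biostrings::DNAStringSet].
#' @param donor_flanks Optional donor-flank [Biostrings::DNAStringSet].
#' @param te_annotation Optional [GenomicRanges::GRanges] with a
#'   \code{family} metadata column, for the target-repeat lookup.
#' @return The calls data.frame with hallmark columns and
#'   \code{classification} appended.
#' @export
annotateHallmarks <- function(calls, reference, donor_flanks = NULL,
                              te_annotation = NULL) {
  gs <- as.character(reference)
  n <- nrow(calls)
  calls$en_motif_state <- NA_character_
  calls$en_site_seq <- NA_character_
  calls$hallmark_tsd_len <- NA_integer_
  calls$transduced_len <- 0L
  calls$transduced_source <- NA_character_
  calls$flank_family <- NA_character_
  calls$target_family <- NA_character_
  calls$classification <- NA_character_
  for (i in seq_len(n)) {
    ctg <- calls$contig[i]
    L <- nchar(gs[ctg])
    # cleavage point: where the genome resumes, minus any site deletion
    cleave <- if (!is.na(calls$bp_left[i]))
      calls$bp_left[i] - calls$deletion_len[i] - 1L
    else calls$bp_right[i] - calls$tsd_len[i]
    if (!is.na(cleave) && cleave > 20L && cleave < L - 20L) {
      en <- enMotifAt(reference, ctg, cleave, calls$strand[i])
      calls$en_motif_state[i] <- en$state
      calls$en_site_seq[i] <- en$site_seq
    } else calls$en_motif_state[i] <- "absent"
    if (!is.na(calls$bp_right[i]) && !is.na(calls$bp_left[i])) {
      lf <- substr(gs[ctg], max(1L, calls$bp_right[i] - 49L),
                   calls$bp_right[i])
      rf <- substr(gs[ctg], calls$bp_left[i],
                   min(L, calls$bp_left[i] + 49L))
      calls$hallmark_tsd_len[i] <- detectTsd(lf, rf)$tsd_len
    } else calls$hallmark_tsd_len[i] <- 0L
    td <- detectTransduction(calls$extra_3p[i], donor_flanks)
    if (!is.null(td)) {
      calls$transduced_len[i] <- nchar(td$sequence)
      calls$transduced_source[i] <- td$donor
      calls$flank_family[i] <- td$source
    }
    if (!is.null(te_annotation) && length(te_annotation)) {
      bp <- if (!is.na(calls$bp_right[i])) calls$bp_right[i] else
        calls$bp_left[i]
      hit <- GenomicRanges::findOverlaps(
        GenomicRanges::GRanges(ctg, IRanges::IRanges(bp, bp)),
        te_annotation)
      if (length(hit)) {
        fams <- S4Vectors::mcols(te_annotation)$family
        if (!is.null(fams))
          calls$target_family[i] <- fams[S4Vectors::subjectHits(hit)[1L]]
      }
    }
    calls$classification[i] <- classifyMechanism(
      polya_len = calls$polya_len[i],
      tsd_len = calls$hallmark_tsd_len[i],
      deletion_len = calls$deletion_len[i],
      en_motif_state = calls$en_motif_state[i],
      donor_family = calls$family[i],
      flank_family = calls$flank_family[i],
      target_family = calls$target_family[i])
  }
  calls
}
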