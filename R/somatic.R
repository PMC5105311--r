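# Tumour-specificity criteria, junction microhomology, and cohort
# sensitivity / junction-coverage metrics.

#' Microhomology across a TE-genome junction
#'
#' Length of the longest exact identity running across the junction: for a
#' 5' junction, a suffix of the genome flank equal to a prefix of the
#' element sequence; for a 3' junction, a suffix of the element equal to a
#' prefix of the genome flank. Long microhomology flags possible molecular
#' chimeras.
#'
#' @param genome_flank Genome sequence oriented so the junction is at its
#'   boundary with \code{te_end} (its end for 5p, its start for 3p).
#' @param te_end Element-side sequence at the junction.
#' @param junction_side "5p" or "3p".
#' @return Integer microhomology length.
#' @export
microhomology <- function(genome_flank, te_end, junction_side = c("5p", "3p")) {
  junction_side <- match.arg(junction_side)
  if (nchar(genome_flank) < 20L || nchar(te_end) < 20L)
    stop("flank and element sequences must each be >= 20 nt")
  if (junction_side == "5p") {
    a <- genome_flank; b <- te_end      # suffix of genome vs prefix of TE
  } else {
    a <- te_end; b <- genome_flank      # suffix of TE vs prefix of genome
  }
  na <- nchar(a)
  kmax <- min(na, nchar(b))
  for (k in rev(seq_len(kmax))) {
    if (substr(a, na - k + 1L, na) == substr(b, 1L, k)) return(k)
  }
  0L
}

#' Tumour-specificity criteria thresholds
#'
#' Defaults follow the five reporting criteria: (i) one tumour sample with
#' at least 8 supporting reads and more than 10 times the combined support
#' of all other samples; (ii) absence from the known-polymorphism
#' database; (iii) junction-side consistency with the capture design (a
#' 5'-junction-only call is acceptable only for elements longer than
#' 6000 nt or shorter than 1000 nt); (iv) strand/family/position
#' confidences above 0.9/0.9/0.3; (v) junction microhomology below 10 nt.
#'
#' @param min_tumour_reads Criterion i read floor.
#' @param ratio Criterion i multiplier over all other samples combined.
#' @param known_db [GenomicRanges::GRanges] of known polymorphic
#'   insertions.
#' @param known_db_slop Interval slop (nt) when intersecting the database.
#' @param design_5p_max_len,design_5p_min_len Criterion iii element-length
#'   rule: a 5'-only call needs length < max or > min.
#' @param strand_conf_min,family_conf_min,position_conf_min Criterion iv
#'   thresholds (strict).
#' @param max_microhomology Criterion v bound (strict).
#' @return A list of thresholds.
#' @export
somaticCriteria <- function(min_tumour_reads = 8L, ratio = 10,
                            known_db = GenomicRanges::GRanges(),
                            known_db_slop = 100L,
                            design_5p_max_len = 1000L,
                            design_5p_min_len = 6000L,
                            strand_conf_min = 0.9, family_conf_min = 0.9,
                            position_conf_min = 0.3,
                            max_microhomology = 10L) {
  list(min_tumour_reads = min_tumour_reads, ratio = ratio,
       known_db = known_db, known_db_slop = known_db_slop,
       design_5p_max_len = design_5p_max_len,
       design_5p_min_len = design_5p_min_len,
       strand_conf_min = strand_conf_min, family_conf_min = family_conf_min,
       position_conf_min = position_conf_min,
       max_microhomology = max_microhomology)
}

#' Evaluate the five tumour-specificity criteria for one call
#'
#' @param call One-row data.frame from [countSupport()] (with
#'   \code{support.<sample>} columns, confidences and
#'   \code{microhomology}).
#' @param sample_roles Named character vector mapping every sample to
#'   "tumour", "normal" or "blood".
#' @param criteria List from [somaticCriteria()].
#' @return List with \code{tumour_specific} (logical), \code{criteria}
#'   (named logical vector i-v) and \code{tumour_sample}.
#' @export
isTumourSpecific <- function(call, sample_roles,
                             criteria = somaticCriteria()) {
  stopifnot(nrow(call) == 1L)
  sup_cols <- grep("^support\\.", names(call), value = TRUE)
  samples <- sub("^support\\.", "", sup_cols)
  if (length(missing_roles <- setdiff(samples, names(sample_roles))))
    stop("missing sample role for: ", paste(missing_roles, collapse = ", "))
  support <- vapply(sup_cols, function(cc) as.numeric(call[[cc]]), numeric(1L))
  names(support) <- samples
  tum <- samples[sample_roles[samples] == "tumour"]

  # i) exactly one tumour sample at/above the read floor, exceeding
  #    ratio x the combined support of every other library
  cand <- tum[support[tum] >= criteria$min_tumour_reads]
  crit_i <- FALSE; tumour_sample <- NA_character_
  if (length(cand) == 1L) {
    others <- sum(support[setdiff(samples, cand)])
    crit_i <- support[cand] > criteria$ratio * others
    if (crit_i) tumour_sample <- cand
  }

  # ii) absent from the known-polymorphism database (with slop)
  bps <- c(call$bp_right, call$bp_left)
  bps <- bps[!is.na(bps)]
  qi <- GenomicRanges::GRanges(call$contig,
    IRanges::IRanges(min(bps) - criteria$known_db_slop,
                     max(bps) + criteria$known_db_slop))
  crit_ii <- length(criteria$known_db) == 0L ||
    GenomicRanges::countOverlaps(qi, criteria$known_db) == 0L

  # iii) junction side consistent with the capture design
  has_3p <- !is.na(call$bp3) && call$support_3p > 0L
  el <- call$element_len
  crit_iii <- has_3p || (!is.na(el) &&
    (el > criteria$design_5p_min_len || el < criteria$design_5p_max_len))

  # iv) confidence scores
  crit_iv <- call$strand_confidence > criteria$strand_conf_min &&
    call$family_confidence > criteria$family_conf_min &&
    call$position_confidence > criteria$position_conf_min

  # v) junction microhomology
  crit_v <- call$microhomology < criteria$max_microhomology

  crits <- c(i = unname(crit_i), ii = unname(crit_ii),
             iii = unname(crit_iii), iv = unname(crit_iv),
             v = unname(crit_v))
  list(tumour_specific = all(crits), criteria = crits,
       tumour_sample = tumour_sample)
}

#' Tabulate tumour-specificity decisions for a call set
#'
#' @param calls Data.frame from [countSupport()].
#' @param sample_roles Named character vector of sample roles.
#' @param criteria List from [somaticCriteria()].
#' @return The calls data.frame with per-criterion columns
#'   (\code{crit_i}..\code{crit_v}), \code{tumour_specific} and
#'   \code{tumour_sample}.
#' @export
somaticTable <- function(calls, sample_roles, criteria = somaticCriteria()) {
  for (cc in c("crit_i", "crit_ii", "crit_iii", "crit_iv", "crit_v",
               "tumour_specific")) calls[[cc]] <- logical(nrow(calls))
  calls$tumour_sample <- NA_character_
  for (i in seq_len(nrow(calls))) {
    r <- isTumourSpecific(calls[i, , drop = FALSE], sample_roles, criteria)
    calls[i, c("crit_i", "crit_ii", "crit_iii", "crit_iv", "crit_v")] <-
      as.list(r$criteria)
    calls$tumour_specific[i] <- r$tumour_specific
    calls$tumour_sample[i] <- r$tumour_sample
  }
  calls
}

# Distinct non-duplicate reads whose alignment spans a junction point
# (at least one aligned base on each side).
junction_spanning_counts <- function(alignments, cohort) {
  a <- alignments[!alignments$duplicate & alignments$mapq_proxy >= 1L, ,
                  drop = FALSE]
  s <- GenomicRanges::start(cohort); e <- GenomicRanges::end(cohort)
  ctg <- as.character(GenomicRanges::seqnames(cohort))
  vapply(seq_along(cohort), function(i) {
    sel <- a$contig == ctg[i] &
      ((a$start <= s[i] - 1L & a$end >= s[i]) |
       (a$start <= e[i] & a$end >= e[i] + 1L))
    length(unique(a$read_id[sel]))
  }, integer(1L))
}

#' Cohort sensitivity: fraction of reference elements detected
#'
#' A cohort element is detected when at least \code{min_reads} distinct
#' non-duplicate reads span one of its two TE-genome junctions.
#'
#' @param alignments Data.frame of per-sample alignments (after
#'   [markDuplicates()]).
#' @param cohort [GenomicRanges::GRanges] of reference TE intervals with
#'   intact 3' ends.
#' @param min_reads Detection read floor (e.g. 20 or 8 depending on
#'   library depth).
#' @return Fraction detected in [0, 1].
#' @export
cohortSensitivity <- function(alignments, cohort, min_reads = 8L) {
  if (length(cohort) == 0L) stop("cohort must be non-empty")
  if (!nrow(alignments)) return(0)
  cnt <- junction_spanning_counts(alignments, cohort)
  mean(cnt >= min_reads)
}

#' Mean junction-spanning reads per cohort element
#'
#' Total junction-spanning reads across all cohort elements divided by the
#' cohort size.
#'
#' @inheritParams cohortSensitivity
#' @return Mean spanning-read count per element.
#' @export
junctionCoverage <- function(alignments, cohort) {
  if (length(cohort) == 0L) stop("cohort must be non-empty")
  if (!nrow(alignments)) return(0)
  mean(junction_spanning_counts(alignments, cohort))
}
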