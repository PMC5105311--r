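# Bisulfite amplicon methylation of the L1 promoter CpG island: pair
# merging, mock conversion, per-CpG calling with conversion QC, and group
# comparison.

#' Merge an overlapping read pair into a single contig
#'
#' R2 is reverse-complemented and the overlap length minimising the
#' mismatch ratio within \code{[min_overlap, max_overlap]} is chosen (ties
#' resolved toward the longest overlap). The pair merges when that ratio is
#' at most \code{max_mismatch_ratio}; disagreeing overlap bases are
#' resolved toward R1.
#'
#' @param r1,r2 Read sequences (single strings).
#' @param min_overlap,max_overlap Overlap length window (nt).
#' @param max_mismatch_ratio Maximum mismatch fraction in the overlap.
#' @return List with \code{sequence}, \code{overlap_len},
#'   \code{mismatch_fraction}, or NULL when the pair cannot be merged.
#' @export
mergePairs <- function(r1, r2, min_overlap = 15L, max_overlap = 150L,
                       max_mismatch_ratio = 0.3) {
  if (nchar(r1) == 0L || nchar(r2) == 0L) stop("zero-length read")
  b <- revcomp(r2)
  n1 <- nchar(r1); n2 <- nchar(b)
  av <- utf8ToInt(r1); bv <- utf8ToInt(b)
  kmax <- min(max_overlap, n1, n2)
  if (kmax < min_overlap) return(NULL)
  best_k <- NA_integer_; best_ratio <- Inf
  for (k in seq(kmax, min_overlap)) {
    mism <- sum(av[(n1 - k + 1L):n1] != bv[seq_len(k)])
    ratio <- mism / k
    if (ratio < best_ratio - 1e-12) {
      best_ratio <- ratio; best_k <- k
      if (ratio == 0) break     # no smaller ratio exists; ties prefer long k
    }
  }
  if (!is.finite(best_ratio) || best_ratio > max_mismatch_ratio) return(NULL)
  list(sequence = paste0(r1, substr(b, best_k + 1L, n2)),
       overlap_len = best_k, mismatch_fraction = best_ratio)
}

#' Merge all pairs of a bisulfite read set
#'
#' @param r1,r2 Named character vectors of mate sequences.
#' @inheritParams mergePairs
#' @return Data.frame of merged contigs (read_pair_id, sequence,
#'   overlap_len, mismatch_fraction); the number of unmerged pairs is
#'   attached as attribute \code{n_unmerged} and reported via message.
#' @export
mergePairSet <- function(r1, r2, min_overlap = 15L, max_overlap = 150L,
                         max_mismatch_ratio = 0.3) {
  stopifnot(length(r1) == length(r2))
  ids <- names(r1) %||% sprintf("pair%06d", seq_along(r1))
  out <- vector("list", length(r1))
  # vectorised prescreen over uniform-length pairs: the largest overlap with
  # an exact match is the minimal-ratio choice under the tie rule
  resolved <- rep(FALSE, length(r1))
  n1u <- unique(nchar(r1)); n2u <- unique(nchar(r2))
  if (length(n1u) == 1L && length(n2u) == 1L) {
    b <- revcomp(unname(r2))
    kmax <- min(max_overlap, n1u, n2u)
    r1v <- unname(r1)
    for (k in seq(kmax, min_overlap)) {
      open <- which(!resolved)
      if (!length(open)) break
      hit <- open[substring(r1v[open], n1u - k + 1L, n1u) ==
                    substring(b[open], 1L, k)]
      for (i in hit) {
        out[[i]] <- data.frame(read_pair_id = ids[i],
                               sequence = paste0(r1v[i],
                                                 substr(b[i], k + 1L, n2u)),
                               overlap_len = k, mismatch_fraction = 0,
                               stringsAsFactors = FALSE)
      }
      resolved[hit] <- TRUE
    }
  }
  for (i in which(!resolved)) {
    m <- mergePairs(r1[[i]], r2[[i]], min_overlap, max_overlap,
                    max_mismatch_ratio)
    if (!is.null(m))
      out[[i]] <- data.frame(read_pair_id = ids[i], sequence = m$sequence,
                             overlap_len = m$overlap_len,
                             mismatch_fraction = m$mismatch_fraction,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(res))
    res <- data.frame(read_pair_id = character(), sequence = character(),
                      overlap_len = integer(),
                      mismatch_fraction = numeric(), stringsAsFactors = FALSE)
  n_un <- length(r1) - nrow(res)
  if (n_un > 0L) message(n_un, " read pair(s) could not be merged")
  attr(res, "n_unmerged") <- n_un
  res
}

#' Mock bisulfite conversion of a sequence
#'
#' Every cytosine outside a CpG dinucleotide becomes T; CpG cytosines are
#' retained as C. Used to build the alignment target for bisulfite
#' contigs.
#'
#' @param x A [TEConsensus-class] or a character string.
#' @return List with \code{sequence} (converted string) and
#'   \code{cpg_index} (1-based positions of CpG cytosines).
#' @export
mockConvert <- function(x) {
  s <- if (is(x, "TEConsensus")) as.character(consensusSequence(x)) else x
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(v)
  is_c <- v == "C"
  is_cpg <- is_c & c(v[-1L] == "G", FALSE)
  v[is_c & !is_cpg] <- "T"
  list(sequence = paste(v, collapse = ""),
       cpg_index = which(is_cpg))
}

# Locate a contig on the mock-converted amplicon: returns list(offset,
# strand, identity) where offset is the amplicon position of contig base 1.
locate_contig <- function(contig, conv_amp, ref_c_mask) {
  na <- nchar(conv_amp)
  best <- NULL
  wv_full <- utf8ToInt(conv_amp)
  ct_code <- utf8ToInt("CT")
  ident_at <- function(qs, d) {
    nq <- nchar(qs)
    lo <- max(1L, d); hi <- min(na, d + nq - 1L)
    if (hi - lo + 1L < 20L) return(NULL)
    qv <- utf8ToInt(substr(qs, lo - d + 1L, hi - d + 1L))
    wv <- wv_full[lo:hi]
    # tolerate C/T states at reference cytosine positions
    tol <- ref_c_mask[lo:hi] & qv %in% ct_code
    mean(qv == wv | tol)
  }
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") contig else revcomp(contig)
    nq <- nchar(qs)
    # full-length contigs usually sit at offset 1; check that directly
    if (nq == na) {
      id0 <- ident_at(qs, 1L)
      if (!is.null(id0) && id0 >= 0.95)
        return(list(offset = 1L, strand = strand, identity = id0,
                    oriented = qs))
    }
    # seed with a handful of 20-mers: exact (plain text search) first, then
    # with mismatches so incomplete conversion does not defeat seeding
    sofs <- unique(pmax(1L, c(1L, round(nq * c(0.25, 0.5, 0.75)) - 10L,
                              nq - 19L)))
    offs <- integer()
    for (o in sofs) {
      sd <- substr(qs, o, o + 19L)
      if (nchar(sd) < 20L) next
      hit <- gregexpr(sd, conv_amp, fixed = TRUE)[[1L]]
      hit <- hit[hit > 0L]
      if (length(hit)) offs <- c(offs, hit - o + 1L)
    }
    if (!length(offs)) {
      conv_dna <- Biostrings::DNAString(conv_amp)
      for (o in sofs) {
        sd <- substr(qs, o, o + 19L)
        if (nchar(sd) < 20L) next
        mp <- Biostrings::matchPattern(sd, conv_dna, max.mismatch = 2L)
        if (length(mp)) offs <- c(offs, Biostrings::start(mp) - o + 1L)
      }
    }
    for (d in unique(offs)) {
      ident <- ident_at(qs, d)
      if (is.null(ident)) next
      if (is.null(best) || ident > best$identity)
        best <- list(offset = d, strand = strand, identity = ident,
                     oriented = qs)
    }
    if (!is.null(best) && best$identity >= 0.95) break
  }
  best
}

#' Call per-CpG methylation states from merged bisulfite contigs
#'
#' Each contig is located on the mock-converted amplicon (both strands
#' tried). At each covered island CpG the contig base gives the state
#' (C = methylated, T = unmethylated, anything else counts toward the
#' mutated-CpG check). The per-contig conversion rate is the fraction of
#' covered non-CpG reference cytosines reading T; contigs converting less
#' than \code{min_conversion} of them are discarded, as are contigs below
#' the alignment identity floor. CpG positions at which more than half of
#' the retained contigs show a non-C/T base are flagged mutated and
#' excluded profile-wide.
#'
#' @param contigs Data.frame from [mergePairSet()].
#' @param consensus A [TEConsensus-class] with the amplicon landmarks.
#' @param group_label Label stored on the resulting profile.
#' @param min_conversion Minimum non-CpG conversion rate.
#' @param min_identity Alignment identity floor.
#' @return List with \code{profile} (a [MethylationProfile-class]) and
#'   \code{qc} (per-contig data.frame: conversion, identity, retained,
#'   reason).
#' @export
alignAndCall <- function(contigs, consensus, group_label = "sample",
                         min_conversion = 0.95, min_identity = 0.8) {
  lm <- landmarks(consensus)
  a0 <- IRanges::start(lm["bis_amplicon"])
  a1 <- IRanges::end(lm["bis_amplicon"])
  amp <- substr(as.character(consensusSequence(consensus)), a0, a1)
  mc <- mockConvert(amp)
  cpg_rel <- islandCpGs(consensus) - a0 + 1L
  ampv <- strsplit(amp, "", fixed = TRUE)[[1L]]
  ref_c <- which(ampv == "C")
  nonCpG_c <- setdiff(ref_c, cpg_rel)
  ref_c_mask <- rep(FALSE, nchar(amp)); ref_c_mask[ref_c] <- TRUE
  n <- nrow(contigs)
  states <- matrix(NA_character_, nrow = n, ncol = length(cpg_rel))
  qc <- data.frame(read_pair_id = contigs$read_pair_id,
                   conversion = NA_real_, identity = NA_real_,
                   retained = FALSE, reason = "", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    loc <- locate_contig(contigs$sequence[i], mc$sequence, ref_c_mask)
    if (is.null(loc)) { qc$reason[i] <- "no_alignment"; next }
    qc$identity[i] <- loc$identity
    if (loc$identity < min_identity) { qc$reason[i] <- "low_identity"; next }
    qs <- loc$oriented; d <- loc$offset; nq <- nchar(qs)
    covered <- function(p) p >= d & p <= d + nq - 1L
    cc <- nonCpG_c[covered(nonCpG_c)]
    if (length(cc) == 0L) { qc$reason[i] <- "no_informative_c"; next }
    bb <- substring(qs, cc - d + 1L, cc - d + 1L)
    nT <- sum(bb == "T"); nC <- sum(bb == "C")
    if (nT + nC == 0L) { qc$reason[i] <- "no_informative_c"; next }
    conv <- nT / (nT + nC)
    qc$conversion[i] <- conv
    if (conv < min_conversion) { qc$reason[i] <- "low_conversion"; next }
    qc$retained[i] <- TRUE
    cp <- cpg_rel[covered(cpg_rel)]
    states[i, match(cp, cpg_rel)] <- substring(qs, cp - d + 1L, cp - d + 1L)
  }
  ret <- which(qc$retained)
  meth <- integer(length(cpg_rel)); tot <- integer(length(cpg_rel))
  other_frac <- numeric(length(cpg_rel))
  for (j in seq_along(cpg_rel)) {
    col <- states[ret, j]
    col <- col[!is.na(col)]
    meth[j] <- sum(col == "C")
    tot[j] <- sum(col %in% c("C", "T"))
    other_frac[j] <- if (length(col)) mean(!col %in% c("C", "T")) else 0
  }
  excluded <- (islandCpGs(consensus))[other_frac > 0.5]
  prof <- new("MethylationProfile",
              cpg_positions = islandCpGs(consensus),
              methylated_counts = meth, total_counts = tot,
              excluded_positions = as.integer(excluded),
              per_read_conversion = stats::setNames(
                qc$conversion[ret], qc$read_pair_id[ret]),
              group_label = group_label)
  list(profile = prof, qc = qc)
}

#' Compare methylation profiles between two groups
#'
#' Per-CpG methylated fractions for each group over the shared,
#' non-excluded CpG positions; the groups are compared with a paired
#' t-test across CpG positions (degrees of freedom = shared positions - 1).
#'
#' @param profile_a,profile_b [MethylationProfile-class] objects (e.g.
#'   tumour and adjacent brain).
#' @return List with \code{per_cpg} (data.frame of per-position fractions),
#'   \code{mean_a}, \code{mean_b}, \code{mean_difference} (a - b),
#'   \code{t_statistic}, \code{df} and \code{p_value}.
#' @export
profileAndCompare <- function(profile_a, profile_b) {
  excl <- union(profile_a@excluded_positions, profile_b@excluded_positions)
  shared <- intersect(profile_a@cpg_positions, profile_b@cpg_positions)
  shared <- setdiff(shared, excl)
  ia <- match(shared, profile_a@cpg_positions)
  ib <- match(shared, profile_b@cpg_positions)
  ok <- profile_a@total_counts[ia] > 0L & profile_b@total_counts[ib] > 0L
  shared <- shared[ok]; ia <- ia[ok]; ib <- ib[ok]
  if (length(shared) < 2L) stop("no shared covered CpG positions to compare")
  fa <- profile_a@methylated_counts[ia] / profile_a@total_counts[ia]
  fb <- profile_b@methylated_counts[ib] / profile_b@total_counts[ib]
  d <- fa - fb
  n <- length(d)
  if (stats::sd(d) > 0) {
    tt <- stats::t.test(fa, fb, paired = TRUE)
    tstat <- unname(tt$statistic); pval <- tt$p.value
  } else {
    tstat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    pval <- if (mean(d) == 0) 1 else 0
  }
  list(per_cpg = data.frame(position = shared, fraction_a = fa,
                            fraction_b = fb, difference = d),
       mean_a = mean(fa), mean_b = mean(fb),
       mean_difference = mean(d), t_statistic = tstat,
       df = n - 1L, p_value = pval)
}
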