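# Junction clustering, filtering, 5'/3' pairing with TSD/deletion
# annotation, per-sample support counting, and VCF output.

# Majority-vote consensus of clips anchored at the junction edge:
# right clips share their first base (the junction), left clips their last.
consensus_clip_vote <- function(clips, side) {
  if (length(clips) == 1L) return(clips)
  n <- nchar(clips)
  w <- max(n)
  mat <- matrix(NA_integer_, nrow = length(clips), ncol = w)
  for (i in seq_along(clips)) {
    v <- utf8ToInt(clips[i])
    if (side == "right") mat[i, seq_len(n[i])] <- v
    else mat[i, (w - n[i] + 1L):w] <- v
  }
  out <- integer(w)
  for (j in seq_len(w)) {
    col <- mat[, j]
    col <- col[!is.na(col)]
    tb <- sort(table(col), decreasing = TRUE)
    top <- as.integer(names(tb)[tb == tb[1L]])
    out[j] <- min(top)
  }
  intToUtf8(out)
}

#' Cluster realigned clips into TE-genome junctions
#'
#' Clips are grouped by contig, clip side and element end; within a group,
#' breakpoints within \code{window} nt of each other (single linkage) form
#' one cluster. Clusters supported by fewer than \code{mincluster} distinct
#' reads are discarded. The cluster breakpoint is the modal member
#' breakpoint (ties resolved leftmost); strand, family and position
#' confidences are the fractions of members agreeing with the modal
#' element strand, family and breakpoint. The cluster's consensus clip is
#' the junction-anchored per-position majority vote of member clips, and is
#' realigned against the consensus set to give the cluster-level hit.
#'
#' @param clips Data.frame from [buildClipTable()].
#' @param mincluster Minimum supporting reads per cluster.
#' @param window Breakpoint linkage window (nt).
#' @param consensus_set Consensus set used for the cluster-level
#'   realignment.
#' @return Data.frame of clusters; \code{support} and
#'   \code{support_samples} are list columns of member read ids/samples.
#' @export
clusterJunctions <- function(clips, mincluster = 2L, window = 10L,
                             consensus_set = consensusSet()) {
  if (!nrow(clips)) return(empty_clusters())
  grp <- paste(clips$contig, clips$clip_side, sep = "|")
  out <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    idx <- idx[order(clips$bp[idx])]
    bps <- clips$bp[idx]
    brk <- c(0L, cumsum(diff(bps) > window))
    for (cl in split(idx, brk)) {
      # distinct reads only (a read supports a junction once per sample)
      cl <- cl[!duplicated(paste(clips$sample[cl], clips$read_id[cl]))]
      if (length(cl) < mincluster) next
      sub <- clips[cl, , drop = FALSE]
      tb <- table(sub$bp)
      modal_bp <- as.integer(min(as.integer(names(tb)[tb == max(tb)])))
      tbs <- table(sub$element_strand)
      modal_strand <- names(tbs)[which.max(tbs)]
      tbf <- table(sub$family)
      modal_family <- names(tbf)[which.max(tbf)]
      # the element end this junction represents follows from the clip side
      # and the modal element strand
      side_te <- if ((sub$clip_side[1L] == "right") == (modal_strand == "+"))
        "5p" else "3p"
      sub$te_side <- side_te
      ccl <- consensus_clip_vote(sub$clip_seq, sub$clip_side[1L])
      hit <- realignClip(ccl, consensus_set)
      # for 3' junctions the poly-A tail is element-derived sequence: count
      # its run towards the consensus-matched span (the consensus itself
      # carries no tail)
      tail_run <- 0L
      if (!is.null(hit) && sub$te_side[1L] == "3p") {
        oc <- if (sub$clip_side[1L] == "left") ccl else revcomp(ccl)
        tail_run <- detectPolyA(oc, element_end = hit$clip_end)$run_len
      }
      out[[length(out) + 1L]] <- data.frame(
        contig = sub$contig[1L], breakpoint = modal_bp,
        te_side = sub$te_side[1L], clip_side = sub$clip_side[1L],
        element_strand = modal_strand, n_support = length(cl),
        consensus_clip = ccl,
        family = if (is.null(hit)) NA_character_ else hit$family,
        cons_start = if (is.null(hit)) NA_integer_ else hit$cons_start,
        cons_end = if (is.null(hit)) NA_integer_ else hit$cons_end,
        identity = if (is.null(hit)) NA_real_ else hit$identity,
        aligned_len = if (is.null(hit)) NA_integer_ else
          hit$aligned_len + tail_run,
        clip_start = if (is.null(hit)) NA_integer_ else hit$clip_start,
        clip_end = if (is.null(hit)) NA_integer_ else hit$clip_end,
        hit_strand = if (is.null(hit)) NA_character_ else hit$strand,
        genome_identity = max(sub$genome_identity),
        strand_confidence = mean(sub$element_strand == modal_strand),
        family_confidence = mean(sub$family == modal_family),
        position_confidence = mean(sub$bp == modal_bp),
        filters = "", stringsAsFactors = FALSE)
      out[[length(out)]]$support <- I(list(sub$read_id))
      out[[length(out)]]$support_samples <- I(list(sub$sample))
    }
  }
  if (!length(out)) return(empty_clusters())
  res <- do.call(rbind, out)
  res$cluster_id <- sprintf("jc%04d", seq_len(nrow(res)))
  res
}

empty_clusters <- function() {
  df <- data.frame(contig = character(), breakpoint = integer(),
                   te_side = character(), clip_side = character(),
                   element_strand = character(), n_support = integer(),
                   consensus_clip = character(), family = character(),
                   cons_start = integer(), cons_end = integer(),
                   identity = numeric(), aligned_len = integer(),
                   clip_start = integer(), clip_end = integer(),
                   hit_strand = character(), genome_identity = numeric(),
                   strand_confidence = numeric(),
                   family_confidence = numeric(),
                   position_confidence = numeric(), filters = character(),
                   stringsAsFactors = FALSE)
  df$support <- I(list()); df$support_samples <- I(list())
  df$cluster_id <- character()
  df
}

add_filter <- function(filters, label) {
  ifelse(filters == "", label, paste(filters, label, sep = ","))
}

#' Apply identity, location and consistency filters to junction clusters
#'
#' Labels applied: \code{te_overlap} (breakpoint inside an annotated
#' reference TE interval), \code{low_te_identity} (cluster consensus clip
#' matches the TE consensus at under \code{min_te_identity} or across under
#' \code{min_te_span} nt), \code{low_genome_identity} (genomic side of the
#' cluster under \code{min_genome_identity}), and
#' \code{inconsistent_breakpoint} (independent realignment of the cluster
#' consensus sequence with a different seed length shifts the breakpoint by
#' more than \code{shift_tol} nt). Unlabelled clusters pass.
#'
#' @param clusters Data.frame from [clusterJunctions()].
#' @param reference [Biostrings::DNAStringSet] reference genome.
#' @param te_annotation [GenomicRanges::GRanges] of reference TE intervals
#'   (e.g. the simulator's decoys). Required.
#' @param min_te_identity,min_te_span,min_genome_identity Filter
#'   thresholds.
#' @param shift_tol Breakpoint consistency tolerance (nt).
#' @param check_k Seed length of the independent realignment.
#' @return The cluster data.frame with its \code{filters} column filled.
#' @export
filterClusters <- function(clusters, reference, te_annotation,
                           min_te_identity = 0.90, min_te_span = 30L,
                           min_genome_identity = 0.95, shift_tol = 5L,
                           check_k = 11L) {
  if (is.null(te_annotation))
    stop("te_annotation is required (reference TE interval BED/GRanges)")
  if (!nrow(clusters)) return(clusters)
  gs <- as.character(reference)
  bp_gr <- GenomicRanges::GRanges(clusters$contig,
    IRanges::IRanges(clusters$breakpoint, clusters$breakpoint))
  ov <- GenomicRanges::countOverlaps(bp_gr, te_annotation) > 0L
  clusters$filters[ov] <- add_filter(clusters$filters[ov], "te_overlap")

  low_te <- is.na(clusters$identity) | clusters$identity < min_te_identity |
    clusters$aligned_len < min_te_span
  low_te[is.na(low_te)] <- TRUE
  clusters$filters[low_te] <- add_filter(clusters$filters[low_te],
                                         "low_te_identity")

  low_g <- clusters$genome_identity < min_genome_identity
  clusters$filters[low_g] <- add_filter(clusters$filters[low_g],
                                        "low_genome_identity")

  # breakpoint consistency: rebuild the cluster consensus sequence (a
  # reference-side anchor plus the consensus clip) and realign it with a
  # different seed length
  for (i in seq_len(nrow(clusters))) {
    ctg <- clusters$contig[i]; bp <- clusters$breakpoint[i]
    L <- nchar(gs[ctg])
    anchor <- 200L   # genome anchor outweighs the clip side at TE copies
    if (clusters$clip_side[i] == "right") {
      seqq <- paste0(substr(gs[ctg], max(1L, bp - anchor + 1L), bp),
                     clusters$consensus_clip[i])
    } else {
      seqq <- paste0(clusters$consensus_clip[i],
                     substr(gs[ctg], bp, min(L, bp + anchor - 1L)))
    }
    re <- alignReads(stats::setNames(seqq, "consensus_check"), reference,
                     k = check_k, min_score = 25L)
    shifted <- TRUE
    if (nrow(re) == 1L && re$contig == ctg) {
      bp2 <- if (clusters$clip_side[i] == "right") re$end else re$start
      if (abs(bp2 - bp) <= shift_tol) shifted <- FALSE
    }
    if (shifted)
      clusters$filters[i] <- add_filter(clusters$filters[i],
                                        "inconsistent_breakpoint")
  }
  clusters
}

#' Pair 5' and 3' junction clusters into insertion calls
#'
#' A right-clip and a left-clip cluster on the same contig with the same
#' element strand are paired when their breakpoints are within
#' \code{pairing_window} nt. The genomic offset between them sets the
#' annotation: breakpoint overlap of k nt means a k nt target-site
#' duplication; a gap of k nt means a k nt deletion at the integration
#' site. Unpaired clusters become single-ended calls (label
#' \code{single_end}). Poly-A length is measured from the 3' cluster's
#' element-oriented consensus clip, and junction microhomology against the
#' reference is recorded per call.
#'
#' @param clusters Filtered cluster data.frame.
#' @param reference Reference genome [Biostrings::DNAStringSet].
#' @param pairing_window Maximum genomic offset between paired junctions
#'   (nt), spanning plausible TSD and site-deletion sizes.
#' @param consensus_set Consensus set (for element length inference).
#' @return Data.frame of insertion calls.
#' @export
pairAndAnnotate <- function(clusters, reference, pairing_window = 700L,
                            consensus_set = consensusSet()) {
  gs <- as.character(reference)
  calls <- list()
  used <- rep(FALSE, nrow(clusters))
  if (nrow(clusters)) {
    rc <- which(clusters$clip_side == "right")
    lc <- which(clusters$clip_side == "left")
    pairs <- expand.grid(r = rc, l = lc)
    if (nrow(pairs)) {
      same <- clusters$contig[pairs$r] == clusters$contig[pairs$l] &
        clusters$element_strand[pairs$r] == clusters$element_strand[pairs$l]
      pairs <- pairs[same, , drop = FALSE]
      off <- clusters$breakpoint[pairs$l] - clusters$breakpoint[pairs$r] - 1L
      keep <- off >= -60L & off <= pairing_window
      pairs <- pairs[keep, , drop = FALSE]
      off <- off[keep]
      for (pi in order(abs(off))) {
        r <- pairs$r[pi]; l <- pairs$l[pi]
        if (used[r] || used[l]) next
        used[r] <- TRUE; used[l] <- TRUE
        calls[[length(calls) + 1L]] <-
          build_call(clusters[r, ], clusters[l, ], gs, consensus_set)
      }
    }
    for (i in which(!used)) {
      calls[[length(calls) + 1L]] <-
        build_call(if (clusters$clip_side[i] == "right") clusters[i, ] else NULL,
                   if (clusters$clip_side[i] == "left") clusters[i, ] else NULL,
                   gs, consensus_set)
    }
  }
  if (!length(calls)) return(empty_calls())
  res <- do.call(rbind, calls)
  res$call_id <- sprintf("call%04d", seq_len(nrow(res)))
  res
}

# Assemble one call from a right-clip cluster and/or left-clip cluster.
build_call <- function(rcl, lcl, gs, consensus_set) {
  one <- if (!is.null(rcl)) rcl else lcl
  strand <- one$element_strand
  tsd <- 0L; del <- 0L; tsd_seq <- ""
  filters <- character()
  if (!is.null(rcl) && !is.null(lcl)) {
    offd <- lcl$breakpoint - rcl$breakpoint - 1L
    if (offd < 0L) {
      tsd <- -offd
      tsd_seq <- substr(gs[rcl$contig], lcl$breakpoint, rcl$breakpoint)
    } else if (offd > 0L) del <- offd
    filters <- union(strsplit(rcl$filters, ",")[[1L]],
                     strsplit(lcl$filters, ",")[[1L]])
  } else {
    filters <- c(strsplit(one$filters, ",")[[1L]], "single_end")
  }
  filters <- setdiff(filters, "")
  j5 <- if (strand == "+") rcl else lcl
  j3 <- if (strand == "+") lcl else rcl
  # poly-A and any 3' transduced segment from the element-oriented 3p clip
  polya <- 0L; extra3p <- ""
  if (!is.null(j3) && !is.na(j3$clip_end)) {
    oc <- if (j3$clip_side == "left") j3$consensus_clip else
      revcomp(j3$consensus_clip)
    pa <- detectPolyA(oc, element_end = j3$clip_end)
    polya <- pa$polya_len
    extra3p <- substr(oc, j3$clip_end + pa$run_len + 1L, nchar(oc))
  }
  # inferred consensus interval and element length
  fam <- if (!is.null(j5) && !is.na(j5$family)) j5$family else one$family
  Lc <- if (!is.na(fam) && fam %in% names(consensus_set))
    length(consensusSequence(consensus_set[[fam]])) else NA_integer_
  cs <- if (!is.null(j5) && !is.na(j5$cons_start)) j5$cons_start else
    NA_integer_
  ce <- if (!is.null(j3) && !is.na(j3$cons_end)) j3$cons_end else
    NA_integer_
  element_len <- if (!is.na(cs) && !is.na(ce)) ce - cs + 1L
    else if (!is.na(cs) && !is.na(Lc)) Lc - cs + 1L
    else if (!is.na(ce)) ce
    else NA_integer_
  # junction microhomology vs the reference, reported as the max over the
  # junctions present
  mh <- 0L
  if (!is.null(rcl) && !is.na(rcl$identity)) {
    flank <- substr(gs[rcl$contig], max(1L, rcl$breakpoint - 49L),
                    rcl$breakpoint)
    mh <- max(mh, microhomology(flank, rcl$consensus_clip, "5p"))
  }
  if (!is.null(lcl) && !is.na(lcl$identity)) {
    L <- nchar(gs[lcl$contig])
    flank <- substr(gs[lcl$contig], lcl$breakpoint,
                    min(L, lcl$breakpoint + 49L))
    mh <- max(mh, microhomology(flank, lcl$consensus_clip, "3p"))
  }
  # call-level confidences from the better-supported junction
  jbest <- if (!is.null(rcl) && (is.null(lcl) ||
               rcl$n_support >= lcl$n_support)) rcl else lcl
  data.frame(
    contig = one$contig,
    bp5 = if (!is.null(j5)) j5$breakpoint else NA_integer_,
    bp3 = if (!is.null(j3)) j3$breakpoint else NA_integer_,
    bp_right = if (!is.null(rcl)) rcl$breakpoint else NA_integer_,
    bp_left = if (!is.null(lcl)) lcl$breakpoint else NA_integer_,
    strand = strand, family = fam,
    tsd_len = tsd, tsd_seq = tsd_seq, deletion_len = del,
    polya_len = polya, extra_3p = extra3p,
    cons_start = cs, cons_end = ce, element_len = element_len,
    microhomology = mh,
    strand_confidence = jbest$strand_confidence,
    family_confidence = jbest$family_confidence,
    position_confidence = jbest$position_confidence,
    support_5p = if (!is.null(j5)) j5$n_support else 0L,
    support_3p = if (!is.null(j3)) j3$n_support else 0L,
    cluster_5p = if (!is.null(j5)) j5$cluster_id else NA_character_,
    cluster_3p = if (!is.null(j3)) j3$cluster_id else NA_character_,
    filters = paste(sort(filters), collapse = ","),
    stringsAsFactors = FALSE)
}

empty_calls <- function() {
  data.frame(contig = character(), bp5 = integer(), bp3 = integer(),
             bp_right = integer(), bp_left = integer(), strand = character(),
             family = character(), tsd_len = integer(), tsd_seq = character(),
             deletion_len = integer(), polya_len = integer(),
             extra_3p = character(), cons_start = integer(),
             cons_end = integer(), element_len = integer(),
             microhomology = integer(), strand_confidence = numeric(),
             family_confidence = numeric(), position_confidence = numeric(),
             support_5p = integer(), support_3p = integer(),
             cluster_5p = character(), cluster_3p = character(),
             filters = character(), call_id = character(),
             stringsAsFactors = FALSE)
}

#' Count per-sample junction-spanning read support for calls
#'
#' Per sample, the number of distinct non-duplicate reads whose realigned
#' clip supports either junction of the call (breakpoint within
#' \code{window} nt, matching consensus family).
#'
#' @param calls Data.frame from [pairAndAnnotate()].
#' @param clips Data.frame from [buildClipTable()] across all samples.
#' @param samples Character vector of sample labels to count (defaults to
#'   those present in \code{clips}).
#' @param window Breakpoint match window (nt).
#' @return The calls data.frame with one \code{support.<sample>} column per
#'   sample.
#' @export
countSupport <- function(calls, clips, samples = NULL, window = 10L) {
  samples <- samples %||% sort(unique(clips$sample))
  if (length(bad <- setdiff(samples, unique(clips$sample))) &&
      nrow(clips) > 0L && length(samples) > length(unique(clips$sample)))
    message("samples with no clipped reads: ", paste(bad, collapse = ", "))
  for (s in samples) calls[[paste0("support.", s)]] <- 0L
  if (!nrow(calls) || !nrow(clips)) return(calls)
  for (i in seq_len(nrow(calls))) {
    near <- clips$contig == calls$contig[i] & clips$family == calls$family[i] &
      ((!is.na(calls$bp_right[i]) & clips$clip_side == "right" &
          abs(clips$bp - calls$bp_right[i]) <= window) |
       (!is.na(calls$bp_left[i]) & clips$clip_side == "left" &
          abs(clips$bp - calls$bp_left[i]) <= window))
    near[is.na(near)] <- FALSE
    sub <- clips[near, , drop = FALSE]
    sub <- sub[!duplicated(paste(sub$sample, sub$read_id)), , drop = FALSE]
    cnt <- table(sub$sample)
    for (s in intersect(samples, names(cnt)))
      calls[i, paste0("support.", s)] <- as.integer(cnt[[s]])
  }
  calls
}
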