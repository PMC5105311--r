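# Soft-clip genome alignment: an internal seed-and-extend aligner, SAM/BAM
# ingestion, duplicate marking, and realignment of clipped ends to the TE
# consensus set.

SW_MATCH <- 1L; SW_MISMATCH <- -1L; SW_GAP_OPEN <- 2; SW_GAP_EXT <- 1

sw_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = SW_MATCH,
                                           mismatch = SW_MISMATCH)
}

# Best-scoring ungapped local segment of read vs genome window on one
# diagonal (match +1 / mismatch -1): returns c(i, j, score, matches) in read
# coordinates of the compared region, or NULL.
best_diag_segment <- function(m) {
  w <- length(m)
  P <- cumsum(m)
  Q <- c(0L, P[-w])              # prefix sums before each position
  Pm <- cummin(Q)
  sc <- P - Pm
  best <- max(sc)
  # tightest maximal segment: zero-sum overhangs (mismatch/match pairs
  # straddling a junction) must not blur the breakpoint
  j <- which.max(sc)
  i <- max(which(Q[seq_len(j)] == Pm[j]))
  matches <- (best + (j - i + 1L)) / 2L
  c(i = i, j = j, score = best, matches = matches)
}

# Parse simulator read names into fragment keys; fall back to the
# alignment-derived key.
fragment_key_from_name <- function(read_id, contig, start, end, strand) {
  m <- regmatches(read_id,
    regexec("^frag\\d+:([^:]+):(\\d+):(\\d+):([+-])", read_id))
  vapply(seq_along(read_id), function(i) {
    g <- m[[i]]
    if (length(g) == 5L)
      paste(g[2L], g[3L], g[4L], g[5L], sep = ":")
    else
      paste(contig[i], start[i], end[i], strand[i], sep = ":")
  }, character(1L))
}

# Start positions of each query in `subject` (a DNAString). Small query
# sets loop matchPattern; large sets amortise a PDict build.
match_starts <- function(queries, subject) {
  if (length(queries) < 200L) {
    lapply(queries, function(q)
      Biostrings::start(Biostrings::matchPattern(q, subject)))
  } else {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(queries))
    Biostrings::startIndex(Biostrings::matchPDict(pd, subject))
  }
}

empty_alignments <- function() {
  data.frame(read_id = character(), sample = character(),
             contig = character(), start = integer(), end = integer(),
             strand = character(), clip_left = character(),
             clip_right = character(), genome_identity = numeric(),
             score = numeric(), mapq_proxy = integer(),
             fragment_key = character(), duplicate = logical(),
             stringsAsFactors = FALSE)
}

#' Align reads to a reference with a seed-and-extend soft-clipping aligner
#'
#' Exact k-mer seeds (default k = 21) locate candidate diagonals; each
#' candidate is extended by maximal-scoring ungapped local alignment
#' (match +1 / mismatch -1), with an affine-gap Smith-Waterman fallback
#' (open 2, extend 1) when the ungapped extension leaves identity below
#' 0.9. Bases outside the chosen local alignment become soft clips, stored
#' in genome-forward orientation. Reads with multiple equally-best
#' candidate locations get \code{mapq_proxy} 0, unique best placements 60.
#'
#' @param reads Named character vector of read sequences.
#' @param reference [Biostrings::DNAStringSet] genome.
#' @param k Seed length.
#' @param min_score Minimum local score to report an alignment.
#' @param sample Sample label attached to every alignment.
#' @return A data.frame of alignments (one row per aligned read) with an
#'   attribute \code{unaligned} holding the read ids with no seed match or
#'   sub-threshold score.
#' @export
alignReads <- function(reads, reference, k = 21L, min_score = 30L,
                       sample = "sample1") {
  stopifnot(length(reads) > 0L)
  ids <- names(reads) %||% sprintf("read%06d", seq_along(reads))
  seqs_f <- unname(reads)
  seqs_r <- revcomp(seqs_f)
  lens <- nchar(seqs_f)
  gs <- as.character(reference)
  glens <- nchar(gs)

  out <- list(); unaligned <- character()

  # fast path: error-free full-length reads resolve by exact whole-read
  # matching (constant width dictionary); the seed-and-extend path then only
  # handles reads with errors or junction-spanning structure
  fast <- vector("list", length(seqs_f))
  todo <- rep(TRUE, length(seqs_f))
  if (length(unique(lens)) == 1L && lens[1L] >= k) {
    nhits <- integer(length(seqs_f))
    for (orient in c("+", "-")) {
      ss <- if (orient == "+") seqs_f else seqs_r
      for (ci in names(gs)) {
        st <- match_starts(ss, Biostrings::DNAString(gs[[ci]]))
        hit <- which(lengths(st) > 0L)
        nhits[hit] <- nhits[hit] + lengths(st)[hit]
        for (ri in hit) {
          if (is.null(fast[[ri]]))
            fast[[ri]] <- list(ctg = ci, start = st[[ri]][1L],
                               orient = orient)
        }
      }
    }
    for (ri in which(!vapply(fast, is.null, logical(1L)))) {
      f <- fast[[ri]]
      out[[length(out) + 1L]] <- data.frame(
        read_id = ids[ri], sample = sample, contig = f$ctg,
        start = f$start, end = f$start + lens[ri] - 1L, strand = f$orient,
        clip_left = "", clip_right = "", genome_identity = 1,
        score = as.numeric(lens[ri]),
        mapq_proxy = if (nhits[ri] == 1L) 60L else 0L,
        fragment_key = NA_character_, duplicate = FALSE,
        stringsAsFactors = FALSE)
      todo[ri] <- FALSE
    }
  }

  # seed table: read index, orientation, offset within the oriented read
  seed_rows <- list()
  for (orient in c("+", "-")) {
    ss <- if (orient == "+") seqs_f else seqs_r
    offs <- lapply(seq_along(lens), function(i) {
      n <- lens[i]
      if (!todo[i] || n < k) return(integer())
      unique(c(1L, max(1L, (n - k) %/% 2L + 1L), n - k + 1L))
    })
    ri <- rep(seq_along(ss), lengths(offs))
    off <- unlist(offs)
    if (!length(off)) next
    seed_rows[[orient]] <- data.frame(
      read = ri, orient = orient, off = off,
      seed = substr(ss[ri], off, off + k - 1L), stringsAsFactors = FALSE)
  }
  seeds <- do.call(rbind, seed_rows)
  if (!is.null(seeds)) {
    keep <- !grepl("[^ACGT]", seeds$seed)
    seeds <- seeds[keep, , drop = FALSE]
  }

  # candidate diagonals per read from exact seed matches
  cand <- list()
  if (!is.null(seeds) && nrow(seeds)) {
    for (ci in names(gs)) {
      st <- match_starts(seeds$seed, Biostrings::DNAString(gs[[ci]]))
      nh <- lengths(st)
      if (!sum(nh)) next
      idx <- rep(seq_len(nrow(seeds)), nh)
      cand[[length(cand) + 1L]] <- data.frame(
        read = seeds$read[idx], orient = seeds$orient[idx], contig = ci,
        diag = unlist(st) - seeds$off[idx] + 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) {
    res <- if (length(out)) do.call(rbind, out) else empty_alignments()
    if (nrow(res))
      res$fragment_key <- fragment_key_from_name(res$read_id, res$contig,
                                                 res$start, res$end,
                                                 res$strand)
    attr(res, "unaligned") <- setdiff(ids, res$read_id)
    return(res)
  }
  cand <- do.call(rbind, cand)
  # aggregate duplicate (read, orientation, contig, diagonal) entries and
  # keep their seed-support count: the true locus is supported by more
  # seeds than chance cross-matches at related TE copies
  key <- paste(cand$read, cand$orient, cand$contig, cand$diag, sep = "|")
  supp <- as.integer(ave(rep(1L, nrow(cand)), key, FUN = sum))
  first <- !duplicated(key)
  cand <- cand[first, , drop = FALSE]
  cand$nseed <- supp[first]
  cand <- cand[order(cand$read, -cand$nseed, cand$contig, cand$orient,
                     cand$diag), ]
  by_read <- split(seq_len(nrow(cand)), cand$read)

  submat <- sw_submat()
  for (ri_chr in names(by_read)) {
    ri <- as.integer(ri_chr)
    rows <- by_read[[ri_chr]]
    n_r <- lens[ri]
    best <- NULL; best_score <- -Inf; tie <- FALSE
    for (ii in rows) {
      orient <- cand$orient[ii]; ctg <- cand$contig[ii]; d <- cand$diag[ii]
      rs <- if (orient == "+") seqs_f[ri] else seqs_r[ri]
      ws <- max(1L, d); we <- min(glens[ctg], d + n_r - 1L)
      if (we < ws) next
      skip <- ws - d                       # read bases before the window
      rseg <- substr(rs, 1L + skip, skip + (we - ws + 1L))
      win <- substr(gs[ctg], ws, we)
      m <- ifelse(utf8ToInt(rseg) == utf8ToInt(win), SW_MATCH, SW_MISMATCH)
      seg <- best_diag_segment(m)
      sc <- seg["score"]
      if (sc > best_score + 1e-9) {
        best_score <- sc; tie <- FALSE
        best <- list(orient = orient, ctg = ctg,
                     r_start = seg[["i"]] + skip, r_end = seg[["j"]] + skip,
                     g_start = ws + seg[["i"]] - 1L, g_end = ws + seg[["j"]] - 1L,
                     matches = seg[["matches"]], rs = rs)
      } else if (abs(sc - best_score) < 1e-9 && !is.null(best) &&
                 !(identical(ctg, best$ctg) &&
                   ws + seg[["i"]] - 1L == best$g_start &&
                   identical(orient, best$orient))) {
        tie <- TRUE
      }
      # a near-full-length placement cannot be beaten; stop evaluating
      # lower-support candidates
      if (best_score >= n_r - 6L) break
    }
    if (is.null(best) || best_score < min_score) {
      unaligned <- c(unaligned, ids[ri]); next
    }
    alen <- best$r_end - best$r_start + 1L
    ident <- best$matches / alen
    if (ident < 0.9) {
      # gapped rescue around the best diagonal
      ws <- max(1L, best$g_start - best$r_start + 1L - 30L)
      we <- min(glens[best$ctg], best$g_start - best$r_start + n_r + 30L)
      pa <- Biostrings::pairwiseAlignment(best$rs,
        substr(gs[best$ctg], ws, we), type = "local",
        substitutionMatrix = submat,
        gapOpening = SW_GAP_OPEN, gapExtension = SW_GAP_EXT)
      if (Biostrings::score(pa) > best_score) {
        pr <- Biostrings::pattern(pa); sr <- Biostrings::subject(pa)
        best$r_start <- Biostrings::start(pr)
        best$r_end <- Biostrings::end(pr)
        best$g_start <- ws + Biostrings::start(sr) - 1L
        best$g_end <- ws + Biostrings::end(sr) - 1L
        best_score <- Biostrings::score(pa)
        cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
        ident <- Biostrings::nmatch(pa) / cols
        alen <- best$r_end - best$r_start + 1L
      }
    }
    clip_l <- substr(best$rs, 1L, best$r_start - 1L)
    clip_r <- substr(best$rs, best$r_end + 1L, n_r)
    out[[length(out) + 1L]] <- data.frame(
      read_id = ids[ri], sample = sample, contig = best$ctg,
      start = best$g_start, end = best$g_end, strand = best$orient,
      clip_left = clip_l, clip_right = clip_r,
      genome_identity = ident, score = as.numeric(best_score),
      mapq_proxy = if (tie) 0L else 60L,
      fragment_key = NA_character_, duplicate = FALSE,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else empty_alignments()
  if (nrow(res))
    res$fragment_key <- fragment_key_from_name(res$read_id, res$contig,
                                               res$start, res$end, res$strand)
  no_seed <- setdiff(ids, c(res$read_id, unaligned))
  attr(res, "unaligned") <- c(unaligned, no_seed)
  res
}

#' Ingest soft-clipped alignments from SAM/BAM
#'
#' Converts each primary alignment's soft-clipped ends into clipped-
#' alignment records (records without soft clips are not emitted).
#' Secondary and supplementary alignments are skipped; hard-clipped records
#' are skipped with a warning since the clipped sequence is unavailable.
#'
#' @param path SAM or BAM file.
#' @param reference Optional [Biostrings::DNAStringSet]; when supplied,
#'   \code{genome_identity} is computed against it (else 1.0 is assumed).
#' @param sample Sample label.
#' @return A data.frame with the same columns as [alignReads()].
#' @export
ingestSam <- function(path, reference = NULL, sample = "sample1") {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "@") & nzchar(ln)]
    fx <- strsplit(ln, "\t")
    b <- list(
      qname = vapply(fx, `[`, character(1L), 1L),
      flag = as.integer(vapply(fx, `[`, character(1L), 2L)),
      rname = vapply(fx, `[`, character(1L), 3L),
      pos = as.integer(vapply(fx, `[`, character(1L), 4L)),
      mapq = as.integer(vapply(fx, `[`, character(1L), 5L)),
      cigar = vapply(fx, `[`, character(1L), 6L),
      isize = as.integer(vapply(fx, `[`, character(1L), 9L)),
      seq = vapply(fx, `[`, character(1L), 10L))
  } else {
    p <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq",
               "isize"))
    sb <- Rsamtools::scanBam(path, param = p)[[1L]]
    b <- list(qname = sb$qname, flag = sb$flag,
              rname = as.character(sb$rname), pos = sb$pos, mapq = sb$mapq,
              cigar = sb$cigar, isize = sb$isize,
              seq = as.character(sb$seq))
  }
  n <- length(b$qname)
  out <- list()
  gs <- if (!is.null(reference)) as.character(reference) else NULL
  for (i in seq_len(n)) {
    flag <- b$flag[i]
    if (bitwAnd(flag, 4L) != 0L) next                    # unmapped
    if (bitwAnd(flag, 256L) != 0L || bitwAnd(flag, 2048L) != 0L) next
    cig <- b$cigar[i]
    ops <- regmatches(cig, gregexpr("\\d+[MIDNSHP=X]", cig))[[1L]]
    lens <- as.integer(sub("[A-Z=]$", "", ops))
    typ <- sub("^\\d+", "", ops)
    if (any(typ == "H")) {
      warning("skipping hard-clipped record: ", b$qname[i])
      next
    }
    if (sum(lens[typ %in% c("M", "I", "S", "=", "X")]) !=
        nchar(b$seq[i]))
      stop("CIGAR/sequence length mismatch for read ", b$qname[i])
    if (!any(typ == "S")) next
    sq <- b$seq[i]
    cl <- if (typ[1L] == "S") substr(sq, 1L, lens[1L]) else ""
    ntyp <- length(typ)
    cr <- if (typ[ntyp] == "S")
      substr(sq, nchar(sq) - lens[ntyp] + 1L, nchar(sq)) else ""
    ref_span <- sum(lens[typ %in% c("M", "D", "N", "=", "X")])
    start <- b$pos[i]; end <- start + ref_span - 1L
    ctg <- b$rname[i]
    rstrand <- if (bitwAnd(flag, 16L) != 0L) "-" else "+"
    ident <- 1
    if (!is.null(gs) && ctg %in% names(gs)) {
      aligned <- substr(sq, nchar(cl) + 1L, nchar(sq) - nchar(cr))
      refseg <- substr(gs[ctg], start, end)
      if (nchar(aligned) == nchar(refseg) && nchar(aligned) > 0L)
        ident <- mean(utf8ToInt(aligned) == utf8ToInt(refseg))
    }
    isz <- b$isize[i]
    fk <- if (!is.na(isz) && isz > 0L)
      paste(ctg, start - nchar(cl) * 0L, b$pos[i] + isz - 1L, "+", sep = ":")
    else if (!is.na(isz) && isz < 0L)
      paste(ctg, b$pos[i] + ref_span + isz, b$pos[i] + ref_span - 1L, "+",
            sep = ":")
    else paste(ctg, start, end,
               rstrand, sep = ":")
    out[[length(out) + 1L]] <- data.frame(
      read_id = b$qname[i], sample = sample, contig = ctg,
      start = start, end = end,
      strand = rstrand,
      clip_left = cl, clip_right = cr, genome_identity = ident,
      score = NA_real_,
      mapq_proxy = ifelse(is.na(b$mapq[i]), 0L, as.integer(b$mapq[i])),
      fragment_key = fk, duplicate = FALSE, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else empty_alignments()
}

#' Mark PCR duplicates by fragment endpoints
#'
#' Within each \code{fragment_key} group (contig + fragment start/end +
#' orientation) one record is kept as representative (highest genome
#' identity, ties broken by lexicographic read id); the rest are flagged.
#' Flagged records are excluded from all downstream counting.
#'
#' @param alignments Data.frame from [alignReads()] or [ingestSam()].
#' @return The data.frame with its \code{duplicate} column filled.
#' @export
markDuplicates <- function(alignments) {
  if (!nrow(alignments)) return(alignments)
  alignments$duplicate <- FALSE
  # a fragment is one physical molecule: both mates share the key, so keys
  # are grouped per (key, mate side) using the first/last 150 coordinates —
  # here each aligned read row is its own observation, grouped by key + the
  # read's own interval side
  grp <- paste(alignments$sample, alignments$fragment_key,
               substr(alignments$read_id, nchar(alignments$read_id) - 1L,
                      nchar(alignments$read_id)), sep = "|")
  ord <- order(grp, -alignments$genome_identity, alignments$read_id)
  first_of_grp <- !duplicated(grp[ord])
  alignments$duplicate[ord] <- !first_of_grp
  alignments
}

#' Realign many clips against the consensus set at once
#'
#' Batch version of [realignClip()]: exact 12-mer seeds from every oriented
#' clip are matched against each consensus in one dictionary pass, and only
#' seeded (clip, consensus, strand) combinations are aligned by
#' Smith-Waterman in a window around the seeds. Seedless clips are still
#' fully scanned against short consensi (<= 1500 nt).
#'
#' @param clips Character vector of clip sequences.
#' @param consensus_set Named list of [TEConsensus-class] objects.
#' @param minclip Minimum clip length considered.
#' @param score_floor Minimum local alignment score for a hit.
#' @return A list (one element per clip) of one-row data.frames as from
#'   [realignClip()], or NULL where there is no hit.
#' @export
realignClipBatch <- function(clips, consensus_set = consensusSet(),
                             minclip = 30L, score_floor = 20) {
  n <- length(clips)
  out <- vector("list", n)
  ok <- which(!is.na(clips) & nchar(clips) >= minclip)
  if (!length(ok)) return(out)
  seed_w <- 12L; stride <- 10L
  oriented <- list(`+` = clips, `-` = rep(NA_character_, n))
  oriented[["-"]][ok] <- revcomp(clips[ok])
  # seed table across all clips and orientations
  st_i <- integer(); st_o <- character(); st_off <- integer()
  st_seed <- character()
  for (o in c("+", "-")) {
    for (i in ok) {
      s <- oriented[[o]][i]
      offs <- unique(c(seq(1L, max(1L, nchar(s) - seed_w + 1L), by = stride),
                       nchar(s) - seed_w + 1L))
      sds <- substr(rep(s, length(offs)), offs, offs + seed_w - 1L)
      keep <- !grepl("[^ACGT]", sds) & nchar(sds) == seed_w
      st_i <- c(st_i, rep(i, sum(keep)))
      st_o <- c(st_o, rep(o, sum(keep)))
      st_off <- c(st_off, offs[keep]); st_seed <- c(st_seed, sds[keep])
    }
  }
  cand <- list()   # (i, o, fam) -> diag range
  if (length(st_seed)) {
    for (fam in names(consensus_set)) {
      cs <- Biostrings::DNAString(
        as.character(consensusSequence(consensus_set[[fam]])))
      mi <- match_starts(st_seed, cs)
      nh <- lengths(mi)
      if (!sum(nh)) next
      idx <- rep(seq_along(st_seed), nh)
      diag <- unlist(mi) - st_off[idx] + 1L
      key <- paste(st_i[idx], st_o[idx], fam, sep = "|")
      sp <- split(diag, key)
      for (kk in names(sp)) cand[[kk]] <- range(sp[[kk]])
    }
  }
  submat <- sw_submat()
  # evaluate candidates per clip
  seeded <- if (length(cand))
    unique(as.integer(vapply(strsplit(names(cand), "|", fixed = TRUE),
                             `[`, character(1L), 1L)))
  else integer()
  for (i in ok) {
    best <- NULL
    for (fam in names(consensus_set)) {
      cons_str <- as.character(consensusSequence(consensus_set[[fam]]))
      L <- nchar(cons_str)
      for (o in c("+", "-")) {
        key <- paste(i, o, fam, sep = "|")
        win <- NULL
        if (!is.null(cand[[key]])) {
          d <- cand[[key]]
          win <- c(max(1L, d[1L] - 30L),
                   min(L, d[2L] + nchar(oriented[[o]][i]) + 30L))
        } else if (!(i %in% seeded) && L <= 1500L) {
          win <- c(1L, L)
        }
        if (is.null(win)) next
        pa <- Biostrings::pairwiseAlignment(oriented[[o]][i],
          substr(cons_str, win[1L], win[2L]), type = "local",
          substitutionMatrix = submat,
          gapOpening = SW_GAP_OPEN, gapExtension = SW_GAP_EXT)
        sc <- Biostrings::score(pa)
        if (!is.finite(sc)) next
        if (is.null(best) || sc > best$score + 1e-9) {
          cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
          best <- list(score = sc, family = fam, strand = o,
            identity = Biostrings::nmatch(pa) / cols,
            cons_start = win[1L] +
              Biostrings::start(Biostrings::subject(pa)) - 1L,
            cons_end = win[1L] + Biostrings::end(Biostrings::subject(pa)) - 1L,
            clip_start = Biostrings::start(Biostrings::pattern(pa)),
            clip_end = Biostrings::end(Biostrings::pattern(pa)),
            aligned_len = Biostrings::width(Biostrings::subject(pa)))
        }
      }
    }
    if (!is.null(best) && best$score >= score_floor) {
      out[[i]] <- data.frame(family = best$family, strand = best$strand,
        cons_start = best$cons_start, cons_end = best$cons_end,
        identity = best$identity, aligned_len = best$aligned_len,
        clip_start = best$clip_start, clip_end = best$clip_end,
        score = best$score, stringsAsFactors = FALSE)
    }
  }
  out
}

# Local alignment of an oriented clip against one consensus sequence,
# seeded; returns NULL or a list with score/identity/interval information.
clip_vs_consensus <- function(clip, cons_str, seed_w = 12L, stride = 10L) {
  n <- nchar(clip)
  L <- nchar(cons_str)
  offs <- seq(1L, max(1L, n - seed_w + 1L), by = stride)
  hits <- integer()
  for (o in offs) {
    sd <- substr(clip, o, o + seed_w - 1L)
    if (nchar(sd) < seed_w || grepl("[^ACGT]", sd)) next
    mp <- Biostrings::matchPattern(sd, cons_str)
    if (length(mp))
      hits <- c(hits, Biostrings::start(mp) - o + 1L)
  }
  win <- NULL
  if (length(hits)) {
    d <- sort(unique(hits))
    win <- c(max(1L, min(d) - 30L), min(L, max(d) + n + 30L))
  } else if (L <= 1500L) {
    win <- c(1L, L)     # small target: full scan is cheap
  } else {
    # no exact seed anywhere on a long consensus: no credible hit
    return(NULL)
  }
  pa <- Biostrings::pairwiseAlignment(clip,
    substr(cons_str, win[1L], win[2L]), type = "local",
    substitutionMatrix = sw_submat(),
    gapOpening = SW_GAP_OPEN, gapExtension = SW_GAP_EXT)
  sc <- Biostrings::score(pa)
  if (!is.finite(sc)) return(NULL)
  cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
  list(score = sc,
       identity = Biostrings::nmatch(pa) / cols,
       cons_start = win[1L] + Biostrings::start(Biostrings::subject(pa)) - 1L,
       cons_end = win[1L] + Biostrings::end(Biostrings::subject(pa)) - 1L,
       clip_start = Biostrings::start(Biostrings::pattern(pa)),
       clip_end = Biostrings::end(Biostrings::pattern(pa)),
       aligned_len = Biostrings::width(Biostrings::subject(pa)))
}

#' Realign a clipped segment against the TE consensus set
#'
#' Local (Smith-Waterman) alignment of the clip against every consensus and
#' its reverse complement; the highest-scoring hit at or above the score
#' floor is returned. Ties prefer earlier entries of \code{consensus_set}
#' and the forward strand.
#'
#' @param clip_seq Clip sequence (genome-forward orientation, as stored by
#'   [alignReads()]).
#' @param consensus_set Named list of [TEConsensus-class] objects.
#' @param minclip Minimum clip length considered.
#' @param score_floor Minimum local alignment score for a hit.
#' @return One-row data.frame (family, strand, cons_start, cons_end,
#'   identity, aligned_len, clip_start, clip_end, score) or NULL when no
#'   alignment reaches the floor. \code{clip_start}/\code{clip_end} are
#'   coordinates on the oriented clip (the reverse complement when strand
#'   is "-").
#' @export
realignClip <- function(clip_seq, consensus_set = consensusSet(),
                        minclip = 30L, score_floor = 20) {
  realignClipBatch(clip_seq, consensus_set, minclip, score_floor)[[1L]]
}

#' Build the read-level clip table: soft clips realigned to the consensus set
#'
#' Extracts every soft-clipped end of length at least \code{minclip} from
#' non-duplicate, confidently mapped alignments, realigns each clip against
#' the consensus set, and annotates the implied junction: \code{bp} is the
#' last aligned reference base for right clips and the first aligned base
#' for left clips; \code{te_side} is which element end the clip represents
#' (5p for right clips of plus-strand elements and left clips of
#' minus-strand elements, 3p otherwise). Clips with no consensus hit are
#' dropped.
#'
#' @param alignments Data.frame from [alignReads()]/[ingestSam()], after
#'   [markDuplicates()].
#' @param consensus_set Named list of [TEConsensus-class] objects.
#' @param minclip Minimum clip length (nt).
#' @param minq Minimum \code{mapq_proxy} (unique placements only by
#'   default).
#' @return A data.frame, one row per realigned clip.
#' @export
buildClipTable <- function(alignments, consensus_set = consensusSet(),
                           minclip = 30L, minq = 1L) {
  a <- alignments[!alignments$duplicate & alignments$mapq_proxy >= minq, ,
                  drop = FALSE]
  cand <- list()
  for (side in c("left", "right")) {
    cl <- if (side == "left") a$clip_left else a$clip_right
    sel <- which(!is.na(cl) & nchar(cl) >= minclip)
    if (length(sel))
      cand[[side]] <- data.frame(row = sel, side = side, clip = cl[sel],
                                 stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, cand)
  rows <- list()
  if (!is.null(cand) && nrow(cand)) {
    hits <- realignClipBatch(cand$clip, consensus_set, minclip = minclip)
    for (j in seq_len(nrow(cand))) {
      hit <- hits[[j]]
      if (is.null(hit)) next
      i <- cand$row[j]; side <- cand$side[j]
      el_strand <- hit$strand
      te_side <- if ((side == "right") == (el_strand == "+")) "5p" else "3p"
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = a$read_id[i], sample = a$sample[i], contig = a$contig[i],
        clip_side = side,
        bp = if (side == "right") a$end[i] else a$start[i],
        clip_seq = cand$clip[j], element_strand = el_strand,
        te_side = te_side,
        family = hit$family, cons_start = hit$cons_start,
        cons_end = hit$cons_end, identity = hit$identity,
        aligned_len = hit$aligned_len, clip_start = hit$clip_start,
        clip_end = hit$clip_end, genome_identity = a$genome_identity[i],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(), sample = character(),
               contig = character(), clip_side = character(), bp = integer(),
               clip_seq = character(), element_strand = character(),
               te_side = character(), family = character(),
               cons_start = integer(), cons_end = integer(),
               identity = numeric(), aligned_len = integer(),
               clip_start = integer(), clip_end = integer(),
               genome_identity = numeric(), stringsAsFactors = FALSE)
}
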