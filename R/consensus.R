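# Built-in synthetic TE consensus sequences.
#
# These are synthetic stand-ins constructed deterministically in code: they
# reproduce the *structure* of the real elements (a ~6 kb L1 with 5'UTR/ORF1/
# ORF2/3'UTR and a C-dense promoter CpG island carrying exactly 19 CpGs; an
# older L1 subfamily a few percent diverged; a ~300 nt Alu) without being the
# real sequences. All pipeline behaviour that matters (junction arithmetic,
# identity thresholds, CpG readout) depends only on this structure.

.consensus_cache <- new.env(parent = emptyenv())

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(expr)
}

# Break homopolymer runs longer than max_run (keeps alignments unambiguous).
break_homopolymers <- function(x, max_run = 6L) {
  v <- strsplit(x, "", fixed = TRUE)[[1L]]
  r <- rle(v)
  long <- which(r$lengths > max_run)
  if (!length(long)) return(x)
  pos <- cumsum(r$lengths)
  for (i in long) {
    at <- pos[i] - r$lengths[i] + seq(max_run + 1L, r$lengths[i], by = max_run + 1L)
    for (p in at) v[p] <- sample(setdiff(DNA_BASES4, v[p]), 1L)
  }
  paste(v, collapse = "")
}

.build_l1ta <- function() with_seed(190462L, {
  L <- 6018L
  amp_len <- 480L
  # C-dense amplicon head (the bisulfite PCR target over the promoter island);
  # high C density gives the non-CpG conversion QC its resolving power.
  head_p <- c(A = 0.17, C = 0.53, G = 0.12, T = 0.18)
  head <- sample(DNA_BASES4, amp_len, replace = TRUE, prob = head_p)
  head <- strsplit(break_homopolymers(paste(head, collapse = ""), 5L), "")[[1L]]
  # plant exactly 19 CpGs, evenly spread within the island
  cpg_at <- seq(60L, 420L, by = 20L)
  stopifnot(length(cpg_at) == 19L)
  head[cpg_at] <- "C"; head[cpg_at + 1L] <- "G"
  # remove accidental CG dinucleotides elsewhere in the amplicon
  repeat {
    cg <- which(head[-amp_len] == "C" & head[-1L] == "G")
    cg <- setdiff(cg, cpg_at)
    if (!length(cg)) break
    head[cg + 1L] <- "A"
  }
  body <- strsplit(break_homopolymers(paste(
    sample(DNA_BASES4, L - amp_len, replace = TRUE,
           prob = c(A = 0.295, C = 0.205, G = 0.205, T = 0.295)),
    collapse = "")), "")[[1L]]
  seqv <- c(head, body)
  # fixed A-free 3' terminus so a simulated poly-A tail never merges into the
  # element end during alignment
  tail12 <- strsplit("GTCGTCCGGTCG", "")[[1L]]
  seqv[(L - 11L):L] <- tail12
  s <- paste(seqv, collapse = "")
  ncg <- sum(vapply(cpg_at, function(p) substr(s, p, p + 1L) == "CG", logical(1L)))
  stopifnot(ncg == 19L)
  lm <- IRanges::IRanges(
    start = c(1L, 909L, 1988L, 5813L, 49L, 1L),
    end = c(908L, 1925L, 5812L, 6018L, 452L, 480L),
    names = c("five_prime_utr", "orf1", "orf2", "three_prime_utr",
              "promoter_cpg_island", "bis_amplicon")
  )
  TEConsensus("L1Ta_synthetic", s, lm, "L1-Ta")
})

.build_l1pa2 <- function() with_seed(271828L, {
  base <- as.character(consensusSequence(l1Consensus("L1-Ta")))
  L <- nchar(base)
  # ~4 % fixed divergence from the young subfamily, sparing the terminal 12 nt
  pos <- sort(sample.int(L - 12L, round(0.04 * L)))
  s <- mutate_positions(base, pos)
  lm <- landmarks(l1Consensus("L1-Ta"))
  TEConsensus("L1PA2_synthetic", s, lm, "L1PA2")
})

.build_alu <- function() with_seed(314159L, {
  s <- break_homopolymers(random_dna(300L, gc = 0.52))
  lm <- IRanges::IRanges(start = 1L, end = 300L, names = "body")
  TEConsensus("Alu_synthetic", s, lm, "Alu")
})

#' Built-in synthetic L1 consensus
#'
#' Returns the package's deterministic synthetic L1 consensus (6018 nt,
#' landmark intervals for the 5'UTR, ORF1, ORF2, 3'UTR and the promoter CpG
#' island, which carries exactly 19 CpG dinucleotides) or its ~4 % diverged
#' older-subfamily counterpart.
#'
#' @param family \code{"L1-Ta"} (young, active subfamily) or \code{"L1PA2"}.
#' @return A [TEConsensus-class].
#' @export
l1Consensus <- function(family = c("L1-Ta", "L1PA2")) {
  family <- match.arg(family)
  key <- if (family == "L1-Ta") "l1ta" else "l1pa2"
  if (is.null(.consensus_cache[[key]])) {
    .consensus_cache[[key]] <-
      if (family == "L1-Ta") .build_l1ta() else .build_l1pa2()
  }
  .consensus_cache[[key]]
}

#' Built-in synthetic Alu consensus
#'
#' @return A 300 nt [TEConsensus-class] of family \code{"Alu"}.
#' @export
aluConsensus <- function() {
  if (is.null(.consensus_cache[["alu"]]))
    .consensus_cache[["alu"]] <- .build_alu()
  .consensus_cache[["alu"]]
}

#' The default consensus set used for clip realignment
#'
#' Order matters: ties in realignment identity are broken in favour of
#' earlier entries, so the young L1 subfamily comes first.
#'
#' @return Named list of [TEConsensus-class] objects.
#' @export
consensusSet <- function() {
  list(`L1-Ta` = l1Consensus("L1-Ta"),
       L1PA2 = l1Consensus("L1PA2"),
       Alu = aluConsensus())
}

#' Island CpG cytosine positions of a consensus
#'
#' @param consensus A [TEConsensus-class] with a \code{promoter_cpg_island}
#'   landmark.
#' @return Integer vector of 1-based consensus positions of CpG cytosines
#'   within the promoter island.
#' @export
islandCpGs <- function(consensus) {
  lm <- landmarks(consensus)
  stopifnot("promoter_cpg_island" %in% names(lm))
  isl <- lm["promoter_cpg_island"]
  s <- as.character(consensusSequence(consensus))
  hits <- gregexpr("CG", s, fixed = TRUE)[[1L]]
  hits <- hits[hits != -1L]
  as.integer(hits[hits >= IRanges::start(isl) & hits + 1L <= IRanges::end(isl)])
}
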