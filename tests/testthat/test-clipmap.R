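# Aligner, SAM ingestion, duplicate marking, clip realignment.

test_that("aligner resolves exact, chimeric and simulated reads", {
  ref <- makeReference(1, 60000, 0.41, n_decoy_te = 0, seed = 13)
  g <- as.character(ref$genome)[[1]]

  # exact substring: full-length alignment, no clips, unique placement
  reads <- c(rexact = substr(g, 10001, 10150))
  a <- alignReads(reads, ref$genome)
  expect_equal(nrow(a), 1)
  expect_equal(a$start, 10001)
  expect_equal(a$end, 10150)
  expect_identical(a$clip_left, "")
  expect_identical(a$clip_right, "")
  expect_equal(a$mapq_proxy, 60L)

  # genome + consensus chimera: 100 nt aligned, 50 nt right clip
  cons <- as.character(consensusSequence(l1Consensus("L1-Ta")))
  chim <- paste0(substr(g, 20001, 20100), substr(cons, 3000, 3049))
  a2 <- alignReads(c(chim = chim), ref$genome)
  expect_equal(a2$start, 20001)
  expect_equal(a2$end, 20100)
  expect_equal(nchar(a2$clip_right), 50)
  expect_identical(a2$clip_right, substr(cons, 3000, 3049))

  # reverse-complement chimera: same genome-forward clip, minus strand
  a3 <- alignReads(c(chimrc = revcomp(chim)), ref$genome)
  expect_equal(a3$start, 20001)
  expect_identical(a3$clip_right, substr(cons, 3000, 3049))
  expect_equal(a3$strand, "-")

  # simulated error-free reads align exactly at their name-encoded
  # fragment coordinates
  rd <- simulateReads(ref$genome, NULL,
                      ReadSimConfig(coverage = 3, error_rate = 0, seed = 4))
  names(rd$r1) <- paste0(names(rd$r1), "/1")
  a4 <- alignReads(rd$r1, ref$genome)
  expect_equal(nrow(a4), length(rd$r1))
  crd <- do.call(rbind, strsplit(sub("/1$", "", a4$read_id), ":"))
  fst <- as.integer(crd[, 3]); fen <- as.integer(crd[, 4])
  fstrand <- crd[, 5]
  exp_start <- ifelse(fstrand == "+", fst, fen - 149L)
  exp_end <- ifelse(fstrand == "+", fst + 149L, fen)
  expect_equal(a4$start, exp_start)
  expect_equal(a4$end, exp_end)
  expect_equal(a4$strand, fstrand)

  # a read absent from the genome is reported unaligned, not an error
  a5 <- alignReads(c(junk = substr(cons, 100, 249)), ref$genome)
  expect_equal(nrow(a5), 0)
  expect_identical(attr(a5, "unaligned"), "junk")
})

test_that("SAM ingestion converts soft clips and skips unusable records", {
  ref <- makeReference(1, 60000, 0.41, n_decoy_te = 0, seed = 13)
  g <- as.character(ref$genome)[[1]]
  aligned <- substr(g, 5001, 5100)
  clip <- strrep("ACGT", 13)  # 52 nt
  sam <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:contig01\tLN:60000",
    paste("r_rightclip", 0, "contig01", 5001, 60, "100M52S", "*", 0, 152,
          paste0(aligned, clip), "*", sep = "\t"),
    paste("r_leftclip", 0, "contig01", 5001, 60, "52S100M", "*", 0, 152,
          paste0(clip, aligned), "*", sep = "\t"),
    paste("r_noclip", 0, "contig01", 5001, 60, "100M", "*", 0, 100,
          aligned, "*", sep = "\t"),
    paste("r_secondary", 256, "contig01", 5001, 0, "100M52S", "*", 0, 152,
          paste0(aligned, clip), "*", sep = "\t"),
    paste("r_hard", 0, "contig01", 5001, 60, "50H100M", "*", 0, 100,
          aligned, "*", sep = "\t"))
  path <- tempfile(fileext = ".sam")
  writeLines(sam, path)
  expect_warning(res <- ingestSam(path, ref$genome), "hard-clipped")
  expect_setequal(res$read_id, c("r_rightclip", "r_leftclip"))
  rr <- res[res$read_id == "r_rightclip", ]
  expect_identical(rr$clip_right, clip)
  expect_equal(rr$start, 5001)
  expect_equal(rr$end, 5100)
  ll <- res[res$read_id == "r_leftclip", ]
  expect_identical(ll$clip_left, clip)
  expect_equal(ll$genome_identity, 1)

  # CIGAR/sequence length mismatch is a format error naming the read
  bad <- c(sam[1:2],
           paste("r_bad", 0, "contig01", 5001, 60, "90M52S", "*", 0, 142,
                 paste0(aligned, clip), "*", sep = "\t"))
  path2 <- tempfile(fileext = ".sam")
  writeLines(bad, path2)
  expect_error(ingestSam(path2, ref$genome), "r_bad")
})

test_that("alignment and SAM ingestion routes yield the same clusters", {
  ref <- makeReference(1, 60000, 0.41, n_decoy_te = 0, seed = 13)
  g <- as.character(ref$genome)[[1]]
  cons <- as.character(consensusSequence(l1Consensus("L1-Ta")))
  # three chimeric reads supporting one junction at 30000, with staggered
  # genome parts; pick a consensus offset that leaves no chance
  # microhomology across the junction
  co <- 4000
  while (substr(cons, co, co) == substr(g, 30001, 30001) ||
         substr(cons, co + 1, co + 1) == substr(g, 30002, 30002)) co <- co + 1
  reads <- character(3); sams <- character(3)
  for (i in 1:3) {
    glen <- 90 + 10 * i
    clen <- 150 - glen
    reads[i] <- paste0(substr(g, 30001 - glen, 30000),
                       substr(cons, co, co + clen - 1))
    sams[i] <- paste(paste0("jr", i), 0, "contig01", 30001 - glen, 60,
                     sprintf("%dM%dS", glen, clen), "*", 0, 150,
                     reads[i], "*", sep = "\t")
  }
  names(reads) <- paste0("jr", 1:3)
  a_int <- markDuplicates(alignReads(reads, ref$genome))
  cl_int <- clusterJunctions(buildClipTable(a_int))

  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:contig01\tLN:60000", sams), path)
  a_sam <- markDuplicates(ingestSam(path, ref$genome))
  cl_sam <- clusterJunctions(buildClipTable(a_sam))

  expect_equal(nrow(cl_int), 1)
  expect_equal(nrow(cl_sam), 1)
  expect_equal(cl_int$breakpoint, cl_sam$breakpoint)
  expect_equal(cl_int$n_support, cl_sam$n_support)
  expect_equal(cl_int$family, cl_sam$family)
  expect_equal(cl_int$cons_start, cl_sam$cons_start)
  expect_equal(cl_int$breakpoint, 30000)
})

test_that("duplicate marking keeps one representative per fragment", {
  base <- data.frame(
    read_id = c("a/1", "b/1", "c/1"), sample = "s1", contig = "contig01",
    start = c(100L, 100L, 500L), end = c(249L, 249L, 649L), strand = "+",
    clip_left = "", clip_right = "", genome_identity = c(0.99, 1, 1),
    score = 150, mapq_proxy = 60L,
    fragment_key = c("k1", "k1", "k2"), duplicate = FALSE,
    stringsAsFactors = FALSE)
  m <- markDuplicates(base)
  expect_equal(sum(m$duplicate), 1)
  # highest identity kept
  expect_false(m$duplicate[m$read_id == "b/1"])
  expect_true(m$duplicate[m$read_id == "a/1"])
  # idempotent
  expect_identical(markDuplicates(m)$duplicate, m$duplicate)
  # all-distinct keys: nothing flagged
  base$fragment_key <- c("k1", "k2", "k3")
  expect_equal(sum(markDuplicates(base)$duplicate), 0)
})

test_that("clip realignment finds exact hits, strands, and rejects noise", {
  cons <- as.character(consensusSequence(l1Consensus("L1-Ta")))
  clip <- substr(cons, 5900, 5939)   # 40-mer from the 3' UTR
  h <- realignClip(clip)
  expect_equal(h$family, "L1-Ta")
  expect_equal(h$identity, 1)
  expect_equal(h$aligned_len, 40)
  expect_equal(h$strand, "+")
  expect_equal(h$cons_start, 5900)
  expect_equal(h$cons_end, 5939)

  hrc <- realignClip(revcomp(clip))
  expect_equal(hrc$strand, "-")
  expect_equal(hrc$cons_start, 5900)

  # below the minimum clip length: not considered
  expect_null(realignClip(substr(cons, 100, 125)))

  # random clips return no hit, in agreement with the exhaustive
  # Smith-Waterman oracle's score floor
  set.seed(99)
  for (i in 1:10) {
    rc <- random_seq(40)
    r <- realignClip(rc)
    targets <- vapply(consensusSet(), function(x)
      as.character(consensusSequence(x)), character(1))
    oracle <- sw_oracle_best(rc, targets)
    if (oracle < 20) expect_null(r)
  }
})
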