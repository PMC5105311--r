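# Clustering, filtering, pairing arithmetic, support counting, VCF I/O.

make_clip_row <- function(read_id, bp, clip_side, element_strand = "+",
                          family = "L1-Ta", clip_seq = NULL,
                          sample = "T1") {
  l1 <- as.character(consensusSequence(l1Consensus(
    if (family == "L1PA2") "L1PA2" else "L1-Ta")))
  if (is.null(clip_seq)) {
    clip_seq <- if (clip_side == "right") substr(l1, 4000, 4049)
      else substr(l1, 5969, 6018)
    if (element_strand == "-") clip_seq <- revcomp(clip_seq)
  }
  te_side <- if ((clip_side == "right") == (element_strand == "+")) "5p"
    else "3p"
  data.frame(read_id = read_id, sample = sample, contig = "contig01",
             clip_side = clip_side, bp = as.integer(bp),
             clip_seq = clip_seq, element_strand = element_strand,
             te_side = te_side, family = family, cons_start = 4000L,
             cons_end = 4049L, identity = 1, aligned_len = 50L,
             clip_start = 1L, clip_end = 50L, genome_identity = 1,
             stringsAsFactors = FALSE)
}

test_that("clustering computes support, modal breakpoint and confidences", {
  # unanimity: one cluster, all confidences 1
  clips <- do.call(rbind, lapply(1:5, function(i)
    make_clip_row(paste0("r", i), 10000, "right")))
  cl <- clusterJunctions(clips)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_support, 5)
  expect_equal(cl$breakpoint, 10000)
  expect_equal(cl$strand_confidence, 1)
  expect_equal(cl$family_confidence, 1)
  expect_equal(cl$position_confidence, 1)
  expect_equal(cl$te_side, "5p")

  # a single supporting read never forms a cluster
  cl1 <- clusterJunctions(make_clip_row("solo", 500, "right"))
  expect_equal(nrow(cl1), 0)

  # 8 reads on the modal strand, 2 opposite: strand confidence 0.8
  clips2 <- rbind(
    do.call(rbind, lapply(1:8, function(i)
      make_clip_row(paste0("p", i), 20000, "right", "+"))),
    do.call(rbind, lapply(1:2, function(i)
      make_clip_row(paste0("m", i), 20000, "right", "-"))))
  cl2 <- clusterJunctions(clips2)
  expect_equal(nrow(cl2), 1)
  expect_equal(cl2$strand_confidence, 0.8)

  # breakpoints more than `window` apart split into separate clusters
  clips3 <- rbind(
    do.call(rbind, lapply(1:3, function(i)
      make_clip_row(paste0("a", i), 30000, "right"))),
    do.call(rbind, lapply(1:3, function(i)
      make_clip_row(paste0("b", i), 30050, "right"))))
  expect_equal(nrow(clusterJunctions(clips3)), 2)

  # duplicate read ids are counted once
  clips4 <- rbind(make_clip_row("dup", 40000, "right"),
                  make_clip_row("dup", 40000, "right"))
  expect_equal(nrow(clusterJunctions(clips4)), 0)
})

test_that("cluster filters label identity, location and consistency failures", {
  run <- mini_run()
  clusters <- clusterJunctions(run$res$clips)
  decoys <- run$ref$decoys
  filt <- filterClusters(clusters, run$imp$reference, decoys)

  # clusters at the true implants carry no labels
  tt <- run$truth
  true_bps <- c(tt$bpR_ref, tt$bpL_ref)
  at_truth <- vapply(filt$breakpoint, function(b)
    min(abs(true_bps - b)) <= 2, logical(1))
  expect_true(all(filt$filters[at_truth] == ""))

  # clusters inside decoy intervals are labelled te_overlap
  in_decoy <- GenomicRanges::countOverlaps(
    GenomicRanges::GRanges(filt$contig,
      IRanges::IRanges(filt$breakpoint, filt$breakpoint)), decoys) > 0
  if (any(in_decoy))
    expect_true(all(grepl("te_overlap", filt$filters[in_decoy])))

  # a cluster whose consensus clip matches the TE at 89 % over 40 nt
  # fails the identity rule
  l1 <- as.character(consensusSequence(l1Consensus("L1-Ta")))
  weak <- substr(l1, 4000, 4044)
  weak <- mutate_positions_test(weak, c(3, 9, 15, 21, 27))  # 5/45 = 11 %
  cl <- make_clip_row("w1", 99000, "right", clip_seq = weak)
  cl <- rbind(cl, make_clip_row("w2", 99000, "right", clip_seq = weak))
  wcl <- clusterJunctions(cl)
  if (nrow(wcl) == 1) {
    wf <- filterClusters(wcl, run$imp$reference, decoys)
    expect_true(grepl("low_te_identity|inconsistent", wf$filters))
  }

  expect_error(filterClusters(clusters, run$imp$reference, NULL),
               "te_annotation")
})

test_that("pairing arithmetic turns junction offsets into TSD or deletion", {
  run <- mini_run()
  ref <- run$imp$reference
  # overlap of 15 nt: TSD of 15
  cl <- rbind(make_cluster_row("contig01", 10000, "right", "+"),
              make_cluster_row("contig01", 9986, "left", "+"))
  calls <- pairAndAnnotate(cl, ref)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$tsd_len, 15)
  expect_equal(calls$deletion_len, 0)
  g <- as.character(ref)[[1]]
  expect_identical(calls$tsd_seq, substr(g, 9986, 10000))

  # gap of 550 nt: deletion of 550
  cl2 <- rbind(make_cluster_row("contig01", 10000, "right", "+"),
               make_cluster_row("contig01", 10551, "left", "+"))
  calls2 <- pairAndAnnotate(cl2, ref)
  expect_equal(calls2$deletion_len, 550)
  expect_equal(calls2$tsd_len, 0)

  # blunt junction: bp_left = bp_right + 1, no TSD, no deletion
  cl3 <- rbind(make_cluster_row("contig01", 10000, "right", "+"),
               make_cluster_row("contig01", 10001, "left", "+"))
  calls3 <- pairAndAnnotate(cl3, ref)
  expect_equal(calls3$tsd_len, 0)
  expect_equal(calls3$deletion_len, 0)

  # lone 5' cluster: single-ended call with zero annotation lengths
  calls4 <- pairAndAnnotate(make_cluster_row("contig01", 10000, "right", "+"),
                            ref)
  expect_equal(calls4$tsd_len, 0)
  expect_equal(calls4$deletion_len, 0)
  expect_true(grepl("single_end", calls4$filters))
  expect_true(is.na(calls4$bp_left))

  # opposite strands never pair
  cl5 <- rbind(make_cluster_row("contig01", 10000, "right", "+"),
               make_cluster_row("contig01", 10001, "left", "-"))
  calls5 <- pairAndAnnotate(cl5, ref)
  expect_equal(nrow(calls5), 2)
  expect_true(all(grepl("single_end", calls5$filters)))
})

test_that("per-sample support counts deduplicated junction reads", {
  run <- mini_run()
  ref <- run$imp$reference
  cl <- rbind(make_cluster_row("contig01", 10000, "right", "+"),
              make_cluster_row("contig01", 9986, "left", "+"))
  calls <- pairAndAnnotate(cl, ref)
  clips <- rbind(
    do.call(rbind, lapply(1:9, function(i)
      make_clip_row(paste0("t", i), 10000, "right", sample = "T1"))),
    do.call(rbind, lapply(1:3, function(i)        # duplicates of t1
      make_clip_row("t1", 10000, "right", sample = "T1"))),
    make_clip_row("n1", 9986, "left", sample = "N1"))
  counted <- countSupport(calls, clips, samples = c("T1", "N1", "B1"))
  expect_equal(counted$support.T1, 9)
  expect_equal(counted$support.N1, 1)
  expect_equal(counted$support.B1, 0)
})

test_that("VCF round-trips calls with 1-based positions", {
  run <- mini_run()
  ref <- run$imp$reference
  cl <- rbind(make_cluster_row("contig01", 9999, "right", "+"),
              make_cluster_row("contig01", 9986, "left", "+"))
  calls <- pairAndAnnotate(cl, ref)
  calls <- countSupport(calls, make_clip_row("x", 9999, "right"),
                        samples = c("T1"))
  path <- tempfile(fileext = ".vcf")
  writeInsertionVcf(calls, ref, path)
  back <- readInsertionVcf(path)
  expect_equal(back$pos, 9999)           # POS = last base before insertion
  expect_equal(back$bp_right, calls$bp_right)
  expect_equal(back$bp_left, calls$bp_left)
  expect_equal(back$tsd_len, calls$tsd_len)
  expect_equal(back$deletion_len, calls$deletion_len)
  expect_equal(back$polya_len, calls$polya_len)
  expect_equal(back$family, calls$family)
  expect_equal(back$microhomology, calls$microhomology)
  expect_equal(back$support.T1, calls$support.T1)
  ln <- readLines(path)
  expect_true(any(grepl("^##INFO=<ID=TSDLEN", ln)))
  expect_true(any(grepl("<INS:ME:LINE1>", ln)))

  # empty call set: a valid header-only VCF
  path2 <- tempfile(fileext = ".vcf")
  writeInsertionVcf(calls[0, ], ref, path2)
  ln2 <- readLines(path2)
  expect_true(all(startsWith(ln2, "#")))
  expect_null(readInsertionVcf(path2))
})
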