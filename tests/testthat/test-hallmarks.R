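# EN motif, TSD, poly-A, transduction detection and mechanism
# classification.

test_that("EN motif states follow the TT/AAAA Hamming rule", {
  ctx <- function(six) paste0(strrep("G", 12), six, strrep("G", 12))
  # cleavage right after the TT: position 14 in the padded context
  r1 <- enMotif(ctx("TTAAAA"), cleavage = 14, strand = "+")
  expect_equal(r1$state, "canonical")
  expect_equal(r1$site_seq, "TTAAAA")

  r2 <- enMotif(ctx("TTAAGA"), 14, "+")
  expect_equal(r2$state, "degenerate")   # Hamming distance 1

  r3 <- enMotif(ctx("GGCCGC"), 14, "+")
  expect_equal(r3$state, "absent")       # distance > 2

  # minus strand: the motif is read from the reverse complement
  r4 <- enMotif(ctx(revcomp("TTAAAA")), 16, "-")
  expect_equal(r4$state, "canonical")

  expect_error(enMotif("TTAAAA", 3, "+"), "10 nt")
})

test_that("TSD detection equals the brute-force duplication oracle", {
  set.seed(17)
  # planted duplications of known length
  for (k in c(4, 8, 15, 26)) {
    dup <- random_seq(k)
    left <- paste0(random_seq(50 - k), dup)
    right <- paste0(dup, random_seq(50 - k))
    d <- detectTsd(left, right)
    o <- dup_oracle(left, right)
    expect_equal(d$tsd_len, o)
    expect_identical(d$tsd_seq, substr(right, 1, o))
  }
  # random unrelated flanks: chance hits of up to 3 nt report 0
  zeros <- vapply(1:40, function(i) {
    d <- detectTsd(random_seq(50), random_seq(50))
    d$tsd_len == 0 || d$tsd_len >= 4
  }, logical(1))
  expect_true(all(zeros))
  # the no-duplication, large-deletion anatomy: zero
  l1 <- as.character(consensusSequence(l1Consensus("L1-Ta")))
  expect_equal(detectTsd(substr(l1, 100, 149), substr(l1, 2000, 2049))$tsd_len,
               dup_oracle(substr(l1, 100, 149), substr(l1, 2000, 2049)))
})

test_that("poly-A measurement honours purity, interruption and length rules", {
  el <- substr(as.character(consensusSequence(l1Consensus("L1-Ta"))),
               5969, 6018)
  # pure 40-A run at the element end
  p1 <- detectPolyA(paste0(el, strrep("A", 40)), element_end = 50)
  expect_equal(p1$polya_len, 40)

  # 8-A run: below the minimum reportable length
  p2 <- detectPolyA(paste0(el, strrep("A", 8), "GCGTAC"), element_end = 50)
  expect_equal(p2$polya_len, 0)

  # single short interruption is tolerated
  p3 <- detectPolyA(paste0(el, strrep("A", 20), "G", strrep("A", 20)),
                    element_end = 50)
  expect_equal(p3$polya_len, 41)

  # a long non-A run terminates the tail
  p4 <- detectPolyA(paste0(el, strrep("A", 25), "GGGG", strrep("A", 50)),
                    element_end = 50)
  expect_equal(p4$polya_len, 25)

  # the 102 nt anatomy is recovered exactly
  p5 <- detectPolyA(paste0(el, strrep("A", 102), "GTCGGC"), element_end = 50)
  expect_equal(p5$polya_len, 102)
})

test_that("transduced flanks are recovered with their source annotation", {
  alu <- as.character(consensusSequence(aluConsensus()))
  fl49 <- substr(alu, 80, 128)
  db <- Biostrings::DNAStringSet(c(donor9 = fl49))
  S4Vectors::mcols(db)$source <- "Alu"
  hit <- detectTransduction(fl49, db)
  expect_equal(nchar(hit$sequence), 49)
  expect_identical(hit$donor, "donor9")
  expect_identical(hit$source, "Alu")
  # a 37 nt segment of the registered flank still matches
  hit37 <- detectTransduction(substr(fl49, 1, 37), db)
  expect_equal(nchar(hit37$sequence), 37)
  # nothing beyond the consensus: no hit
  expect_null(detectTransduction("", db))
  expect_null(detectTransduction(random_seq(40), db))
})

test_that("mechanism classification applies its rules in order", {
  # TPRT-type: long tail, degenerate motif, no deletion
  expect_identical(classifyMechanism(102, 0, 0, "degenerate", "L1-Ta"),
                   "TPRT")
  # ENi-type: no hallmarks, 550 nt deletion
  expect_identical(classifyMechanism(0, 0, 550, "absent", "L1-Ta"), "ENi")
  # recombination-class: L1PA2 donor without a motif wins over ENi
  expect_identical(classifyMechanism(0, 0, 58, "absent", "L1PA2"),
                   "RECOMBINATION_CANDIDATE")
  # recombination via flank/target family match
  expect_identical(classifyMechanism(0, 0, 58, "absent", "L1-Ta",
                                     flank_family = "Alu",
                                     target_family = "Alu"),
                   "RECOMBINATION_CANDIDATE")
  # leftovers are ambiguous
  expect_identical(classifyMechanism(0, 12, 0, "canonical", "L1-Ta"),
                   "AMBIGUOUS")
  # pure function: identical inputs, identical outputs
  expect_identical(classifyMechanism(30, 12, 0, "canonical", "L1-Ta"),
                   classifyMechanism(30, 12, 0, "canonical", "L1-Ta"))
})

test_that("hallmark annotation recovers implant truth on synthetic calls", {
  fx <- archetypeFixtures()
  calls <- truthCalls(fx$implanted)
  hm <- annotateHallmarks(calls, fx$implanted$reference,
                          fx$implanted$donor_flanks, fx$te_annotation)
  got <- stats::setNames(hm$classification, hm$call_id)
  expect_identical(got[["mecp2_like"]], "RECOMBINATION_CANDIDATE")
  expect_identical(got[["egfr_like"]], "ENi")
  expect_identical(got[["cep112_like"]], "TPRT")
  cep <- hm[hm$call_id == "cep112_like", ]
  expect_equal(cep$polya_len, 102)
  expect_identical(cep$en_motif_state, "degenerate")
  mec <- hm[hm$call_id == "mecp2_like", ]
  expect_equal(mec$deletion_len, 58)
  expect_equal(mec$transduced_len, 37)
  expect_identical(mec$flank_family, "Alu")
  expect_identical(mec$target_family, "Alu")
  expect_equal(mec$hallmark_tsd_len, 0)
})
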