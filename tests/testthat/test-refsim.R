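# Synthetic-data simulator: reference construction, implantation mechanics,
# read simulation, bisulfite simulation.

test_that("reference generation is deterministic and honours its contract", {
  ref0 <- makeReference(1, 100000, 0.41, n_decoy_te = 0, seed = 7)
  expect_equal(sum(nchar(as.character(ref0$genome))), 100000)
  expect_length(ref0$decoys, 0)

  ref1 <- makeReference(1, 150000, 0.41, n_decoy_te = 3, seed = 7)
  ref2 <- makeReference(1, 150000, 0.41, n_decoy_te = 3, seed = 7)
  expect_identical(as.character(ref1$genome), as.character(ref2$genome))
  expect_length(ref1$decoys, 3)

  # each decoy is a (possibly truncated) 2-10 % mutated consensus copy:
  # positional identity against the source segment is >= 90 %
  g <- as.character(ref1$genome)[[1]]
  cons <- as.character(consensusSequence(l1Consensus("L1-Ta")))
  for (i in seq_along(ref1$decoys)) {
    d <- ref1$decoys[i]
    dseq <- substr(g, GenomicRanges::start(d), GenomicRanges::end(d))
    if (as.character(GenomicRanges::strand(d)) == "-") dseq <- revcomp(dseq)
    src <- substr(cons, d$trunc_start, nchar(cons))
    expect_equal(nchar(dseq), nchar(src))
    ident <- mean(utf8ToInt(dseq) == utf8ToInt(src))
    expect_gte(ident, 0.90)
  }
  expect_error(makeReference(1, 50000, 0.41, n_decoy_te = 2, seed = 1),
               "20x consensus")
})

test_that("implantation writes the specified junction anatomy", {
  ref <- makeReference(1, 150000, 0.41, n_decoy_te = 0, seed = 5)
  cons <- as.character(consensusSequence(l1Consensus("L1-Ta")))

  # TPRT: the TSD flanks the insertion identically on both sides
  tp <- implantTruth("t", "TPRT", "contig01", 50000, "+", 4000, 6018,
                     polya_len = 40, tsd_len = 15,
                     en_motif_state = "canonical")
  imp <- implantInsertions(ref, tp, seed = 2)
  mg <- as.character(imp$genome)[[1]]
  t1 <- imp$truth
  left_tsd <- substr(mg, t1$bpR_mut - 14, t1$bpR_mut)
  right_tsd <- substr(mg, t1$bpL_mut, t1$bpL_mut + 14)
  expect_identical(left_tsd, right_tsd)
  # canonical motif written around the cleavage point (TT before, AAAA after)
  rg <- as.character(imp$reference)[[1]]
  expect_identical(substr(rg, 49999, 50004), "TTAAAA")
  # implant round trip: the inserted segment is exactly consensus + tail
  ins <- substr(mg, t1$bpR_mut + 1, t1$bpL_mut - 1)
  expect_identical(ins, paste0(substr(cons, 4000, 6018), strrep("A", 40)))

  # ENi with deletion: mutated contig is shorter than a deletion-free
  # implant by exactly the deletion length
  en0 <- implantTruth("e0", "ENi", "contig01", 50000, "+", 5108, 6018,
                      deletion_len = 0, en_motif_state = "absent")
  en550 <- implantTruth("e1", "ENi", "contig01", 50000, "+", 5108, 6018,
                        deletion_len = 550, en_motif_state = "absent")
  g0 <- implantInsertions(ref, en0, seed = 2)
  g550 <- implantInsertions(ref, en550, seed = 2)
  expect_equal(nchar(as.character(g0$genome)[[1]]) -
                 nchar(as.character(g550$genome)[[1]]), 550)

  # recombination-class: inserted sequence ends with the Alu-derived flank
  # and carries no poly-A run
  alu <- as.character(consensusSequence(aluConsensus()))
  fl <- substr(alu, 100, 136)
  rec <- implantTruth("r", "RECOMBINATION", "contig01", 50000, "+",
                      5119, 6018, deletion_len = 58,
                      en_motif_state = "absent", transduced_flank = fl,
                      flank_source = "Alu", donor_family = "L1PA2")
  gr <- implantInsertions(ref, rec, seed = 2)
  tr <- gr$truth
  mgr <- as.character(gr$genome)[[1]]
  insr <- substr(mgr, tr$bpR_mut + 1, tr$bpL_mut - 1)
  expect_identical(substr(insr, nchar(insr) - 36, nchar(insr)), fl)
  expect_false(grepl("AAAAAAAAAA",
                     substr(insr, nchar(insr) - 60, nchar(insr))))

  # determinism and validation errors
  imp2 <- implantInsertions(ref, tp, seed = 2)
  expect_identical(as.character(imp$genome), as.character(imp2$genome))
  expect_error(implantTruth("x", "TPRT", "c", 1, "+", 1, 10, polya_len = 5,
                            tsd_len = 3, deletion_len = 4),
               "mutually exclusive")
  expect_error(implantInsertions(ref,
    implantTruth("x", "ENi", "contig01", 500, "+", 5108, 6018,
                 deletion_len = 10, en_motif_state = "absent"), seed = 1),
    "2 kb")
  expect_error(implantInsertions(ref,
    implantTruth("x", "ENi", "contig01", 50000, "+", 5108, 9999,
                 deletion_len = 10, en_motif_state = "absent"), seed = 1),
    "bounds")
})

test_that("read simulator meets its coverage, enrichment and error contracts", {
  ref <- makeReference(1, 100000, 0.41, n_decoy_te = 0, seed = 9)
  cfg <- ReadSimConfig(coverage = 50, error_rate = 0, seed = 3)
  rd <- simulateReads(ref$genome, NULL, cfg)
  total_bases <- sum(nchar(rd$r1)) + sum(nchar(rd$r2))
  expect_lt(abs(total_bases - 50 * 100000) / (50 * 100000), 0.10)

  # error-free reads are exact substrings of the genome or its complement
  g <- as.character(ref$genome)[[1]]
  grc <- revcomp(g)
  sub <- sample(seq_along(rd$r1), 150)
  ok <- vapply(rd$r1[sub], function(r)
    grepl(r, g, fixed = TRUE) || grepl(r, grc, fixed = TRUE), logical(1))
  expect_true(all(ok))

  # deterministic for a fixed seed
  rd2 <- simulateReads(ref$genome, NULL, cfg)
  expect_identical(rd$r1, rd2$r1)
  expect_error(simulateReads(Biostrings::DNAStringSet(), NULL, cfg),
               "empty genome")

  # probe enrichment: depth ratio inside/outside the probe lands near the
  # enrichment factor (fragment coordinates are encoded in read names)
  probe <- GenomicRanges::GRanges("contig01",
                                  IRanges::IRanges(40001, 42000))
  ratios <- vapply(c(21, 22), function(sd) {
    rdp <- simulateReads(ref$genome, probe,
      ReadSimConfig(coverage = 10, enrichment_factor = 20,
                    error_rate = 0, seed = sd))
    crd <- do.call(rbind, strsplit(names(rdp$r1), ":"))
    st <- as.integer(crd[, 3]); en <- as.integer(crd[, 4])
    inside <- sum(st <= 41000 & en >= 41000)
    outside <- sum(st <= 80000 & en >= 80000)
    inside / outside
  }, numeric(1))
  expect_true(all(ratios >= 10 & ratios <= 30))
})

test_that("bisulfite simulator reflects methylation and conversion settings", {
  cons <- l1Consensus("L1-Ta")
  ncpg <- length(islandCpGs(cons))
  expect_equal(ncpg, 19L)

  # full conversion, no methylation: no cytosine survives anywhere
  bs0 <- simulateBisulfiteReads(cons,
    BisulfiteSimConfig(0, conversion_efficiency = 1, n_read_pairs = 40,
                       seed = 1))
  expect_false(any(grepl("C", bs0$r1, fixed = TRUE)))
  expect_false(any(grepl("G", bs0$r2, fixed = TRUE)))

  # full methylation: every island CpG reads C in every molecule
  bs1 <- simulateBisulfiteReads(cons,
    BisulfiteSimConfig(1, conversion_efficiency = 1, n_read_pairs = 40,
                       seed = 2))
  cpg_rel <- bs1$cpg_positions  # amplicon starts at consensus position 1
  front <- cpg_rel[cpg_rel <= 250]
  for (p in front)
    expect_true(all(substr(bs1$r1, p, p) == "C"))

  # intermediate methylation recovers within binomial error at n = 10000
  bs3 <- simulateBisulfiteReads(cons,
    BisulfiteSimConfig(0.3, conversion_efficiency = 1,
                       n_read_pairs = 10000, seed = 3))
  fr <- vapply(front, function(p) mean(substr(bs3$r1, p, p) == "C"),
               numeric(1))
  expect_true(all(abs(fr - 0.3) <= 0.03))

  # probability vector length must match the island CpG count
  expect_error(simulateBisulfiteReads(cons,
    BisulfiteSimConfig(rep(0.5, 5), n_read_pairs = 2, seed = 1)),
    "does not match")
})
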