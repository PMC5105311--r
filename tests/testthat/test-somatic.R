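# Microhomology, tumour-specificity criteria, sensitivity metrics.

test_that("microhomology measures exact identity across the junction", {
  flank <- paste0(random_seq(46), "ACGT")
  te <- paste0("ACGT", random_seq(46))
  # guard against accidental extension in the random parts
  expect_equal(microhomology(flank, te, "5p"), dup_oracle(flank, te))
  expect_gte(microhomology(flank, te, "5p"), 4)

  # first base already differs: zero
  f2 <- paste0(random_seq(49), "A")
  t2 <- paste0("C", random_seq(49))
  expect_equal(microhomology(f2, t2, "5p"), dup_oracle(f2, t2))

  # 12 nt shared: returned in full (the criterion then rejects it)
  sh <- random_seq(12)
  f3 <- paste0(random_seq(38), sh)
  t3 <- paste0(sh, strrep("G", 38))
  mh <- microhomology(f3, t3, "5p")
  expect_gte(mh, 12)

  # 3' side: suffix of the element vs prefix of the genome flank
  te4 <- paste0(random_seq(40), "TTGCA")
  f4 <- paste0("TTGCA", random_seq(40))
  expect_equal(microhomology(f4, te4, "3p"), dup_oracle(te4, f4))

  expect_error(microhomology("ACGT", te, "5p"), ">= 20 nt")
})

test_that("tumour-specificity criteria follow the stated inequalities", {
  roles <- c(T1 = "tumour", T2 = "tumour", N1 = "normal", B1 = "blood")
  crit <- somaticCriteria()

  # 12 reads in one tumour, 1 elsewhere: specific (12 >= 8, 12 > 10 x 1)
  r <- isTumourSpecific(make_call_row(c(T1 = 12, T2 = 0, N1 = 0, B1 = 1)),
                        roles, crit)
  expect_true(r$tumour_specific)
  expect_identical(r$tumour_sample, "T1")

  # 12 vs 2: fails criterion i (12 <= 10 x 2)
  r2 <- isTumourSpecific(make_call_row(c(T1 = 12, T2 = 0, N1 = 2, B1 = 0)),
                         roles, crit)
  expect_false(r2$criteria[["i"]])

  # two tumour samples above the floor: not "only one tumour sample"
  r3 <- isTumourSpecific(make_call_row(c(T1 = 20, T2 = 9, N1 = 0, B1 = 0)),
                         roles, crit)
  expect_false(r3$criteria[["i"]])

  # known-database overlap fails criterion ii regardless of support
  db <- GenomicRanges::GRanges("contig01", IRanges::IRanges(9950, 10050))
  crit_db <- somaticCriteria(known_db = db)
  r4 <- isTumourSpecific(make_call_row(c(T1 = 50, T2 = 0, N1 = 0, B1 = 0)),
                         roles, crit_db)
  expect_false(r4$criteria[["ii"]])
  expect_false(r4$tumour_specific)

  # missing sample role is a configuration error
  expect_error(isTumourSpecific(make_call_row(c(T1 = 12, X9 = 0)),
                                roles, crit), "X9")
})

test_that("criterion i is monotone in the supports", {
  roles <- c(T1 = "tumour", N1 = "normal")
  crit <- somaticCriteria()
  set.seed(31)
  for (rep in 1:25) {
    t_sup <- sample(0:40, 1); n_sup <- sample(0:6, 1)
    base <- isTumourSpecific(
      make_call_row(c(T1 = t_sup, N1 = n_sup)), roles, crit)$criteria[["i"]]
    up_t <- isTumourSpecific(
      make_call_row(c(T1 = t_sup + sample(1:20, 1), N1 = n_sup)),
      roles, crit)$criteria[["i"]]
    up_n <- isTumourSpecific(
      make_call_row(c(T1 = t_sup, N1 = n_sup + sample(1:20, 1))),
      roles, crit)$criteria[["i"]]
    if (base) expect_true(up_t)       # more tumour reads never flips pass
    if (!base) expect_false(up_n)     # more normal reads never rescues
  }
})

test_that("sensitivity and junction coverage follow their definitions", {
  # synthetic alignment table: 3 cohort elements spanned by 10/20/30 reads
  mk <- function(n, jx, prefix) data.frame(
    read_id = sprintf("%s%03d", prefix, seq_len(n)), sample = "s",
    contig = "c1", start = jx - 75L, end = jx + 74L, strand = "+",
    clip_left = "", clip_right = "", genome_identity = 1, score = 150,
    mapq_proxy = 60L, fragment_key = sprintf("%s%03d", prefix, seq_len(n)),
    duplicate = FALSE, stringsAsFactors = FALSE)
  cohort <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(c(1000, 5000, 9000), c(3000, 7000, 11000)))
  aln <- rbind(mk(10, 1000, "a"), mk(20, 5000, "b"), mk(30, 9000, "c"))
  expect_equal(junctionCoverage(aln, cohort), 20)
  expect_equal(cohortSensitivity(aln, cohort, min_reads = 8), 1)
  expect_equal(cohortSensitivity(aln, cohort, min_reads = 15), 2 / 3)
  expect_equal(cohortSensitivity(aln[0, ], cohort, min_reads = 8), 0)
  # 9 of 10 detected at threshold: 0.9
  cohort10 <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(seq(1000, 91000, by = 10000),
                     seq(3000, 93000, by = 10000)))
  aln10 <- do.call(rbind, lapply(1:9, function(i)
    mk(8, 1000 + (i - 1) * 10000, paste0("e", i))))
  expect_equal(cohortSensitivity(aln10, cohort10, min_reads = 8), 0.9)
  expect_error(cohortSensitivity(aln, GenomicRanges::GRanges()), "non-empty")
})
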