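test_that("column calls follow quality-filtered strict majority", {
  expect_equal(call_column(c("A", "A", "G"), c(30, 30, 30)), "A")
  # no majority -> N
  expect_equal(call_column(c("A", "G"), c(30, 30)), "N")
  # low-quality votes are not counted: only the G remains
  expect_equal(call_column(c("A", "A", "G"), c(10, 10, 30)), "G")
  # nothing passes the filter -> N
  expect_equal(call_column(c("A", "A"), c(10, 10)), "N")
  # gaps vote like bases
  expect_equal(call_column(c("-", "-", "A"), c(30, 30, 30)), "-")
  expect_error(call_column(character(0), numeric(0)), "empty")
})

test_that("gap quality is the rank-weighted mean of the 8 nearest bases", {
  # constant neighbourhood -> that constant
  q <- c(30, 30, 30, 30, NA, 30, 30, 30, 30)
  expect_equal(gap_quality(q, 5), 30)
  # 40/30/20/10 nearest-to-farthest on each side: (4*40+3*30+2*20+1*10)/10
  q2 <- c(10, 20, 30, 40, NA, 40, 30, 20, 10)
  expect_equal(gap_quality(q2, 5), 30)
  # at a sequence end only one side contributes, same weights renormalised
  expect_equal(gap_quality(c(NA, 40, 30, 20, 10), 1), 30)
  # fewer than 4 neighbours on the only side
  expect_equal(gap_quality(c(NA, 40, 20), 1), (4 * 40 + 3 * 20) / 7)
  # no real base at all
  expect_equal(gap_quality(c(NA, NA), 1), 0)
  expect_error(gap_quality(c(40, NA), 1), "not a gap")
})

test_that("SSCS calling enforces the family-size threshold and drops gaps", {
  al <- align_family(c("ACGT", "ACGT", "ACGT"))
  expect_equal(call_sscs(al)$seq, "ACGT")
  expect_equal(call_sscs(al)$n_reads, 3L)
  expect_null(call_sscs(align_family(c("ACGT", "ACGT"))))

  # a gap in the minority is outvoted
  al2 <- list(seqs = c("ACGT", "A-GT", "ACGT"),
              quals = c("IIII", "I II", "IIII"))
  expect_equal(call_sscs(al2)$seq, "ACGT")
  # a gap in the majority removes the column
  al3 <- list(seqs = c("A-GT", "A-GT", "ACGT"),
              quals = c("I II", "I II", "IIII"))
  expect_equal(call_sscs(al3)$seq, "AGT")
})

test_that("IUPAC pairing covers agreement, ambiguity, gaps and N", {
  expect_equal(iupac_pair("A", "A"), "A")
  expect_equal(iupac_pair("A", "G"), "R")
  expect_equal(iupac_pair(c("C", "G", "A", "G"), c("T", "C", "T", "T")),
               c("Y", "S", "W", "K"))
  expect_equal(iupac_pair("A", "C"), "M")
  expect_equal(iupac_pair("A", "-"), "N")
  expect_equal(iupac_pair("N", "A"), "N")
  expect_error(iupac_pair("A", "Z"), "invalid")
  # symmetry over the whole alphabet
  chars <- c("A", "C", "G", "T", "N", "-")
  for (x in chars) for (y in chars) {
    expect_identical(iupac_pair(x, y), iupac_pair(y, x))
  }
})

test_that("duplex consensus reconciles agreement, mismatch and indels", {
  expect_equal(call_dcs("ACGT", "ACGT")$seq, "ACGT")
  expect_equal(call_dcs("ACGT", "ACAT")$seq, "ACRT")
  # a one-base deletion becomes N at the indel column
  expect_equal(call_dcs("ACGTACGTCAG", "ACGTAGTCAG")$seq, "ACGTANGTCAG")
  expect_null(call_dcs("", "ACGT"))
  expect_null(call_dcs(NULL, "ACGT"))
  d <- call_dcs("ACGT", "ACGT", n_ab = 5L, n_ba = 4L)
  expect_equal(d$n_ab, 5L)
  expect_equal(d$n_ba, 4L)
})

test_that("unpaired SSCS routing honours the three policies exactly", {
  sscs <- data.frame(barcode = "B", order = "AB", mate = 1L, seq = "ACGT",
                     n_reads = 3L)
  inc <- handle_unpaired_sscs(sscs, "include")
  expect_equal(nrow(inc$main), 1L)
  expect_equal(nrow(inc$separate), 0L)
  sep <- handle_unpaired_sscs(sscs, "separate")
  expect_equal(nrow(sep$main), 0L)
  expect_equal(nrow(sep$separate), 1L)
  dis <- handle_unpaired_sscs(sscs, "discard")
  expect_equal(nrow(dis$main) + nrow(dis$separate), 0L)
  expect_error(handle_unpaired_sscs(sscs, "shred"))
})

test_that("ambiguity trimming and removal behave on clean and dirty input", {
  expect_equal(trim_ambiguous("ACGT", "trim"), "ACGT")
  expect_equal(trim_ambiguous("ACGT", "remove"), "ACGT")
  expect_equal(trim_ambiguous("NNNNACGTACGT", "trim"), "ACGTACGT")
  expect_equal(trim_ambiguous("ACGTACGTNNNN", "trim"), "ACGTACGT")
  expect_true(is.na(trim_ambiguous("NNNNNN", "remove")))
  expect_equal(trim_ambiguous("NNNNNN", "trim"), "")
  # internal ambiguity below the window threshold survives trim mode
  expect_equal(trim_ambiguous("ACGTACGTNACGTACGT", "trim"),
               "ACGTACGTNACGTACGT")
  # removal threshold is a fraction of the whole sequence
  expect_equal(trim_ambiguous("ACGN", "remove", max_frac_n = 0.25), "ACGN")
  expect_true(is.na(trim_ambiguous("ACNN", "remove", max_frac_n = 0.25)))
})

test_that("raising the quality threshold never turns N into a base call", {
  set.seed(13)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    bases <- sample(c("A", "C", "G", "T", "-"), k, replace = TRUE)
    quals <- rep(30, k)
    lo <- call_column(bases, quals, qual_thresh = 10)
    hi <- call_column(bases, quals, qual_thresh = 30)
    if (lo == "N") expect_equal(hi, "N")
  }
})

test_that("SSCS equals an independent brute-force column tally", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(3:5, 1)
    len <- sample(4:12, 1)
    template <- random_dna(len)
    reads <- vapply(seq_len(n), function(j) {
      s <- template
      if (runif(1) < 0.6) {
        p <- sample(len, 1)
        substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      if (runif(1) < 0.25) s <- paste0(substr(s, 1, 2), substr(s, 4, len))
      s
    }, character(1))
    quals <- vapply(reads, function(s) {
      paste(sample(strsplit("!5I+", "")[[1]], nchar(s), TRUE), collapse = "")
    }, character(1))
    al <- align_family(reads, quals)
    got <- call_sscs(al, min_reads = 3L, qual_thresh = 20)$seq
    want <- oracle_consensus(al$seqs, quals, 20)
    expect_identical(got, want)
  }
})

test_that("identity end to end: families of identical reads give back the read", {
  for (k in c(3, 5, 9)) {
    reads <- rep("ACGTTGCAACGT", k)
    al <- align_family(reads)
    s <- call_sscs(al)
    expect_equal(s$seq, "ACGTTGCAACGT")
    d <- call_dcs(s$seq, s$seq)
    expect_equal(d$seq, "ACGTTGCAACGT")
  }
})
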