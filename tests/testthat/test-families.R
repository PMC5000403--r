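test_that("tag extraction splits tag, linker and payload", {
  pairs <- data.frame(
    name = "r1",
    seq1 = paste0(strrep("A", 12), "GGGGG", "ACGT"),
    qual1 = strrep("I", 21),
    seq2 = paste0(strrep("C", 12), "GGGGG", "TTTT"),
    qual2 = strrep("5", 21)
  )
  out <- extract_tags(pairs)
  expect_equal(out$n_rejected, 0L)
  expect_equal(out$pairs$alpha, strrep("A", 12))
  expect_equal(out$pairs$beta, strrep("C", 12))
  expect_equal(out$pairs$seq1, "ACGT")
  expect_equal(out$pairs$seq2, "TTTT")
  expect_equal(out$pairs$qual2, "5555")

  # invariant_len = 0 removes only the tags
  out0 <- extract_tags(pairs, invariant_len = 0L)
  expect_equal(out0$pairs$seq1, "GGGGGACGT")

  # a too-short mate rejects the pair
  pairs$seq2 <- strrep("C", 10)
  pairs$qual2 <- strrep("I", 10)
  expect_message(out <- extract_tags(pairs), "rejected")
  expect_equal(nrow(out$pairs), 0L)
  expect_equal(out$n_rejected, 1L)
})

test_that("canonical barcode is order-invariant with AB/BA bookkeeping", {
  a <- strrep("A", 12)
  c_ <- strrep("C", 12)
  fwd <- canonical_barcode(a, c_)
  rev <- canonical_barcode(c_, a)
  expect_equal(fwd$canonical, paste0(a, c_))
  expect_equal(rev$canonical, fwd$canonical)
  expect_equal(fwd$order, "AB")
  expect_equal(rev$order, "BA")
  # tie: equal tags define order AB
  tie <- canonical_barcode(a, a)
  expect_equal(tie$order, "AB")
  expect_equal(tie$canonical, strrep("A", 24))
  expect_error(canonical_barcode("ACGT", a), "12 bases")
  expect_error(canonical_barcode(strrep("X", 12), a), "A, C, G, T or N")
})

test_that("canonical barcode equals brute-force minimum over both orders", {
  set.seed(42)
  for (i in 1:200) {
    x <- random_dna(12)
    y <- random_dna(12)
    got <- canonical_barcode(x, y)$canonical
    both <- c(paste0(x, y), paste0(y, x))
    expect_identical(got, both[order(both)][1])
  }
})

test_that("grouping partitions pairs by barcode and strand, conserving reads", {
  pairs <- toy_pairs(1, n_ab = 2, n_ba = 1)
  tagged <- extract_tags(pairs)
  tbl <- build_family_table(tagged$pairs)
  fams <- group_families(tbl)
  expect_length(fams, 1L)
  expect_equal(nrow(fams[[1]]$ab), 4L)  # 2 pairs x 2 mates
  expect_equal(nrow(fams[[1]]$ba), 2L)

  # unrelated tags -> singleton families; reads conserved
  set.seed(7)
  pairs2 <- toy_pairs(2, n_ab = 1, n_ba = 0)
  tbl2 <- build_family_table(extract_tags(pairs2)$pairs)
  fams2 <- group_families(tbl2)
  expect_length(fams2, 2L)
  total <- sum(vapply(fams2, function(f) nrow(f$ab) + nrow(f$ba), numeric(1)))
  expect_equal(total, nrow(tbl2))
  # families come out in sorted barcode order
  expect_identical(names(fams2), sort(names(fams2), method = "radix"))
})

test_that("strand swap leaves canonical barcodes fixed and flips AB/BA", {
  set.seed(11)
  pairs <- toy_pairs(5, n_ab = 2, n_ba = 2)
  swapped <- data.frame(name = pairs$name, seq1 = pairs$seq2,
                        qual1 = pairs$qual2, seq2 = pairs$seq1,
                        qual2 = pairs$qual1)
  t1 <- extract_tags(pairs)$pairs
  t2 <- extract_tags(swapped)$pairs
  expect_identical(sort(t1$canonical), sort(t2$canonical))
  expect_identical(table(t1$order)[["AB"]], table(t2$order)[["BA"]])
  expect_identical(table(t1$order)[["BA"]], table(t2$order)[["AB"]])
})

test_that("census reproduces the ten-fragment hundred-pair bookkeeping", {
  set.seed(3)
  pairs <- toy_pairs(10, n_ab = 5, n_ba = 5)  # 10 fragments, 100 read pairs
  tbl <- build_family_table(extract_tags(pairs)$pairs)
  census <- family_census(tbl)
  v <- setNames(census$value, census$stat)
  expect_equal(v[["read_pairs"]], 100)
  expect_equal(v[["unique_tags"]], 10)       # ten duplex families
  expect_equal(v[["unique_duplex"]], 10)
  expect_equal(v[["unique_duplex_ge_k_both"]], 10)
  expect_equal(v[["read_pairs_in_duplex_ge_k"]], 100)
  expect_equal(v[["unique_tags_single"]], 0)

  # one lone AB pair: a single configuration, no duplex
  lone <- build_family_table(extract_tags(toy_pairs(1, 1, 0))$pairs)
  v1 <- with(family_census(lone), setNames(value, stat))
  expect_equal(v1[["unique_ab_single"]], 1)
  expect_equal(v1[["unique_duplex"]], 0)
})
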