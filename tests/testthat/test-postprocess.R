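test_that("minor allele frequency matches published count arithmetic", {
  expect_equal(maf(c(G = 1085, A = 14)), 14 / 1099)
  expect_equal(maf(c(G = 1132, A = 6)), 6 / 1138)
  expect_equal(maf(c(A = 50)), 0)
  expect_error(maf(c(A = 0, G = 0)), "zero depth")
  expect_error(maf(numeric(0)), "invalid")
  # biallelic MAF can never exceed one half
  set.seed(19)
  for (i in 1:50) {
    x <- sample(0:100, 2)
    if (sum(x) == 0) next
    expect_lte(maf(x), 0.5)
  }
})

test_that("strand bias is zero when balanced, grows with imbalance", {
  expect_equal(strand_bias(500, 500, 5, 5), 0)
  expect_equal(strand_bias(123, 123, 77, 77), 0)
  # proportionally balanced strands of different depths also score 0
  expect_equal(strand_bias(100, 200, 10, 20), 0)
  # all alternate reads on one strand
  one_sided <- strand_bias(100, 100, 10, 0)
  expect_gt(one_sided, strand_bias(100, 100, 5, 5))
  expect_gt(one_sided, 0)
  # symmetric under strand relabelling
  expect_equal(strand_bias(80, 120, 3, 9), strand_bias(120, 80, 9, 3))
  # no alternate reads at all: no evidence of bias
  expect_equal(strand_bias(100, 100, 0, 0), 0)
  # a strand with no coverage is undefined
  expect_true(is.na(strand_bias(0, 100, 0, 5)))
})

test_that("site summary picks major/minor alleles deterministically", {
  counts <- data.frame(
    chrom = "chr", pos = c(100, 100, 200, 300, 300, 300),
    allele = c("G", "A", "T", "C", "A", "G"),
    plus_count = c(540, 7, 10, 40, 3, 3),
    minus_count = c(545, 7, 12, 38, 3, 3)
  )
  ss <- site_stats(counts)
  s100 <- ss[ss$pos == 100, ]
  expect_equal(s100$depth, 1099)
  expect_equal(s100$major, "G")
  expect_equal(s100$minor, "A")
  expect_equal(s100$maf, 14 / 1099)
  # strand bias computed from the major/minor stranded counts
  expect_equal(s100$sb, strand_bias(540, 545, 7, 7))
  # monoallelic site
  expect_equal(ss[ss$pos == 200, ]$maf, 0)
  # tie between A and G minors -> alphabetical
  expect_equal(ss[ss$pos == 300, ]$minor, "A")
})

test_that("site filters apply MAF, strand bias and depth cuts", {
  sites <- data.frame(
    chrom = "chr",
    pos = c(1, 2, 3, 4, 5),
    depth = c(1099, 1000, 1000, 1000, 5),
    major = "G", minor = "A",
    maf = c(0.0128, 0.004, 0.02, 0.02, 0.4),
    sb = c(0.01, 0.1, 6.08, NA, 0.2)
  )
  suppressMessages({
    keep <- filter_sites(sites, maf_min = 0.005, sb_max = 1, depth_min = 10)
  })
  expect_equal(keep$pos, 1)
  expect_messages <- capture_messages(
    filter_sites(sites, maf_min = 0.005, sb_max = 1, depth_min = 10)
  )
  expect_match(expect_messages, "rejected", all = TRUE)
  expect_length(expect_messages, 4)
  # extreme thresholds pass or reject everything
  suppressMessages({
    expect_equal(nrow(filter_sites(sites, 0, Inf, 0)), 4)  # NA sb still fails
    expect_equal(nrow(filter_sites(sites, 1, 0, 1e9)), 0)
  })
})

test_that("stranded count tables roundtrip through the TSV reader", {
  d <- withr::local_tempdir()
  p <- file.path(d, "counts.tsv")
  counts <- data.frame(chrom = "chrM", pos = c(10L, 10L), allele = c("A", "G"),
                       plus_count = c(3L, 100L), minus_count = c(2L, 98L))
  write.table(counts, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_stranded_counts(p), counts)
})
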