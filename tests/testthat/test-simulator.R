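test_that("variant injection respects spacing and roundtrips", {
  set.seed(2)
  ref <- random_reference(16569)
  none <- mutate_reference(ref, n_sites = 0)
  expect_identical(none$seq, ref)

  res <- mutate_reference(ref, n_sites = 21, min_spacing = 600)
  pos <- res$variants$pos
  expect_length(pos, 21L)
  expect_true(all(diff(sort(pos)) >= 600))
  expect_true(min(pos) > 600 && max(pos) <= 16569 - 600)
  expect_true(all(res$variants$ref != res$variants$alt))
  # applying the truth records to the reference reproduces the mutant
  rebuilt <- ref
  for (i in seq_len(nrow(res$variants))) {
    substr(rebuilt, pos[i], pos[i]) <- res$variants$alt[i]
  }
  expect_identical(rebuilt, res$seq)

  expect_error(mutate_reference(random_reference(2000), 10, 600), "at most")
})

test_that("fragment sampling stays in bounds on both strands", {
  set.seed(4)
  ref <- random_reference(1000)
  one <- sample_fragments(ref, 1, 1000)
  expect_equal(one$start, 1L)
  expect_equal(one$end, 1000L)

  many <- sample_fragments(ref, 500, 600)
  expect_true(all(many$start >= 1 & many$end <= 1000))
  expect_true(all(many$end - many$start + 1 == 600))
  expect_true(all(c("+", "-") %in% many$strand))
  expect_equal(nrow(sample_fragments(ref, 0, 600)), 0L)
})

test_that("family sizes follow the distribution and honour exact singletons", {
  set.seed(6)
  d <- default_family_size_dist()
  expect_equal(sum(d$prob), 1)
  expect_equal(d$size[which.max(d$prob)], 9)  # mode at nine reads
  expect_equal(d$prob[1], 0.012)

  sizes <- sample_family_sizes(10000, d, exact_singleton_frac = 0.012)
  expect_equal(sum(sizes == 1), 120L)
  expect_equal(length(sizes), 10000L)
})

test_that("PCR trees have one leaf per read and 2^-cycle coalescence", {
  set.seed(9)
  for (s in c(1, 2, 3, 7, 12)) {
    tree <- build_pcr_tree(s, 30)
    expect_length(tree$leaves, s)
    expect_true(all(tree$daughter %in% 1:2))
    # every node traces back to a daughter
    expect_true(all(tree$parent[-(1:2)] != 0))
  }
  # with 2 reads and 3 cycles: P(shared ancestor at the last cycle) = 1/8,
  # P(at cycle 2) = (7/8)(1/4)
  merged_at <- replicate(4000, {
    tr <- build_pcr_tree(2, 3)
    p <- tr$parent[tr$leaves]
    if (p[1] == p[2] && p[1] > 2) tr$cycle[p[1]] else 0L
  })
  expect_equal(mean(merged_at == 2), 1 / 8, tolerance = 0.15)
  expect_equal(mean(merged_at == 1), 7 / 32, tolerance = 0.15)
})

test_that("error-free amplification copies the template exactly", {
  tree <- build_pcr_tree(5, 30)
  out <- apply_errors(tree, "ACGTACGT", error_rate = 0)
  expect_identical(out$seqs, rep("ACGTACGT", 5))
})

test_that("substitution counts match the per-base per-cycle rate", {
  set.seed(10)
  template <- random_reference(2000)
  # single leaf, 1 PCR cycle: daughter branch (1 round) + sequencing round
  fracs <- replicate(10, {
    tree <- build_pcr_tree(1, 1)
    leaf <- apply_errors(tree, template, error_rate = 0.1,
                         indel_frac = 0)$seqs
    mean(strsplit(leaf, "")[[1]] != strsplit(template, "")[[1]])
  })
  # two rounds at 0.1: P(changed) = 1 - (0.9^2 + 2*0.9*0.1/3... ) ~ 0.187
  expect_equal(mean(fracs), 0.1867, tolerance = 0.05)
})

test_that("mutations are inherited by all descendants of a branch", {
  set.seed(15)
  # two leaves sharing an internal ancestor at cycle 25 under daughter 1:
  # 25 cycles of shared branch, 5 private cycles each
  tree <- list(parent = c(0L, 0L, 5L, 5L, 1L), cycle = c(1L, 1L, 30L, 30L, 25L),
               leaves = 3:4, daughter = c(1L, 1L), n_nodes = 5L)
  tpl <- random_reference(600)
  out <- apply_errors(tree, tpl, error_rate = 0.005, indel_frac = 0)
  t_chars <- strsplit(tpl, "")[[1]]
  l1 <- strsplit(out$seqs[1], "")[[1]]
  l2 <- strsplit(out$seqs[2], "")[[1]]
  shared <- sum(l1 != t_chars & l1 == l2)
  # inherited changes dominate: far more shared differences than two
  # independent lineages could produce by coincidence
  expect_gt(shared, 30)
  indep <- replicate(3, {
    a <- apply_errors(list(parent = c(0L, 0L, 1L), cycle = c(1L, 1L, 30L),
                           leaves = 3L, daughter = 1L, n_nodes = 3L),
                      tpl, error_rate = 0.005, indel_frac = 0)$seqs
    b <- apply_errors(list(parent = c(0L, 0L, 1L), cycle = c(1L, 1L, 30L),
                           leaves = 3L, daughter = 1L, n_nodes = 3L),
                      tpl, error_rate = 0.005, indel_frac = 0)$seqs
    ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
    sum(ac != t_chars & ac == bc)
  })
  expect_lt(max(indep), 30)
})

test_that("read emission follows tag order and strand geometry", {
  alpha <- strrep("A", 12)
  beta <- strrep("C", 12)
  insert <- random_reference(50)
  molecule <- paste0(alpha, "TGACT", insert, revcomp("TGACT"), revcomp(beta))
  reads <- emit_reads(rep(molecule, 2), daughter = c(1L, 2L),
                      names = c("t", "b"), read_length = 40L)
  # daughter 1: mate 1 starts with the alpha tag
  expect_equal(substr(reads$seq1[1], 1, 12), alpha)
  expect_equal(substr(reads$seq2[1], 1, 12), beta)
  # daughter 2 reads the reverse complement: tags swap
  expect_equal(substr(reads$seq1[2], 1, 12), beta)
  expect_equal(substr(reads$seq2[2], 1, 12), alpha)
  # mate 2 payload is the reverse complement of the molecule 3' end
  expect_equal(reads$seq2[1], substr(revcomp(molecule), 1, 40))
  expect_equal(reads$qual1[1], strrep("I", 40))
})

test_that("a zero-error run yields one barcode per fragment and matches truth", {
  set.seed(23)
  ref <- random_reference(2000)
  cfg <- sim_config(fragment_length = 400L, read_length = 100L,
                    error_rate = 0)
  sim <- simulate_run(cfg, c(ref = ref), c(ref = 100), seed = 77)
  tagged <- extract_tags(sim$reads)$pairs
  expect_equal(length(unique(tagged$canonical)), 100L)
  expect_setequal(unique(tagged$canonical), sim$fragments$barcode)
  # per-family pair counts equal the drawn family sizes
  counts <- table(tagged$canonical)
  expect_equal(unname(sort(as.integer(counts))), sort(sim$fragments$size))
  expect_equal(sim$fragments$n_top + sim$fragments$n_bottom,
               sim$fragments$size)
  # census agrees with generator truth
  cns <- family_census(build_family_table(tagged))
  v <- setNames(cns$value, cns$stat)
  expect_equal(v[["read_pairs"]], sum(sim$fragments$size))
  expect_equal(v[["unique_tags"]], 100)
  expect_equal(v[["unique_tags_single"]], sum(sim$fragments$size == 1))
  expect_equal(v[["unique_duplex"]],
               sum(sim$fragments$n_top > 0 & sim$fragments$n_bottom > 0))
})

test_that("identical seeds reproduce a run byte for byte", {
  ref <- random_reference(1500)
  cfg <- sim_config(fragment_length = 300L, read_length = 80L)
  a <- simulate_run(cfg, c(ref = ref), c(ref = 30), seed = 5)
  b <- simulate_run(cfg, c(ref = ref), c(ref = 30), seed = 5)
  expect_identical(a$reads, b$reads)
  expect_identical(a$fragments, b$fragments)
  c <- simulate_run(cfg, c(ref = ref), c(ref = 30), seed = 6)
  expect_false(identical(a$reads, c$reads))
})

test_that("singleton fraction is zero when no fragment is a singleton", {
  set.seed(33)
  ref <- random_reference(1000)
  cfg <- sim_config(fragment_length = 300L, read_length = 80L,
                    error_rate = 0, exact_singleton_frac = 0)
  res <- singleton_fraction_experiment(0, ref, n_fragments = 150,
                                       config = cfg)
  expect_equal(res$singleton_fraction, 0)
  expect_equal(res$n_singletons, 0)
})
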