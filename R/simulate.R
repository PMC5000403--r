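# In silico duplex sequencing.
#
# Each simulated fragment is a stretch of reference sequence flanked by two
# random 12-base tags and a constant linker. Its family of reads descends
# from a PCR amplification tree built by backward coalescence: starting from
# the final reads at the last PCR cycle, lineages are randomly paired and
# merge with probability 2^-cycle at each cycle walking backwards, and
# whatever remains attaches to the two first-cycle daughter strands of the
# original molecule. Polymerase errors accumulate along every branch (per
# base, per spanned cycle) and one extra error round per leaf models the
# sequencing reaction; descendants inherit ancestral errors. Reads are
# emitted from both molecule ends with tag order alpha-beta or beta-alpha
# according to which daughter strand a leaf descends from, with fixed
# qualities. Ground truth (fragment origins, tags, sizes, injected variants)
# is returned alongside the reads.

#' Simulation configuration
#'
#' Defaults follow a standard in silico duplex experiment: 600-bp fragments,
#' 250-bp paired reads, 12-bp tags, a 5-bp linker, 30 PCR cycles, an error
#' probability of 0.001 per base per cycle of which 0.15 are indels with
#' extension probability 0.3, and fixed Phred 40 qualities. The linker
#' sequence itself is an arbitrary constant; only its length matters.
#'
#' @param fragment_length fragment (insert) length in bp.
#' @param read_length length of each emitted read in bp.
#' @param tag_len random tag length in bp.
#' @param linker constant linker sequence between tag and insert.
#' @param pcr_cycles number of simulated PCR cycles.
#' @param error_rate per-base, per-cycle error probability.
#' @param indel_frac fraction of errors that are indels (the rest are
#'   substitutions to a uniformly chosen different base).
#' @param indel_ext per-base extension probability of an indel (geometric
#'   length; insertion and deletion equiprobable).
#' @param fixed_phred Phred value assigned to every read base.
#' @param family_dist family-size distribution, see
#'   [default_family_size_dist()].
#' @param exact_singleton_frac if non-NULL, the realised family-size
#'   assignment is constrained to contain exactly
#'   `round(frac * n_fragments)` single-read fragments.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(fragment_length = 600L, read_length = 250L,
                       tag_len = 12L, linker = "TGACT", pcr_cycles = 30L,
                       error_rate = 0.001, indel_frac = 0.15,
                       indel_ext = 0.3, fixed_phred = 40L,
                       family_dist = default_family_size_dist(),
                       exact_singleton_frac = NULL) {
  stopifnot(error_rate >= 0, error_rate <= 1, indel_frac >= 0,
            indel_frac <= 1, indel_ext >= 0, indel_ext < 1,
            pcr_cycles >= 1, tag_len >= 1, fragment_length >= 1,
            read_length <= fragment_length + tag_len + nchar(linker))
  structure(list(fragment_length = as.integer(fragment_length),
                 read_length = as.integer(read_length),
                 tag_len = as.integer(tag_len), linker = toupper(linker),
                 pcr_cycles = as.integer(pcr_cycles),
                 error_rate = error_rate, indel_frac = indel_frac,
                 indel_ext = indel_ext, fixed_phred = as.integer(fixed_phred),
                 family_dist = family_dist,
                 exact_singleton_frac = exact_singleton_frac),
            class = "sim_config")
}

#' Family-size distribution with a mode at nine reads
#'
#' Discretised log-normal over sizes 1..`max_size`, parameterised so the
#' mode sits at `mode` reads, with the singleton mass pinned to an
#' explicit value (duplex experiments show a small natural fraction of
#' fragments that yield a single read pair).
#'
#' @param mode most likely family size.
#' @param singleton_mass probability that a fragment yields exactly one
#'   read pair.
#' @param sdlog log-scale spread of the distribution.
#' @param max_size largest family size with non-zero probability.
#' @return data.frame with columns `size` and `prob` (summing to 1).
#' @export
default_family_size_dist <- function(mode = 9, singleton_mass = 0.012,
                                     sdlog = 0.35, max_size = 40L) {
  sizes <- seq_len(max_size)
  meanlog <- log(mode) + sdlog^2  # log-normal mode = exp(meanlog - sdlog^2)
  p <- dlnorm(sizes, meanlog, sdlog)
  p[1] <- 0
  p <- p / sum(p) * (1 - singleton_mass)
  p[1] <- singleton_mass
  data.frame(size = sizes, prob = p)
}

#' Draw family sizes for a set of fragments
#'
#' @param n number of fragments.
#' @param dist family-size distribution (`size`, `prob`).
#' @param exact_singleton_frac if non-NULL, force the realised assignment to
#'   contain exactly `round(n * frac)` singletons; the remaining fragments
#'   draw from the distribution conditional on size >= 2.
#' @return integer vector of `n` family sizes.
#' @export
sample_family_sizes <- function(n, dist = default_family_size_dist(),
                                exact_singleton_frac = NULL) {
  if (n <= 0L) return(integer(0))
  draw <- function(d, k) {  # safe for length-1 supports
    d$size[sample.int(nrow(d), k, replace = TRUE, prob = d$prob)]
  }
  if (is.null(exact_singleton_frac)) {
    return(draw(dist, n))
  }
  n1 <- round(n * exact_singleton_frac)
  multi <- dist[dist$size >= 2L, ]
  sizes <- c(rep.int(1L, n1), draw(multi, n - n1))
  sample(sizes)  # shuffle so singletons are not clustered
}

#' Random reference sequence
#'
#' @param length sequence length in bp.
#' @return a single character string over A/C/G/T.
#' @export
random_reference <- function(length) {
  paste(sample(BASES, length, replace = TRUE), collapse = "")
}

#' Inject well-spaced substitution variants into a reference
#'
#' Places `n_sites` substitutions (to a uniformly chosen different base) at
#' positions at least `min_spacing` apart from each other and from the
#' sequence ends, sampling uniformly over all valid configurations.
#'
#' @param ref reference sequence (single character string).
#' @param n_sites number of variant sites.
#' @param min_spacing minimum pairwise and end distance in bp.
#' @return list with `seq` (the mutated reference) and `variants`
#'   (data.frame `pos`, `ref`, `alt`; 1-based positions).
#' @export
mutate_reference <- function(ref, n_sites = 21L, min_spacing = 600L) {
  L <- nchar(ref)
  if (n_sites == 0L) {
    return(list(seq = ref, variants = data.frame(pos = integer(),
                                                 ref = character(),
                                                 alt = character())))
  }
  s <- min_spacing
  lo <- s + 1L
  hi <- L - s - (n_sites - 1L) * (s - 1L)
  n_max <- if (L - 2L * s < 1L) 0L else (L - 2L * s - 1L) %/% s + 1L
  if (hi - lo + 1L < n_sites) {
    stop("cannot place ", n_sites, " sites with spacing ", s, " in ", L,
         " bp; at most ", n_max, " sites fit")
  }
  y <- sort(sample(seq.int(lo, hi), n_sites))
  pos <- y + (seq_len(n_sites) - 1L) * (s - 1L)
  ref_allele <- substring(ref, pos, pos)
  alt <- vapply(ref_allele, function(b) sample(setdiff(BASES, b), 1L),
                character(1))
  mut <- ref
  for (i in seq_len(n_sites)) substr(mut, pos[i], pos[i]) <- alt[i]
  list(seq = mut, variants = data.frame(pos = pos, ref = unname(ref_allele),
                                        alt = unname(alt)))
}

#' Sample fragment origins from a reference
#'
#' Start positions are uniform over the valid range and strands uniform;
#' coordinates are linear (a circular genome's textual representation is
#' not).
#'
#' @param ref reference sequence.
#' @param n number of fragments.
#' @param fragment_length fragment length in bp.
#' @return data.frame with 1-based `start`, `end` and `strand` (`"+"`/`"-"`).
#' @export
sample_fragments <- function(ref, n, fragment_length) {
  L <- nchar(ref)
  if (L < fragment_length) stop("reference shorter than fragment length")
  if (n <= 0L) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character()))
  }
  start <- sample.int(L - fragment_length + 1L, n, replace = TRUE)
  data.frame(start = start, end = start + fragment_length - 1L,
             strand = sample(c("+", "-"), n, replace = TRUE))
}

#' PCR amplification tree for one family
#'
#' Backward coalescent: the `family_size` final reads start as open lineages
#' at the last cycle; at each cycle `c`, walking backwards, the open
#' lineages are shuffled and successive disjoint pairs merge with
#' probability `2^-c`; every lineage still open after cycle 2 attaches to
#' one of the two first-cycle daughter strands of the original fragment
#' (chosen uniformly), so a family may descend entirely from one strand.
#'
#' @param family_size number of leaf reads.
#' @param pcr_cycles number of PCR cycles.
#' @return list with `parent` (0 for the two daughters), `cycle` (birth
#'   cycle per node), `leaves` (node ids), `daughter` (1 or 2 per leaf) and
#'   `n_nodes`. Nodes 1 and 2 are the daughter strands.
#' @export
build_pcr_tree <- function(family_size, pcr_cycles = 30L) {
  stopifnot(family_size >= 1L, pcr_cycles >= 1L)
  n_max <- 2L * family_size + 2L
  parent <- integer(n_max)
  cycle <- integer(n_max)
  cycle[1:2] <- 1L
  leaves <- seq.int(3L, 2L + family_size)
  cycle[leaves] <- pcr_cycles
  n_nodes <- 2L + family_size
  open <- leaves
  if (pcr_cycles >= 2L) {
    for (cyc in seq.int(pcr_cycles, 2L)) {
      if (length(open) < 2L) break
      open <- sample(open)
      p_merge <- 2^(-cyc)
      new_open <- integer(0)
      i <- 1L
      while (i + 1L <= length(open)) {
        if (runif(1) < p_merge) {
          n_nodes <- n_nodes + 1L
          parent[open[i]] <- n_nodes
          parent[open[i + 1L]] <- n_nodes
          cycle[n_nodes] <- cyc - 1L
          new_open <- c(new_open, n_nodes)
        } else {
          new_open <- c(new_open, open[i], open[i + 1L])
        }
        i <- i + 2L
      }
      if (i == length(open)) new_open <- c(new_open, open[i])
      open <- new_open
    }
  }
  parent[open] <- sample(c(1L, 2L), length(open), replace = TRUE)
  # strand of each leaf = which daughter it descends from
  anc <- integer(n_nodes)
  anc[1:2] <- 1:2
  ord <- order(cycle[seq_len(n_nodes)], seq_len(n_nodes))
  for (v in ord) {
    p <- parent[v]
    if (p > 0L) anc[v] <- anc[p]
  }
  list(parent = parent[seq_len(n_nodes)], cycle = cycle[seq_len(n_nodes)],
       leaves = leaves, daughter = anc[leaves], n_nodes = n_nodes)
}

# one round of error accumulation: each base suffers an error with
# probability `rate` per spanned cycle; errors are indels with probability
# `indel_frac` (geometric length, insertion/deletion equiprobable), else
# substitutions to a uniformly chosen different base
mutate_seq <- function(seq, n_cycles, rate, indel_frac, indel_ext) {
  if (rate == 0 || n_cycles == 0L) return(seq)
  len <- nchar(seq)
  if (len == 0L) return(seq)
  n_events <- rbinom(1L, len * n_cycles, rate)
  if (n_events == 0L) return(seq)
  is_indel <- runif(n_events) < indel_frac
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_sub <- sum(!is_indel)
  if (n_sub > 0L) {
    pos <- sample.int(length(chars), n_sub, replace = TRUE)
    idx <- match(chars[pos], BASES)
    idx[is.na(idx)] <- sample.int(4L, sum(is.na(idx)), replace = TRUE)
    shift <- sample.int(3L, n_sub, replace = TRUE)  # any of the 3 others
    chars[pos] <- BASES[(idx - 1L + shift) %% 4L + 1L]
  }
  for (i in seq_len(sum(is_indel))) {
    if (!length(chars)) break
    pos <- sample.int(length(chars), 1L)
    ilen <- 1L + rgeom(1L, 1 - indel_ext)
    if (runif(1) < 0.5) {
      chars <- append(chars, sample(BASES, ilen, replace = TRUE),
                      after = pos)
    } else {
      chars <- chars[-(pos:min(pos + ilen - 1L, length(chars)))]
    }
  }
  paste(chars, collapse = "")
}

#' Evolve a template molecule down a PCR tree
#'
#' Applies error accumulation along every branch of the tree (per base, per
#' spanned cycle; descendants inherit ancestral errors) plus one extra
#' error round per leaf for the sequencing reaction.
#'
#' @param tree a [build_pcr_tree()] result.
#' @param template the tagged molecule sequence at the root.
#' @param error_rate,indel_frac,indel_ext error model, see [sim_config()].
#' @return list with `seqs` (one per leaf) and `daughter` (strand of each
#'   leaf).
#' @export
apply_errors <- function(tree, template, error_rate = 0.001,
                         indel_frac = 0.15, indel_ext = 0.3) {
  if (error_rate == 0) {
    return(list(seqs = rep.int(template, length(tree$leaves)),
                daughter = tree$daughter))
  }
  n <- tree$n_nodes
  seqs <- character(n)
  ord <- order(tree$cycle[seq_len(n)], seq_len(n))
  for (v in ord) {
    p <- tree$parent[v]
    base <- if (p == 0L) template else seqs[p]
    span <- tree$cycle[v] - if (p == 0L) 0L else tree$cycle[p]
    seqs[v] <- mutate_seq(base, span, error_rate, indel_frac, indel_ext)
  }
  leaf_seqs <- vapply(seqs[tree$leaves], mutate_seq, character(1),
                      n_cycles = 1L, rate = error_rate,
                      indel_frac = indel_frac, indel_ext = indel_ext)
  list(seqs = unname(leaf_seqs), daughter = tree$daughter)
}

#' Emit paired reads from final molecule copies
#'
#' A molecule is laid out as tag + linker + insert + rc(linker) + rc(tag).
#' Leaves descending from daughter strand 1 read the molecule forward
#' (mate 1 starts with the alpha tag); leaves from daughter 2 read the
#' reverse complement (mate 1 starts with the beta tag). Each mate is the
#' first `read_length` bases of its strand (shorter if errors shortened the
#' molecule) with every base at `fixed_phred`.
#'
#' @param leaf_seqs character vector of final molecule sequences.
#' @param daughter integer vector (1 or 2) of strand origins.
#' @param names read names.
#' @param read_length read length in bp.
#' @param fixed_phred Phred value for all bases.
#' @return read-pair data.frame (`name`, `seq1`, `qual1`, `seq2`, `qual2`).
#' @export
emit_reads <- function(leaf_seqs, daughter, names, read_length = 250L,
                       fixed_phred = 40L) {
  rc <- revcomp(leaf_seqs)
  top <- daughter == 1L
  seq1 <- ifelse(top, leaf_seqs, rc)
  seq2 <- ifelse(top, rc, leaf_seqs)
  seq1 <- substr(seq1, 1L, read_length)
  seq2 <- substr(seq2, 1L, read_length)
  short <- nchar(seq1) < read_length | nchar(seq2) < read_length
  if (any(short)) {
    message(sum(short), " read(s) truncated: molecule shorter than ",
            read_length, " bases")
  }
  qc <- substr(phred_to_chars(fixed_phred), 1, 1)
  data.frame(name = names, seq1 = seq1, qual1 = strrep(qc, nchar(seq1)),
             seq2 = seq2, qual2 = strrep(qc, nchar(seq2)))
}

random_tags <- function(n, tag_len) {
  m <- matrix(sample(BASES, n * tag_len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m))
}

#' Simulate a full duplex sequencing run
#'
#' Composes fragment sampling, family sizes, PCR trees, error accumulation
#' and read emission over one or more (optionally mixed) reference
#' sequences, and returns reads plus per-fragment ground truth. Fully
#' reproducible for a given `seed`.
#'
#' @param config a [sim_config()].
#' @param refs named character vector of reference sequences (e.g.
#'   `c(ref = ..., mut = ...)`).
#' @param n_fragments named integer vector of fragment counts per reference.
#' @param seed optional integer seed.
#' @return list with `reads` (read-pair data.frame), `fragments`
#'   (data.frame: `frag`, `source`, `start`, `end`, `strand`, `alpha`,
#'   `beta`, `barcode`, `flipped`, `size`, `n_top`, `n_bottom`) and
#'   `config`. `flipped` records whether the canonical barcode reversed the
#'   physical tag order; `n_top`/`n_bottom` are reads per daughter strand.
#' @export
simulate_run <- function(config = sim_config(), refs, n_fragments,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(refs)) || !all(names(n_fragments) %in% names(refs))) {
    stop("refs and n_fragments must be named consistently")
  }
  frag_list <- lapply(names(n_fragments), function(src) {
    f <- sample_fragments(refs[[src]], n_fragments[[src]],
                          config$fragment_length)
    if (nrow(f)) f$source <- src
    f
  })
  frags <- do.call(rbind, frag_list)
  n <- nrow(frags)
  if (n == 0L) stop("no fragments to simulate")
  sizes <- sample_family_sizes(n, config$family_dist,
                               config$exact_singleton_frac)
  alpha <- random_tags(n, config$tag_len)
  beta <- random_tags(n, config$tag_len)
  inserts <- substring(refs[frags$source], frags$start, frags$end)
  neg <- frags$strand == "-"
  inserts[neg] <- revcomp(inserts[neg])
  molecules <- paste0(alpha, config$linker, inserts,
                      revcomp(config$linker), revcomp(beta))
  leaf_seqs <- vector("list", n)
  leaf_daughter <- vector("list", n)
  for (i in seq_len(n)) {
    tree <- build_pcr_tree(sizes[i], config$pcr_cycles)
    ev <- apply_errors(tree, molecules[i], config$error_rate,
                       config$indel_frac, config$indel_ext)
    leaf_seqs[[i]] <- ev$seqs
    leaf_daughter[[i]] <- ev$daughter
  }
  frag_of_leaf <- rep.int(seq_len(n), sizes)
  daughter <- unlist(leaf_daughter)
  read_names <- sprintf("frag%06d-%d", frag_of_leaf,
                        sequence(sizes))
  reads <- emit_reads(unlist(leaf_seqs), daughter, read_names,
                      config$read_length, config$fixed_phred)
  bc <- canonical_barcode(alpha, beta, tag_len = config$tag_len)
  fragments <- data.frame(
    frag = seq_len(n), source = frags$source, start = frags$start,
    end = frags$end, strand = frags$strand, alpha = alpha, beta = beta,
    barcode = bc$canonical, flipped = bc$order == "BA", size = sizes,
    n_top = tabulate(frag_of_leaf[daughter == 1L], nbins = n),
    n_bottom = tabulate(frag_of_leaf[daughter == 2L], nbins = n)
  )
  list(reads = reads, fragments = fragments, config = config)
}

#' Write a simulation to FASTQ + truth TSVs
#'
#' @param sim a [simulate_run()] result.
#' @param prefix output path prefix; writes `<prefix>_1.fastq`,
#'   `<prefix>_2.fastq` and `<prefix>_truth_fragments.tsv`.
#' @param variants optional variant truth data.frame (written as
#'   `<prefix>_truth_variants.tsv`).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, prefix, variants = NULL) {
  p1 <- paste0(prefix, "_1.fastq")
  p2 <- paste0(prefix, "_2.fastq")
  write_paired_fastq(sim$reads, p1, p2)
  pf <- paste0(prefix, "_truth_fragments.tsv")
  write.table(sim$fragments, pf, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(p1, p2, pf)
  if (!is.null(variants)) {
    pv <- paste0(prefix, "_truth_variants.tsv")
    write.table(variants, pv, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, pv)
  }
  invisible(paths)
}

#' Singleton-family fraction as a function of the error rate
#'
#' Runs one simulation per error rate (all other settings constant),
#' groups the output reads by canonical barcode and reports the fraction of
#' unique barcodes observed in exactly one read pair — the quantity that
#' serves as a proxy for the barcode error rate.
#'
#' @param error_rates numeric vector of per-base per-cycle error rates.
#' @param ref reference sequence.
#' @param n_fragments fragments per run.
#' @param config base [sim_config()]; its `error_rate` is overridden.
#' @param seed optional seed applied once before the grid.
#' @return data.frame with `error_rate`, `n_unique_barcodes`,
#'   `n_singletons`, `singleton_fraction`.
#' @export
singleton_fraction_experiment <- function(error_rates, ref,
                                          n_fragments = 10000L,
                                          config = sim_config(
                                            fragment_length = 400L,
                                            read_length = 100L),
                                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(error_rates, function(e) {
    cfg <- config
    cfg$error_rate <- e
    sim <- simulate_run(cfg, c(ref = ref), c(ref = n_fragments))
    tagged <- extract_tags(sim$reads, cfg$tag_len, nchar(cfg$linker))
    census <- family_census(build_family_table(tagged$pairs))
    n_tags <- census$value[census$stat == "unique_tags"]
    n_single <- census$value[census$stat == "unique_tags_single"]
    data.frame(error_rate = e, n_unique_barcodes = n_tags,
               n_singletons = n_single,
               singleton_fraction = n_single / n_tags)
  })
  do.call(rbind, rows)
}
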