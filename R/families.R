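# Grouping of barcoded read pairs into strand-specific families.
#
# Each mate of a duplex read pair starts with a 12-base random tag followed
# by a constant linker. The mate-1 tag (alpha) and mate-2 tag (beta) are
# concatenated in lexicographically normalised order into a 24-base
# "canonical barcode" that is identical for the two strands of one fragment;
# the original tag order (AB or BA) records which strand a pair came from.
# Grouping is by exact barcode match: tags containing N simply form their own
# families, and no mismatch tolerance is attempted.

#' Canonical barcode from a pair of duplex tags
#'
#' Concatenates the two tags in lexicographically normalised order (plain
#' bytewise string comparison), so that `canonical_barcode(a, b)` and
#' `canonical_barcode(b, a)` give the same barcode. When `alpha <= beta` the
#' order is `"AB"`, otherwise `"BA"`; equal tags are defined as `"AB"`.
#'
#' @param alpha,beta character vectors of tags over A/C/G/T/N.
#' @param tag_len required tag length (default 12).
#' @return data.frame with columns `canonical` and `order`.
#' @export
canonical_barcode <- function(alpha, beta, tag_len = 12L) {
  if (length(alpha) != length(beta)) stop("alpha and beta differ in length")
  if (any(nchar(alpha) != tag_len) || any(nchar(beta) != tag_len)) {
    stop("tags must all be exactly ", tag_len, " bases long")
  }
  if (any(grepl("[^ACGTN]", c(alpha, beta)))) {
    stop("tags may only contain A, C, G, T or N")
  }
  ab <- cpp_str_leq(alpha, beta)
  data.frame(
    canonical = ifelse(ab, paste0(alpha, beta), paste0(beta, alpha)),
    order = ifelse(ab, "AB", "BA")
  )
}

#' Extract duplex tags and trim tag + linker from a read-pair table
#'
#' Takes the first `tag_len` bases of each mate as the alpha (mate 1) and
#' beta (mate 2) tags and removes the tag and the following `invariant_len`
#' linker bases, together with their qualities, from both mates. Pairs in
#' which either mate is shorter than `tag_len + invariant_len + 1` (i.e.
#' leaves no payload) are rejected, counted and reported via a message.
#'
#' @param pairs data.frame from [read_paired_fastq()].
#' @param tag_len random tag length in bases.
#' @param invariant_len constant linker length in bases.
#' @return list with `pairs` (data.frame: `name`, `alpha`, `beta`,
#'   `canonical`, `order`, trimmed `seq1`, `qual1`, `seq2`, `qual2`) and
#'   `n_rejected`.
#' @export
extract_tags <- function(pairs, tag_len = 12L, invariant_len = 5L) {
  min_len <- tag_len + invariant_len + 1L
  ok <- nchar(pairs$seq1) >= min_len & nchar(pairs$seq2) >= min_len
  n_rejected <- sum(!ok)
  if (n_rejected > 0L) {
    message(n_rejected, " read pair(s) shorter than tag + linker rejected")
    pairs <- pairs[ok, , drop = FALSE]
  }
  alpha <- substr(pairs$seq1, 1L, tag_len)
  beta <- substr(pairs$seq2, 1L, tag_len)
  bc <- canonical_barcode(alpha, beta, tag_len = tag_len)
  off <- tag_len + invariant_len + 1L
  out <- data.frame(
    name = pairs$name, alpha = alpha, beta = beta,
    canonical = bc$canonical, order = bc$order,
    seq1 = substr(pairs$seq1, off, nchar(pairs$seq1)),
    qual1 = substr(pairs$qual1, off, nchar(pairs$qual1)),
    seq2 = substr(pairs$seq2, off, nchar(pairs$seq2)),
    qual2 = substr(pairs$qual2, off, nchar(pairs$qual2))
  )
  list(pairs = out, n_rejected = n_rejected)
}

#' Build the six-column family table from tagged pairs
#'
#' Emits one row per mate per read pair and sorts by
#' (barcode, order, mate, name) in C locale, the grouped order the rest of
#' the pipeline expects.
#'
#' @param tagged data.frame as in the `pairs` element of [extract_tags()].
#' @return data.frame with the family-table columns.
#' @export
build_family_table <- function(tagged) {
  tbl <- data.frame(
    barcode = rep(tagged$canonical, 2L),
    order = rep(tagged$order, 2L),
    mate = rep(c(1L, 2L), each = nrow(tagged)),
    name = rep(tagged$name, 2L),
    seq = c(tagged$seq1, tagged$seq2),
    qual = c(tagged$qual1, tagged$qual2)
  )
  sort_family_table(tbl)
}

#' @rdname build_family_table
#' @param tbl a family table.
#' @export
sort_family_table <- function(tbl) {
  dt <- data.table::as.data.table(tbl)
  data.table::setorder(dt, barcode, order, mate, name)  # data.table: C locale
  as.data.frame(dt)
}

#' Group a family table into read families
#'
#' Returns one family per canonical barcode, in sorted barcode order, with
#' member pairs partitioned by tag order. Purely a regrouping: the total
#' number of reads out equals the number in.
#'
#' @param tbl family table (any row order).
#' @return named list of families; each family is a list with `barcode`,
#'   `ab` and `ba` (data.frames with columns `mate`, `name`, `seq`, `qual`).
#' @export
group_families <- function(tbl) {
  tbl <- sort_family_table(tbl)
  rows <- split(tbl, factor(tbl$barcode, levels = unique(tbl$barcode)))
  lapply(rows, function(fam) {
    list(
      barcode = fam$barcode[1],
      ab = fam[fam$order == "AB", c("mate", "name", "seq", "qual")],
      ba = fam[fam$order == "BA", c("mate", "name", "seq", "qual")]
    )
  })
}

#' Tally family structure of a duplex experiment
#'
#' Counts read pairs, distinct canonical barcodes, strand configurations
#' (alpha-beta and beta-alpha, split by single-pair and >= k pairs), duplex
#' families (both strands observed), duplex families with at least `k` read
#' pairs on both strands, and the read pairs inside them.
#'
#' @param tbl family table.
#' @param k family-size threshold used for the ">= k" rows (default 3, the
#'   consensus threshold).
#' @return two-column data.frame (`stat`, `value`).
#' @export
family_census <- function(tbl, k = 3L) {
  dt <- data.table::as.data.table(tbl)[mate == 1L]
  cfg <- dt[, .(n_pairs = .N), by = .(barcode, order)]
  fam <- cfg[, .(n_ab = sum(n_pairs[order == "AB"]),
                 n_ba = sum(n_pairs[order == "BA"])), by = barcode]
  stats <- c(
    read_pairs = nrow(dt),
    unique_tags = nrow(fam),
    unique_tags_single = sum(fam$n_ab + fam$n_ba == 1L),
    unique_ab = sum(cfg$order == "AB"),
    unique_ab_single = sum(cfg$order == "AB" & cfg$n_pairs == 1L),
    unique_ab_ge_k = sum(cfg$order == "AB" & cfg$n_pairs >= k),
    unique_ba = sum(cfg$order == "BA"),
    unique_ba_single = sum(cfg$order == "BA" & cfg$n_pairs == 1L),
    unique_ba_ge_k = sum(cfg$order == "BA" & cfg$n_pairs >= k),
    unique_duplex = sum(fam$n_ab > 0L & fam$n_ba > 0L),
    unique_duplex_ge_k_both = sum(fam$n_ab >= k & fam$n_ba >= k),
    read_pairs_in_duplex_ge_k = sum((fam$n_ab + fam$n_ba)[fam$n_ab >= k &
                                                            fam$n_ba >= k])
  )
  data.frame(stat = names(stats), value = unname(stats))
}
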