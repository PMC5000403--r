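# Consensus calling: single-stranded consensus sequences (SSCS) from aligned
# families, duplex consensus sequences (DCS) from pairs of SSCSs, and
# trimming/removal of ambiguous consensus output.
#
# A column's consensus is the character (gaps vote like bases) holding a
# strict majority of the votes that pass the quality threshold; without a
# majority the call is N. A gap has no quality of its own, so it competes
# with a score derived from its row's eight nearest real bases (up to four
# per side), weighted linearly by rank distance (4, 3, 2, 1) and renormalised
# near sequence ends.

#' Consensus call for one alignment column
#'
#' Reference (plain R) implementation of the per-column vote; the family
#' pipeline uses an equivalent compiled kernel.
#'
#' @param bases character vector of column characters, `"-"` for gaps.
#' @param quals numeric Phred scores, one per base; for a gap supply its
#'   computed [gap_quality()].
#' @param qual_thresh characters with quality below this are not counted.
#' @return single character: the majority character or `"N"`.
#' @export
call_column <- function(bases, quals, qual_thresh = 20) {
  if (!length(bases)) stop("empty column")
  if (length(quals) != length(bases)) stop("bases/quals length mismatch")
  counted <- bases[!is.na(quals) & quals >= qual_thresh]
  if (!length(counted)) return("N")
  tab <- table(counted)
  top <- which(tab * 2 > length(counted))
  if (!length(top)) return("N")
  names(tab)[top[1]]
}

#' Quality score standing in for a gap position
#'
#' Weighted mean of the Phred scores of the up-to-eight nearest real bases of
#' the row (up to four on each side of the gap), with weight `5 - d` where
#' `d` is the rank distance (1 = nearest) on that side. Near sequence ends
#' fewer neighbours contribute and the weights are renormalised. A row with
#' no real base scores 0.
#'
#' @param quals numeric vector of the row's Phred scores in alignment
#'   coordinates, `NA` at gap positions.
#' @param position column index of the gap (1-based).
#' @return numeric Phred-scale quality.
#' @export
gap_quality <- function(quals, position) {
  if (position < 1L || position > length(quals)) stop("position out of range")
  if (!is.na(quals[position])) stop("position is not a gap")
  real <- which(!is.na(quals))
  if (!length(real)) return(0)
  left <- rev(real[real < position])[1:4]
  right <- real[real > position][1:4]
  w <- c(4, 3, 2, 1)
  use_l <- !is.na(left)
  use_r <- !is.na(right)
  num <- sum(w[use_l] * quals[left[use_l]]) + sum(w[use_r] * quals[right[use_r]])
  den <- sum(w[use_l]) + sum(w[use_r])
  num / den
}

#' Single-stranded consensus from an aligned family
#'
#' Applies the per-column majority call over all rows of one strand family
#' (one mate), then removes the columns whose consensus is a gap. Families
#' smaller than `min_reads` produce no consensus.
#'
#' @param aligned list with gapped `seqs` and `quals` as returned by
#'   [align_family()].
#' @param min_reads minimum family size required to call a consensus.
#' @param qual_thresh Phred threshold below which bases are not counted.
#' @return list with `seq` and `n_reads`, or `NULL` when the family is too
#'   small.
#' @export
call_sscs <- function(aligned, min_reads = 3L, qual_thresh = 20) {
  n <- length(aligned$seqs)
  if (n < min_reads) return(NULL)
  cons <- cpp_consensus(aligned$seqs, aligned$quals, qual_thresh, 33L)
  list(seq = gsub("-", "", cons, fixed = TRUE), n_reads = n)
}

IUPAC2 <- c(AA = "A", CC = "C", GG = "G", TT = "T",
            AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' IUPAC reconciliation of one pair of consensus characters
#'
#' Equal bases give that base; two distinct bases give the two-base IUPAC
#' ambiguity code; any pairing involving a gap and a base, or involving `N`,
#' gives `N`.
#'
#' @param b1,b2 character vectors over A/C/G/T/N/-.
#' @return character vector of reconciled calls.
#' @export
iupac_pair <- function(b1, b2) {
  ok <- c("A", "C", "G", "T", "N", "-")
  if (!all(b1 %in% ok) || !all(b2 %in% ok)) {
    stop("invalid consensus character; expected A/C/G/T/N/-")
  }
  key <- paste0(pmin(b1, b2), pmax(b1, b2))
  out <- unname(IUPAC2[key])
  out[is.na(out)] <- "N"  # anything with N or a gap/base conflict
  out[b1 == "-" & b2 == "-"] <- "-"
  out
}

#' Duplex consensus from the two strand consensi of a fragment
#'
#' The two SSCSs are aligned with [smith_waterman()] and each aligned column
#' is reconciled with [iupac_pair()]; columns outside the local alignment are
#' excluded. When the aligned region is much shorter than either input
#' (wildly different SSCS lengths) the truncation is reported via a message.
#'
#' @param sscs_ab,sscs_ba the two strand consensus sequences.
#' @param n_ab,n_ba family sizes recorded with the output.
#' @param match,mismatch,gap_open,gap_extend passed to [smith_waterman()].
#' @return list with `seq`, `n_ab`, `n_ba`, or `NULL` when either input is
#'   empty or the strands share no positive-scoring local alignment.
#' @export
call_dcs <- function(sscs_ab, sscs_ba, n_ab = NA_integer_, n_ba = NA_integer_,
                     match = 1, mismatch = -1, gap_open = -2,
                     gap_extend = -1) {
  if (is.null(sscs_ab) || is.null(sscs_ba) ||
      !nzchar(sscs_ab) || !nzchar(sscs_ba)) {
    return(NULL)
  }
  al <- smith_waterman(sscs_ab, sscs_ba, match, mismatch, gap_open, gap_extend)
  if (!nzchar(al$aligned_a)) return(NULL)
  if (al$a_end - al$a_start + 1L < 0.5 * min(nchar(sscs_ab), nchar(sscs_ba))) {
    message("duplex reconciliation truncated to ", nchar(al$aligned_a),
            " aligned columns (inputs ", nchar(sscs_ab), " and ",
            nchar(sscs_ba), " bases)")
  }
  a <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]]
  b <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]]
  seq <- paste(iupac_pair(a, b), collapse = "")
  list(seq = gsub("-", "", seq, fixed = TRUE), n_ab = n_ab, n_ba = n_ba)
}

#' Route single-stranded consensi that have no opposite-strand partner
#'
#' @param sscs data.frame of unpaired SSCS records.
#' @param policy `"include"` (return them for the main output, flagged
#'   single-stranded), `"separate"` (return them for a separate SSCS file)
#'   or `"discard"`.
#' @return list with `main` and `separate` data.frames.
#' @export
handle_unpaired_sscs <- function(sscs,
                                 policy = c("separate", "include", "discard")) {
  policy <- match.arg(policy)
  none <- sscs[0, , drop = FALSE]
  switch(policy,
    include = list(main = sscs, separate = none),
    separate = list(main = none, separate = sscs),
    discard = list(main = none, separate = none)
  )
}

#' Trim or remove consensus sequences with ambiguous characters
#'
#' In `"trim"` mode, bases are removed from each end while the terminal base
#' is not A/C/G/T or the fraction of non-A/C/G/T characters in the terminal
#' window exceeds `max_frac_n`. In `"remove"` mode the whole sequence is
#' dropped (returned as `NA`) when its overall non-A/C/G/T fraction exceeds
#' `max_frac_n`.
#'
#' @param seq character vector of sequences.
#' @param mode `"trim"` or `"remove"`.
#' @param max_frac_n maximum tolerated fraction of ambiguous characters.
#' @param window window length used in trim mode.
#' @return character vector; trimmed sequences (possibly `""`) or
#'   `NA_character_` for removed ones.
#' @export
trim_ambiguous <- function(seq, mode = c("trim", "remove"), max_frac_n = 0.3,
                           window = 10L) {
  mode <- match.arg(mode)
  frac_ambig <- function(s) {
    if (!nzchar(s)) return(0)
    nchar(gsub("[ACGT]", "", s)) / nchar(s)
  }
  if (mode == "remove") {
    drop <- vapply(seq, frac_ambig, numeric(1)) > max_frac_n
    seq[drop] <- NA_character_
    return(unname(seq))
  }
  trim_one <- function(s) {
    repeat {
      n <- nchar(s)
      if (n == 0L) return(s)
      head_win <- substr(s, 1L, min(window, n))
      if (!substr(s, 1L, 1L) %in% BASES || frac_ambig(head_win) > max_frac_n) {
        s <- substr(s, 2L, n)
        next
      }
      tail_win <- substr(s, max(1L, n - window + 1L), n)
      if (!substr(s, n, n) %in% BASES || frac_ambig(tail_win) > max_frac_n) {
        s <- substr(s, 1L, n - 1L)
        next
      }
      return(s)
    }
  }
  unname(vapply(seq, trim_one, character(1)))
}

#' Call all consensus sequences from a family table
#'
#' Groups the table by (canonical barcode, tag order, mate), aligns each
#' group of at least `min_reads` reads, calls its SSCS, and reconciles
#' opposite-strand SSCSs into DCSs. Opposite tag order means opposite
#' physical strand, so mates swap when pairing: the AB-family mate-1
#' consensus is reconciled with the BA-family mate-2 consensus (both read
#' the same fragment end) and vice versa. The DCS `mate` is the AB family's
#' mate.
#'
#' @param tbl family table (see [build_family_table()]).
#' @param min_reads per-strand family-size threshold; a duplex consensus
#'   requires both strands to pass it.
#' @param qual_thresh Phred threshold for the per-column vote.
#' @param backend,match,mismatch,gap_open,gap_extend see [align_family()].
#' @param prealigned set to `TRUE` when `tbl$seq` already holds gapped
#'   alignment rows (e.g. an align-families output); the within-family
#'   alignment step is then skipped and `tbl$qual` is threaded onto the
#'   gapped rows.
#' @return list with data.frames `sscs` (`barcode`, `order`, `mate`, `seq`,
#'   `n_reads`), `dcs` (`barcode`, `mate`, `seq`, `n_ab`, `n_ba`) and
#'   `unpaired` (SSCS rows without an opposite-strand partner).
#' @export
call_consensi <- function(tbl, min_reads = 3L, qual_thresh = 20,
                          backend = "builtin", match = 1, mismatch = -1,
                          gap_open = -2, gap_extend = -1,
                          prealigned = FALSE) {
  dt <- data.table::as.data.table(tbl)
  dt <- dt[, if (.N >= min_reads) .SD, by = .(barcode, order, mate)]
  empty_sscs <- data.frame(barcode = character(), order = character(),
                           mate = integer(), seq = character(),
                           n_reads = integer())
  if (!nrow(dt)) {
    return(list(sscs = empty_sscs, dcs = empty_dcs(), unpaired = empty_sscs))
  }
  sscs <- dt[, {
    if (prealigned) {
      rows <- seq
      gq <- thread_gap_quals(rows, qual)
    } else {
      al <- align_family(seq, qual, backend = backend, match = match,
                         mismatch = mismatch, gap_open = gap_open,
                         gap_extend = gap_extend)
      rows <- al$seqs
      gq <- al$quals
    }
    cons <- cpp_consensus(rows, gq, qual_thresh, 33L)
    .(seq = gsub("-", "", cons, fixed = TRUE), n_reads = .N)
  }, by = .(barcode, order, mate)]

  ab <- sscs[order == "AB"]
  ba <- sscs[order == "BA"][, mate := 3L - mate]  # partner covers same end
  both <- merge(ab, ba, by = c("barcode", "mate"), suffixes = c("_ab", "_ba"))
  dcs_rows <- vector("list", nrow(both))
  for (i in seq_len(nrow(both))) {
    d <- call_dcs(both$seq_ab[i], both$seq_ba[i], both$n_reads_ab[i],
                  both$n_reads_ba[i], match, mismatch, gap_open, gap_extend)
    if (!is.null(d)) {
      dcs_rows[[i]] <- data.frame(barcode = both$barcode[i],
                                  mate = both$mate[i], seq = d$seq,
                                  n_ab = d$n_ab, n_ba = d$n_ba)
    }
  }
  dcs_rows <- dcs_rows[!vapply(dcs_rows, is.null, logical(1))]
  dcs <- if (length(dcs_rows)) do.call(rbind, dcs_rows) else empty_dcs()
  paired_key <- paste(both$barcode, both$mate)
  ab_unpaired <- ab[!paste(ab$barcode, ab$mate) %in% paired_key]
  ba_unpaired <- sscs[order == "BA"][!paste(barcode, 3L - mate) %in% paired_key]
  unpaired <- as.data.frame(rbind(ab_unpaired, ba_unpaired))
  list(sscs = as.data.frame(sscs), dcs = dcs, unpaired = unpaired)
}

empty_dcs <- function() {
  data.frame(barcode = character(), mate = integer(), seq = character(),
             n_ab = integer(), n_ba = integer())
}
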