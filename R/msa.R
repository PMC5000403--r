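# Within-family multiple alignment and the pairwise local aligner used to
# reconcile the two strand consensi of a fragment.
#
# The built-in MSA is a deterministic center-star progressive alignment: the
# longest read is the center and every other read is globally aligned to it
# (affine gap costs), after which the pairwise gap patterns are merged. Reads
# in a duplex family are near-identical copies of one template, so this is
# accurate where it matters and keeps results reproducible. An external
# MAFFT backend can be selected when the `mafft` executable is installed.

default_sw <- list(match = 1, mismatch = -1, gap_open = -2, gap_extend = -1)

GAP_QUAL_CHAR <- " "  # placeholder in gapped quality rows, never a real score

#' Align the reads of one single-stranded family
#'
#' @param seqs character vector of read sequences (one family, one strand,
#'   one mate); at least one read.
#' @param quals character vector of Sanger quality strings matching `seqs`;
#'   defaults to Phred 40 everywhere.
#' @param backend `"builtin"` center-star alignment, or `"mafft"` to shell
#'   out to the MAFFT executable.
#' @param match,mismatch,gap_open,gap_extend scoring for the builtin backend;
#'   gap of length L costs `gap_open + (L - 1) * gap_extend`.
#' @param band half-width of the alignment band around the (length-shifted)
#'   main diagonal used when aligning each read to the center; family reads
#'   are near-identical, so a narrow band loses nothing and keeps long
#'   families fast. `0` disables banding.
#' @return list with `seqs` (gapped rows, equal length), `quals` (gapped
#'   quality rows; gap positions hold a space placeholder) and `center`.
#' @export
align_family <- function(seqs, quals = NULL, backend = c("builtin", "mafft"),
                         match = 1, mismatch = -1, gap_open = -2,
                         gap_extend = -1, band = 16L) {
  backend <- match.arg(backend)
  if (length(seqs) == 0L) stop("cannot align an empty family")
  if (is.null(quals)) quals <- strrep(phred_to_chars(40L), nchar(seqs))
  if (length(quals) != length(seqs) || any(nchar(quals) != nchar(seqs))) {
    stop("qualities do not match sequences")
  }
  if (any(!nzchar(seqs))) stop("cannot align empty sequences")
  if (length(seqs) == 1L) {
    return(list(seqs = seqs, quals = quals, center = 1L))
  }
  if (backend == "mafft") {
    return(align_family_mafft(seqs, quals))
  }
  out <- cpp_center_star(toupper(seqs), quals, match, mismatch,
                         gap_open, gap_extend, band)
  list(seqs = out$seqs, quals = out$quals, center = out$center)
}

# re-thread ungapped quality strings onto gapped alignment rows, putting the
# placeholder at gap positions
thread_gap_quals <- function(gapped, quals) {
  vapply(seq_along(gapped), function(i) {
    chars <- strsplit(gapped[i], "", fixed = TRUE)[[1]]
    out <- rep(GAP_QUAL_CHAR, length(chars))
    out[chars != "-"] <- strsplit(quals[i], "", fixed = TRUE)[[1]]
    paste(out, collapse = "")
  }, character(1))
}

align_family_mafft <- function(seqs, quals) {
  if (Sys.which("mafft") == "") stop("mafft executable not found on PATH")
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa))
  writeLines(paste0(">r", seq_along(seqs), "\n", seqs), fa)
  out <- system2("mafft", c("--quiet", "--retree", "1", fa), stdout = TRUE)
  hdr <- grep("^>", out)
  stopifnot(length(hdr) == length(seqs))
  ends <- c(hdr[-1] - 1L, length(out))
  rows <- toupper(vapply(seq_along(hdr), function(i) {
    paste(out[(hdr[i] + 1L):ends[i]], collapse = "")
  }, character(1)))
  # MAFFT keeps input order without --reorder; re-thread the qualities
  list(seqs = rows, quals = thread_gap_quals(rows, quals),
       center = NA_integer_)
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Optimal local alignment under match/mismatch scores and affine gap costs.
#' `N` is scored as a mismatch against everything, including another `N`.
#' Traceback ties are broken deterministically (diagonal, then up, then
#' left); among equal-scoring end cells the one furthest along both
#' sequences is used, so full-length overlaps win over clipped ones.
#'
#' @param a,b non-empty sequences.
#' @param match,mismatch,gap_open,gap_extend scoring scheme; a gap of length
#'   L costs `gap_open + (L - 1) * gap_extend`.
#' @return list with `aligned_a`, `aligned_b` (equal-length gapped strings,
#'   empty when no positive-scoring local match exists), `score`, and
#'   1-based `a_start`, `a_end`, `b_start`, `b_end` offsets (0 when empty).
#' @export
smith_waterman <- function(a, b, match = 1, mismatch = -1, gap_open = -2,
                           gap_extend = -1) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align empty sequences")
  cpp_pairwise_align(toupper(a), toupper(b), match, mismatch, gap_open,
                     gap_extend, local = TRUE)
}
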