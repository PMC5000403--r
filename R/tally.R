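# Truth-based allele tallying for simulated runs.
#
# Read mapping and variant calling are outside this package's scope, but
# simulation studies still need per-site allele counts from the consensus
# output. Because the simulator records each fragment's origin, every DCS
# can be placed on the reference directly from its provenance: its payload
# is locally aligned to the small reference window its fragment came from,
# and aligned columns are tallied per reference position. Only unambiguous
# A/C/G/T consensus characters are counted; IUPAC ambiguity codes and N are
# ignored.

#' Tally DCS alleles against the reference using simulation truth
#'
#' @param dcs DCS data.frame from [call_consensi()] (`barcode`, `mate`,
#'   `seq`, ...).
#' @param fragments truth data.frame from [simulate_run()].
#' @param refs named character vector of reference sequences, indexed by the
#'   truth table's `source` column. Sources must share one coordinate
#'   system (e.g. a reference and the same reference with substitutions).
#' @param read_length,tag_len,linker_len the simulation's read geometry,
#'   used to compute the payload length.
#' @param pad extra reference bases on each side of the expected window.
#' @param match,mismatch,gap_open,gap_extend passed to [smith_waterman()].
#' @return data.frame with `pos`, `allele`, `count`, aggregated over all
#'   DCSs.
#' @export
tally_dcs_alleles <- function(dcs, fragments, refs, read_length = 250L,
                              tag_len = 12L, linker_len = 5L, pad = 10L,
                              match = 1, mismatch = -1, gap_open = -2,
                              gap_extend = -1) {
  if (!nrow(dcs)) {
    return(data.frame(pos = integer(), allele = character(),
                      count = integer()))
  }
  payload <- read_length - tag_len - linker_len
  tr <- fragments[match(dcs$barcode, fragments$barcode), ]
  if (anyNA(tr$frag)) stop("DCS barcode missing from truth table")
  head_mate <- ifelse(tr$flipped, 2L, 1L)
  forward <- (dcs$mate == head_mate) == (tr$strand == "+")
  pos_all <- vector("list", nrow(dcs))
  allele_all <- vector("list", nrow(dcs))
  for (i in seq_len(nrow(dcs))) {
    ref <- refs[[tr$source[i]]]
    if (forward[i]) {
      w_start <- tr$start[i]
      w_end <- min(tr$start[i] + payload - 1L + pad, nchar(ref))
      query <- dcs$seq[i]
    } else {
      w_start <- max(tr$end[i] - payload + 1L - pad, 1L)
      w_end <- tr$end[i]
      query <- revcomp(dcs$seq[i])
    }
    if (!nzchar(query)) next
    window <- substr(ref, w_start, w_end)
    al <- smith_waterman(query, window, match, mismatch, gap_open,
                         gap_extend)
    if (!nzchar(al$aligned_a)) next
    qa <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]]
    wa <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]]
    refpos <- w_start - 1L + al$b_start - 1L + cumsum(wa != "-")
    keep <- wa != "-" & qa %in% BASES
    pos_all[[i]] <- refpos[keep]
    allele_all[[i]] <- qa[keep]
  }
  tallied <- data.table::data.table(pos = unlist(pos_all),
                                    allele = unlist(allele_all))
  if (!nrow(tallied)) {
    return(data.frame(pos = integer(), allele = character(),
                      count = integer()))
  }
  out <- tallied[, .(count = .N), by = .(pos, allele)]
  data.table::setorder(out, pos, allele)
  as.data.frame(out)
}

#' Per-site minor-allele summary of a tally
#'
#' @param tally data.frame from [tally_dcs_alleles()].
#' @return data.frame with `pos`, `depth`, `major`, `minor`, `maf`.
#' @export
tally_site_stats <- function(tally) {
  dt <- data.table::as.data.table(tally)
  out <- dt[, {
    o <- order(-count, allele)
    depth <- sum(count)
    .(depth = depth, major = allele[o[1]],
      minor = if (.N >= 2L) allele[o[2]] else NA_character_,
      maf = if (.N >= 2L) count[o[2]] / depth else 0)
  }, by = pos]
  data.table::setorder(out, pos)
  as.data.frame(out)
}
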