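# End-to-end driver: raw paired FASTQ -> family table -> within-family
# alignment -> SSCS/DCS -> optional ambiguity trimming -> FASTA (and
# optionally fixed-quality FASTQ) output, plus a run report. Equivalent to
# chaining the individual stages through files.

#' Run the full duplex consensus pipeline
#'
#' @param fq1,fq2 paired FASTQ inputs (mate 1 / mate 2).
#' @param out_prefix path prefix for outputs: `<prefix>_dcs_1.fa`,
#'   `<prefix>_dcs_2.fa` and, when the SSCS policy is `"separate"`,
#'   `<prefix>_sscs_1.fa` / `<prefix>_sscs_2.fa`. `NULL` skips writing.
#' @param tag_len,invariant_len tag/linker geometry, see [extract_tags()].
#' @param min_reads,qual_thresh consensus thresholds, see [call_consensi()].
#' @param sscs_policy disposition of SSCSs without an opposite-strand
#'   partner, see [handle_unpaired_sscs()].
#' @param trim_mode `"none"`, `"trim"` or `"remove"`, see
#'   [trim_ambiguous()].
#' @param max_frac_n,trim_window trimming parameters.
#' @param fastq_out also write `.fq` files with every base at
#'   `fixed_phred`.
#' @param fixed_phred Phred value for FASTQ output.
#' @param backend MSA backend, see [align_family()].
#' @return invisibly, a list with `dcs`, `sscs`, `unpaired` data.frames,
#'   the `report` (named integer vector) and `files` written. The report
#'   satisfies
#'   `read_pairs_in == read_pairs_used + read_pairs_discarded + read_pairs_rejected`.
#' @export
run_pipeline <- function(fq1, fq2, out_prefix = NULL, tag_len = 12L,
                         invariant_len = 5L, min_reads = 3L,
                         qual_thresh = 20, sscs_policy = "separate",
                         trim_mode = c("none", "trim", "remove"),
                         max_frac_n = 0.3, trim_window = 10L,
                         fastq_out = FALSE, fixed_phred = 40L,
                         backend = "builtin") {
  trim_mode <- match.arg(trim_mode)
  pairs <- read_paired_fastq(fq1, fq2)
  tagged <- extract_tags(pairs, tag_len, invariant_len)
  tbl <- build_family_table(tagged$pairs)
  cons <- call_consensi(tbl, min_reads = min_reads,
                        qual_thresh = qual_thresh, backend = backend)
  routed <- handle_unpaired_sscs(cons$unpaired, sscs_policy)
  dcs <- cons$dcs
  if (nrow(routed$main)) {
    extra <- data.frame(barcode = routed$main$barcode,
                        mate = routed$main$mate, seq = routed$main$seq,
                        n_ab = ifelse(routed$main$order == "AB",
                                      routed$main$n_reads, 0L),
                        n_ba = ifelse(routed$main$order == "BA",
                                      routed$main$n_reads, 0L))
    dcs <- rbind(dcs, extra)
  }
  if (trim_mode != "none" && nrow(dcs)) {
    dcs$seq <- trim_ambiguous(dcs$seq, mode = trim_mode,
                              max_frac_n = max_frac_n, window = trim_window)
    dcs <- dcs[!is.na(dcs$seq) & nzchar(dcs$seq), , drop = FALSE]
  }
  # accounting: a pair is used if its strand group met the size threshold
  dt <- data.table::as.data.table(tbl)[mate == 1L]
  grp <- dt[, .(n_pairs = .N), by = .(barcode, order)]
  used <- sum(grp$n_pairs[grp$n_pairs >= min_reads])
  report <- c(
    read_pairs_in = nrow(pairs),
    read_pairs_rejected = tagged$n_rejected,
    read_pairs_used = used,
    read_pairs_discarded = nrow(pairs) - tagged$n_rejected - used,
    n_families = length(unique(tbl$barcode)),
    n_sscs = nrow(cons$sscs),
    n_dcs = nrow(cons$dcs),
    n_unpaired_sscs = nrow(cons$unpaired)
  )
  files <- character(0)
  if (!is.null(out_prefix)) {
    files <- write_consensus_files(dcs, routed$separate, out_prefix,
                                   fastq_out, fixed_phred)
  }
  invisible(list(dcs = dcs, sscs = cons$sscs, unpaired = cons$unpaired,
                 report = report, files = files))
}

write_consensus_files <- function(dcs, separate_sscs, prefix, fastq_out,
                                  fixed_phred) {
  files <- character(0)
  for (m in 1:2) {
    rows <- dcs[dcs$mate == m, , drop = FALSE]
    seqs <- rows$seq
    names(seqs) <- sprintf("%s %d-%d", rows$barcode, rows$n_ab, rows$n_ba)
    f <- sprintf("%s_dcs_%d.fa", prefix, m)
    write_fasta(seqs, f)
    files <- c(files, f)
    if (fastq_out) {
      fq <- sprintf("%s_dcs_%d.fq", prefix, m)
      write_fastq(seqs, fq, fixed_qual = fixed_phred)
      files <- c(files, fq)
    }
  }
  if (nrow(separate_sscs)) {
    for (m in 1:2) {
      rows <- separate_sscs[separate_sscs$mate == m, , drop = FALSE]
      if (!nrow(rows)) next
      seqs <- rows$seq
      names(seqs) <- sprintf("%s %s-%d", rows$barcode, rows$order,
                             rows$n_reads)
      f <- sprintf("%s_sscs_%d.fa", prefix, m)
      write_fasta(seqs, f)
      files <- c(files, f)
    }
  }
  files
}

#' Print a pipeline run report
#'
#' @param report named vector from [run_pipeline()].
#' @return the report, invisibly.
#' @export
format_report <- function(report) {
  for (k in names(report)) cat(sprintf("%-24s %d\n", k, report[[k]]))
  invisible(report)
}
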