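# Readers and writers for the formats the pipeline touches: paired FASTQ in,
# the six-column family table in between, FASTA/FASTQ consensus output.
# Quality scores are Sanger-encoded Phred (+33) throughout; no other encoding
# is accepted. Gzip input/output is inferred from a ".gz" extension.

#' Convert Sanger-encoded quality strings to Phred integers
#'
#' @param x character vector of quality strings (offset +33).
#' @return for `chars_to_phred`, a list of integer vectors (one per string);
#'   for `phred_to_chars`, a single quality string.
#' @examples
#' chars_to_phred("!I")[[1]]   # 0 40
#' phred_to_chars(c(0, 40))    # "!I"
#' @export
chars_to_phred <- function(x) {
  lapply(x, function(s) {
    if (!nzchar(s)) return(integer(0))
    utf8ToInt(s) - 33L
  })
}

#' @rdname chars_to_phred
#' @param q integer vector of Phred scores.
#' @export
phred_to_chars <- function(q) {
  if (!length(q)) return("")
  if (any(q < 0L | q > 93L)) stop("Phred scores must be in [0, 93]")
  intToUtf8(as.integer(q) + 33L)
}

file_conn <- function(path, open) {
  if (identical(path, "-")) {
    if (startsWith(open, "r")) return(file("stdin", open = open))
    return(stdout())
  }
  if (grepl("\\.gz$", path)) gzfile(path, open = open) else file(path, open = open)
}

parse_fastq_lines <- function(lines, label) {
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop("malformed FASTQ in ", label, ": truncated record near line ", n)
  }
  idx <- seq(1L, n, by = 4L)
  hdr <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad)) {
    stop("malformed FASTQ in ", label, ": bad record at line ",
         (bad[1] - 1L) * 4L + 1L)
  }
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) {
    stop("malformed FASTQ in ", label, ": sequence/quality length mismatch ",
         "at line ", (bad[1] - 1L) * 4L + 2L)
  }
  data.frame(name = sub("^@", "", hdr), seq = toupper(seqs), qual = qual)
}

read_fastq_one <- function(path) {
  if (identical(path, "-")) {
    return(parse_fastq_lines(readLines(file("stdin")), "<stdin>"))
  }
  x <- withCallingHandlers(
    tryCatch(
      Biostrings::readQualityScaledDNAStringSet(path),
      error = function(e) stop("malformed FASTQ in ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    ),
    # Biostrings notes that it drops mcols it never needs here
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  data.frame(
    name = names(x),
    seq = as.character(x),
    qual = as.character(Biostrings::quality(x)),
    row.names = NULL
  )
}

strip_mate_suffix <- function(name) {
  sub("/[12]$", "", sub("\\s.*$", "", name))
}

#' Read a pair of FASTQ files into a read-pair table
#'
#' Mates must appear in the same order in both files. Read names are
#' truncated at the first whitespace and any `/1` / `/2` suffix is removed;
#' the remaining names must match mate for mate.
#'
#' @param path1,path2 FASTQ files (plain or gzip) for mate 1 and mate 2.
#' @return a data.frame with columns `name`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_paired_fastq <- function(path1, path2) {
  r1 <- read_fastq_one(path1)
  r2 <- read_fastq_one(path2)
  if (nrow(r1) != nrow(r2)) {
    stop("unequal mate counts: ", nrow(r1), " records in ", path1, " vs ",
         nrow(r2), " in ", path2)
  }
  n1 <- strip_mate_suffix(r1$name)
  n2 <- strip_mate_suffix(r2$name)
  bad <- which(n1 != n2)
  if (length(bad)) {
    stop("mate name mismatch at record ", bad[1], ": '", n1[bad[1]],
         "' vs '", n2[bad[1]], "'")
  }
  data.frame(name = n1, seq1 = r1$seq, qual1 = r1$qual,
             seq2 = r2$seq, qual2 = r2$qual)
}

#' Write a read-pair table as two FASTQ files
#'
#' @param reads data.frame as returned by [read_paired_fastq()].
#' @param path1,path2 output paths (".gz" for gzip).
#' @export
write_paired_fastq <- function(reads, path1, path2) {
  write_one <- function(path, seqs, quals) {
    con <- file_conn(path, "wt")
    if (!identical(path, "-")) on.exit(close(con))
    writeLines(paste0("@", reads$name, "\n", seqs, "\n+\n", quals), con)
  }
  if (nrow(reads)) {
    write_one(path1, reads$seq1, reads$qual1)
    write_one(path2, reads$seq2, reads$qual2)
  } else {
    for (p in c(path1, path2)) if (!identical(p, "-")) file.create(p)
  }
  invisible(c(path1, path2))
}

family_table_cols <- c("barcode", "order", "mate", "name", "seq", "qual")

#' Write / read the intermediate family table
#'
#' The family table holds one row per mate per read pair, with columns
#' (canonical barcode, tag order, mate, read name, sequence, quality) in that
#' fixed order and no header, so that a plain lexicographic sort of the file
#' reproduces the grouping by canonical barcode.
#'
#' @param tbl data.frame with the six family-table columns.
#' @param path output path, `"-"` for stdout/stdin.
#' @return `read_family_table` returns a data.frame with columns
#'   `barcode`, `order`, `mate`, `name`, `seq`, `qual`.
#' @export
write_family_table <- function(tbl, path) {
  tbl <- as.data.frame(tbl)[, family_table_cols]
  bad <- which(nchar(tbl$seq) != nchar(tbl$qual))
  if (length(bad)) {
    stop("family table row ", bad[1], ": sequence/quality length mismatch")
  }
  if (!nrow(tbl)) {
    if (!identical(path, "-")) file.create(path)
    return(invisible(path))
  }
  if (identical(path, "-")) {
    write.table(tbl, stdout(), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    data.table::fwrite(tbl, path, sep = "\t", col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_family_table
#' @export
read_family_table <- function(path) {
  empty <- data.frame(barcode = character(), order = character(),
                      mate = integer(), name = character(),
                      seq = character(), qual = character())
  if (identical(path, "-")) {
    lines <- readLines(file("stdin"))
    if (!length(lines)) return(empty)
    dt <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                            colClasses = list(character = c(1, 2, 4, 5, 6)))
  } else {
    if (file.size(path) == 0) return(empty)
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            colClasses = list(character = c(1, 2, 4, 5, 6)))
  }
  data.table::setnames(dt, family_table_cols)
  dt[, mate := as.integer(mate)]
  as.data.frame(dt)
}

clean_fasta_names <- function(x) gsub(" ", "_", x, fixed = TRUE)

drop_empty_records <- function(seqs) {
  empty <- !nzchar(seqs) | is.na(seqs)
  if (any(empty)) {
    warning(sum(empty), " empty sequence(s) skipped: ",
            paste(utils::head(names(seqs)[empty], 3), collapse = ", "))
    seqs <- seqs[!empty]
  }
  seqs
}

#' Write consensus sequences as FASTA or fixed-quality FASTQ
#'
#' Consensus sequences carry no per-base qualities, so the FASTQ writer
#' (mirroring the combine-FASTA-and-QUAL step of the standard workflow)
#' assigns one fixed Phred value to every base. Sequences are written on a
#' single line; spaces in names become underscores; empty sequences are
#' skipped with a warning.
#'
#' @param seqs named character vector of sequences.
#' @param path output path (".gz" for gzip, `"-"` for stdout).
#' @param fixed_qual Phred value used for every base in FASTQ output.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- drop_empty_records(seqs)
  con <- file_conn(path, "wt")
  if (!identical(path, "-")) on.exit(close(con))
  if (length(seqs)) {
    writeLines(paste0(">", clean_fasta_names(names(seqs)), "\n", seqs), con)
  }
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(seqs, path, fixed_qual = 40L) {
  seqs <- drop_empty_records(seqs)
  con <- file_conn(path, "wt")
  if (!identical(path, "-")) on.exit(close(con))
  if (length(seqs)) {
    qc <- substr(phred_to_chars(rep.int(fixed_qual, 1L)), 1, 1)
    quals <- strrep(qc, nchar(seqs))
    writeLines(paste0("@", clean_fasta_names(names(seqs)), "\n", seqs,
                      "\n+\n", quals), con)
  }
  invisible(path)
}
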