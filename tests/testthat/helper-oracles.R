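# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results from first principles (naive tallies,
# textbook dynamic programming) without touching the package's own kernels.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Score-only affine local alignment (Gotoh), straight from the textbook
# recurrences, O(nm) matrices.
oracle_sw_score <- function(a, b, match = 1, mismatch = -1, go = -2,
                            ge = -1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      F[i, j] <- max(H[i - 1, j] + go, F[i - 1, j] + ge)
      E[i, j] <- max(H[i, j - 1] + go, E[i, j - 1] + ge)
      s <- if (A[i - 1] == B[j - 1] && A[i - 1] != "N") match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Brute-force per-column consensus over gapped rows with plain (ungapped,
# per-read) quality strings: its own neighbour-weighted gap score, its own
# vote tally.
oracle_consensus <- function(rows, quals, thresh) {
  mat <- do.call(rbind, strsplit(rows, ""))
  qn <- lapply(quals, function(q) utf8ToInt(q) - 33)
  L <- ncol(mat)
  out <- character(L)
  for (col in seq_len(L)) {
    votes <- character(0)
    for (r in seq_len(nrow(mat))) {
      ch <- mat[r, col]
      real <- which(mat[r, ] != "-")
      if (ch == "-") {
        left <- rev(real[real < col])
        right <- real[real > col]
        num <- 0
        den <- 0
        for (d in 1:4) {
          w <- 5 - d
          if (d <= length(left)) {
            num <- num + w * qn[[r]][which(real == left[d])]
            den <- den + w
          }
          if (d <= length(right)) {
            num <- num + w * qn[[r]][which(real == right[d])]
            den <- den + w
          }
        }
        q <- if (den > 0) num / den else 0
      } else {
        q <- qn[[r]][which(real == col)]
      }
      if (q >= thresh) votes <- c(votes, ch)
    }
    if (!length(votes)) {
      out[col] <- "N"
      next
    }
    tab <- table(votes)
    winner <- names(tab)[tab * 2 > length(votes)]
    out[col] <- if (length(winner)) winner else "N"
  }
  paste(out[out != "-"], collapse = "")
}

# a tiny read-pair table built by hand: n_frag fragments, per-fragment tag
# pair, n_ab/n_ba read pairs per strand, fixed payloads
toy_pairs <- function(n_frag, n_ab, n_ba, payload = "ACGTACGTAC",
                      linker = "GGGGG") {
  rows <- list()
  for (f in seq_len(n_frag)) {
    tags <- sort(c(random_dna(12), random_dna(12)))
    alpha <- tags[1]  # alpha < beta, so "ab" rows really carry order AB
    beta <- tags[2]
    q <- strrep("I", nchar(payload) + 17)
    for (i in seq_len(n_ab)) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("f%d_ab%d", f, i),
        seq1 = paste0(alpha, linker, payload),
        qual1 = q,
        seq2 = paste0(beta, linker, payload),
        qual2 = q
      )
    }
    for (i in seq_len(n_ba)) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("f%d_ba%d", f, i),
        seq1 = paste0(beta, linker, payload),
        qual1 = q,
        seq2 = paste0(alpha, linker, payload),
        qual2 = q
      )
    }
  }
  do.call(rbind, rows)
}
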