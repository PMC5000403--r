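# Analytic model of sequencing errors inside duplex tags and the artifactual
# single-read families they create.
#
# A barcode of length l in which each base is wrong independently with
# cumulative probability E is erroneous with probability r = 1 - (1 - E)^l.
# The same identity composes error rates across stages (PCR cycles plus the
# sequencing reaction), and its inverse estimates the per-base rate from an
# observed erroneous-barcode fraction. Since an erroneous 24-mer is almost
# certainly unique, each erroneous read pair founds its own singleton family,
# so the singleton-family fraction of a real experiment estimates r.

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(name, " must be a probability in [0, 1]")
  }
}

check_stages <- function(l) {
  if (any(l < 1) || any(l != as.integer(l))) {
    stop("length/stage count must be a positive integer")
  }
}

#' Fraction of barcodes expected to carry at least one error
#'
#' @param E per-base error probability (cumulative over all stages).
#' @param l barcode length in bases.
#' @return `1 - (1 - E)^l`.
#' @export
erroneous_fraction <- function(E, l) {
  check_prob(E, "E"); check_stages(l)
  1 - (1 - E)^l
}

#' Cumulative per-base error rate across amplification/sequencing stages
#'
#' Composes a per-stage, per-base error rate over `n_stages` independent
#' stages (typically the number of PCR cycles plus one for the sequencing
#' reaction) using the same survival identity as [erroneous_fraction()].
#'
#' @param per_stage_E per-base error probability at each stage.
#' @param n_stages number of stages.
#' @return cumulative per-base error probability.
#' @export
cumulative_error <- function(per_stage_E, n_stages) {
  check_prob(per_stage_E, "per_stage_E"); check_stages(n_stages)
  1 - (1 - per_stage_E)^n_stages
}

#' Invert the barcode-error model for the per-base rate
#'
#' Solves `r = 1 - (1 - E)^l` for `E`, so that
#' `erroneous_fraction(invert_for_E(r, l), l)` recovers `r` to machine
#' precision.
#'
#' @param r erroneous fraction in `[0, 1)`.
#' @param l barcode length (or stage count).
#' @return per-base error probability `E`.
#' @export
invert_for_E <- function(r, l) {
  check_prob(r, "r"); check_stages(l)
  if (any(r >= 1)) stop("r must be < 1: E is undefined at r = 1")
  1 - (1 - r)^(1 / l)
}

#' Estimate the erroneous-barcode fraction from singleton families
#'
#' Under the assumption that every single-read family is the byproduct of a
#' sequencing error inside a duplex tag, the erroneous-barcode fraction is
#' the ratio of singleton families to total read pairs.
#'
#' @param n_singleton_families number of families with exactly one read pair.
#' @param n_total_read_pairs total read pairs in the experiment.
#' @return estimated erroneous fraction `r`.
#' @export
singleton_error_estimate <- function(n_singleton_families,
                                     n_total_read_pairs) {
  if (n_singleton_families < 0 || n_total_read_pairs < 0) {
    stop("counts must be non-negative")
  }
  if (n_total_read_pairs == 0) stop("total read pairs must be positive")
  n_singleton_families / n_total_read_pairs
}

#' Expected number of observed families under the barcode-error model
#'
#' In an idealised experiment of `n_fragments` tagged fragments sequenced
#' into `n_read_pairs` read pairs, every read pair whose barcode acquired an
#' error founds a unique artifactual singleton family on top of the real
#' ones, so the expected family count is
#' `n_fragments + round(n_read_pairs * r)` (half-up rounding of the artifact
#' term, a presentation-level choice).
#'
#' @param n_fragments number of real tagged fragments.
#' @param n_read_pairs total read pairs produced from them.
#' @param r erroneous-barcode fraction.
#' @return expected total number of observed families.
#' @export
expected_observed_families <- function(n_fragments, n_read_pairs, r) {
  if (n_fragments < 0 || n_read_pairs < 0) stop("counts must be non-negative")
  check_prob(r, "r")
  n_fragments + floor(n_read_pairs * r + 0.5)
}
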