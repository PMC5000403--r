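# Post-processing of strand-stratified allele counts: minor allele
# frequency, strand bias, and the site filters used for low-frequency
# variant screening (MAF >= 0.5 %, SB < 1, optional depth floor).
#
# The strand-bias score is the relative difference of the alternate-allele
# fraction between the two sequencing strands (Guo et al. 2012,
# BMC Genomics 13:666):
#
#   SB = | b/(a+b) - d/(c+d) | / ( (b+d)/(a+b+c+d) )
#
# with a,b the reference/alternate counts on the plus strand and c,d on the
# minus strand. Perfectly balanced strands score exactly 0, growing
# imbalance scores larger, and the score is invariant under relabelling the
# strands. It is undefined (NA, and the site fails filtering) when either
# strand has no coverage.

#' Read a strand-stratified allele-count table
#'
#' Expects a TSV with columns `chrom`, `pos` (1-based), `allele`,
#' `plus_count`, `minus_count` (header optional, but column order fixed).
#'
#' @param path input path, `"-"` for stdin.
#' @return data.frame with those five columns.
#' @export
read_stranded_counts <- function(path) {
  cols <- c("chrom", "pos", "allele", "plus_count", "minus_count")
  if (identical(path, "-")) {
    dt <- read.table(file("stdin"), sep = "\t", header = FALSE,
                     col.names = cols, colClasses = c("character", "integer",
                                                      "character", "integer",
                                                      "integer"))
    if (dt$chrom[1] == "chrom") dt <- dt[-1, ]
    dt$pos <- as.integer(dt$pos)
    dt$plus_count <- as.integer(dt$plus_count)
    dt$minus_count <- as.integer(dt$minus_count)
    return(dt)
  }
  dt <- data.table::fread(path, sep = "\t")
  data.table::setnames(dt, cols)
  as.data.frame(dt)
}

#' Minor allele frequency from per-allele counts
#'
#' Frequency of the second-most-frequent allele. Ties for the minor allele
#' are broken by count and then alphabetically, which does not affect the
#' frequency itself.
#'
#' @param counts named or unnamed numeric vector of per-allele depths at one
#'   site.
#' @return minor allele count divided by total depth; 0 when only one
#'   allele is present.
#' @export
maf <- function(counts) {
  if (!length(counts) || any(counts < 0)) stop("invalid allele counts")
  depth <- sum(counts)
  if (depth == 0) stop("MAF undefined at zero depth")
  if (length(counts) == 1L) return(0)
  unname(sort(counts, decreasing = TRUE)[2] / depth)
}

#' Strand-bias score from stranded reference/alternate counts
#'
#' @param ref_plus,ref_minus reference-allele depth on the plus/minus
#'   strand.
#' @param alt_plus,alt_minus alternate-allele depth on the plus/minus
#'   strand.
#' @return numeric score (vectorised): 0 for perfectly balanced strands,
#'   larger for more imbalance, 0 when there are no alternate reads at all,
#'   `NA` when either strand has no coverage.
#' @export
strand_bias <- function(ref_plus, ref_minus, alt_plus, alt_minus) {
  a <- ref_plus; c <- ref_minus; b <- alt_plus; d <- alt_minus
  n <- a + b + c + d
  out <- rep(NA_real_, length(n))
  ok <- (a + b) > 0 & (c + d) > 0
  alt_tot <- b + d
  num <- abs(b / (a + b) - d / (c + d))
  sb <- num / (alt_tot / n)
  out[ok & alt_tot > 0] <- sb[ok & alt_tot > 0]
  out[ok & alt_tot == 0] <- 0
  out
}

#' Per-site summary of a stranded allele-count table
#'
#' Determines the major and minor allele at each site (ties broken by count
#' then alphabetically), and computes depth, MAF and the strand-bias score
#' of minor versus major allele.
#'
#' @param counts data.frame as from [read_stranded_counts()].
#' @return data.frame with one row per site: `chrom`, `pos`, `depth`,
#'   `major`, `minor`, `maf`, `sb` (`minor` is `NA` at monoallelic sites).
#' @export
site_stats <- function(counts) {
  dt <- data.table::as.data.table(counts)
  dt[, count := plus_count + minus_count]
  dt[, {
    o <- order(-count, allele)
    major_i <- o[1]
    depth <- sum(count)
    if (.N >= 2L) {
      minor_i <- o[2]
      .(depth = depth, major = allele[major_i], minor = allele[minor_i],
        maf = count[minor_i] / depth,
        sb = strand_bias(plus_count[major_i], minus_count[major_i],
                         plus_count[minor_i], minus_count[minor_i]))
    } else {
      .(depth = depth, major = allele[major_i], minor = NA_character_,
        maf = 0, sb = 0)
    }
  }, by = .(chrom, pos)] |> as.data.frame()
}

#' Filter sites on MAF, strand bias and depth
#'
#' Keeps sites with `maf >= maf_min`, `sb < sb_max` (an undefined score
#' fails) and `depth >= depth_min`; one message is emitted per rejected
#' site naming the first failing criterion.
#'
#' @param sites data.frame from [site_stats()].
#' @param maf_min minimum minor allele frequency.
#' @param sb_max strand-bias scores at or above this fail.
#' @param depth_min minimum site depth.
#' @return the passing subset of `sites`.
#' @export
filter_sites <- function(sites, maf_min = 0.005, sb_max = 1.0,
                         depth_min = 0) {
  reason <- rep(NA_character_, nrow(sites))
  reason[sites$depth < depth_min] <- "depth"
  reason[is.na(reason) & sites$maf < maf_min] <- "MAF"
  reason[is.na(reason) & (is.na(sites$sb) | sites$sb >= sb_max)] <-
    "strand bias"
  for (i in which(!is.na(reason))) {
    message("site ", sites$chrom[i], ":", sites$pos[i], " rejected on ",
            reason[i])
  }
  sites[is.na(reason), , drop = FALSE]
}
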