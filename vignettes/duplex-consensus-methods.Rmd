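---
title: "Reference-free duplex consensus calling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free duplex consensus calling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexr)
```

## The problem

Duplex sequencing tags both strands of every input DNA fragment with random
barcodes before amplification, so that sequencing and PCR errors — which
appear in only some reads of a tag family, or on only one strand — can be
removed by consensus. This makes allele frequencies far below 1 % accessible,
which matters for mitochondrial heteroplasmies, sub-clonal tumour mutations
and viral populations, where a site can carry any allele frequency between 0
and 1 and no diploid genotype prior helps.

`duplexr` implements the analysis side of this design without a reference
genome. Each read pair carries a 12-base random tag at the start of each
mate (the *alpha* tag on mate 1, the *beta* tag on mate 2), followed by a
constant 5-base linker. The two strands of one fragment produce the same two
tags in opposite order, so the order-normalised concatenation — the
24-base **canonical barcode**, taking `alpha + beta` when
`alpha <= beta` by plain bytewise string comparison, else `beta + alpha` —
is identical for both strands. Sorting on canonical barcode groups the two
strand families of each fragment next to each other; the physical order
(`AB` or `BA`) is kept in a separate field. Grouping is by exact barcode
match; tags containing `N` are kept verbatim and simply form their own
families (they end up below the family-size threshold in practice). Equal
tags are defined as order `AB`, which keeps the labelling deterministic and
symmetric under a strand swap.

## Consensus model

Within one strand family (one tag order, one mate) the reads are
near-identical copies of one template, so they are aligned with a
deterministic **center-star progressive alignment**: the longest read is the
center, every other read is globally aligned to it with affine gap costs
(match +1, mismatch −1, gap open −2, gap extend −1), and the pairwise gap
patterns are merged into one coordinate system. An optional backend shells
out to the MAFFT executable when it is installed; the builtin aligner is
the reference behaviour for tests because it is fully deterministic.

The **single-stranded consensus (SSCS)** is called per column. Gaps vote
like bases. A character needs a *strict majority* (more than half) of the
counted votes — a plurality is not enough, and a tied or empty column is
called `N`. Votes with Phred quality below a threshold (default 20) are not
counted. A gap has no quality of its own, so it competes with a surrogate
score: the weighted mean of the up-to-eight nearest real bases of its row,
four per side, with weight decreasing linearly with rank distance
(4, 3, 2, 1) and renormalised where a sequence end leaves fewer than four
neighbours. The 8-neighbour rule and the linear decrease are fixed by the
method; the exact weight constants and the end-of-read renormalisation are
this package's choice, documented here and pinned by tests. Families
smaller than `min_reads` (default 3) produce no consensus; the threshold
applies to each strand independently. Columns whose consensus is a gap are
removed from the output sequence.

The **duplex consensus (DCS)** reconciles the two strand consensi of a
fragment. Opposite tag order means opposite physical strand, so mates swap:
the AB family's mate-1 SSCS covers the same fragment end as the BA family's
mate-2 SSCS, and those two are aligned with Smith–Waterman (affine gaps,
same default scores). Matching columns keep their base; two different bases
become the two-base IUPAC ambiguity code (A/G → R, C/T → Y, ...); a gap
against a base, or anything against `N`, becomes `N` — disagreement and
ignorance are never outvoted at the duplex stage. Columns outside the local
alignment are excluded, and a reconciliation that covers less than half of
either input is reported as truncated. SSCSs with no opposite-strand
partner are included, diverted to a separate file, or discarded, under the
user's policy.

Two numerical details of the aligner are deliberate. First, traceback ties
break diagonal > up > left, and among equal-scoring local end cells the one
furthest along both sequences wins, so full-length overlaps beat clipped
prefixes (`ACGT` vs `ACAT` reconciles to `ACRT`, not to a clipped `AC`).
Second, the *within-family* global aligner restricts the dynamic program to
a band (half-width 16 plus the length difference) around the shifted main
diagonal. At the error rates this method targets, family reads diverge by a
few percent, far inside the band; `band = 0` disables the restriction. The
exported `smith_waterman()` is always exact.

Ambiguous consensus output can be trimmed (bases removed from each end
while the terminal base is not A/C/G/T or a terminal window of 10 carries
more than 30 % ambiguity) or removed outright when the whole-sequence
ambiguous fraction exceeds a cutoff. Consensus sequences are written as
FASTA; an optional FASTQ writer assigns one fixed Phred value (default 40)
to every base, mirroring the combine-FASTA-and-QUAL step of the standard
workflow, since consensus bases carry no per-base quality model (posterior
consensus qualities are out of scope).

## The barcode-error model

Most families in real duplex experiments contain a single read pair. The
package includes the analytic model that explains much of this loss: a
barcode of length $l$ whose bases are each wrong with cumulative
probability $E$ is erroneous with probability

$$ r = 1 - (1 - E)^l . $$

The same identity composes per-stage rates across amplification and
sequencing ($E_{cum} = 1 - (1 - E_{stage})^{n}$ with $n$ = PCR cycles + 1),
and its inverse $E = 1 - (1-r)^{1/l}$ estimates the cumulative rate from an
observed erroneous fraction. Because a 24-mer with an error is almost
certainly unique, each erroneous read pair founds its own singleton family,
so the ratio of singleton families to total read pairs estimates $r$
(`singleton_error_estimate()`), and
`expected_observed_families(n_fragments, n_read_pairs, r)` counts the
expected families as `n_fragments + round(n_read_pairs * r)` — half-up
rounding of the artifact term, a presentation-level choice. The model's
simplifying assumptions (errors only in tags, every erroneous barcode
unique) are kept as stated, not "improved": the point of the model is its
arithmetic. With a per-stage rate of 0.1 % over 31 stages the cumulative
rate is about 3 %, and feeding the unrounded cumulative value back into the
model gives an erroneous-barcode fraction of 52.5 % for a 24-base barcode:

```{r}
E_cum <- cumulative_error(0.001, 31)
round(100 * erroneous_fraction(E_cum, 24), 1)
```

## The simulator

The simulator is first-class code, not a fixture: it is the generator for
every test input and the engine for the two simulation studies the package
reproduces.

Each fragment is a uniformly placed stretch of reference sequence (strand
uniform, linear coordinates — a circular genome's textual representation is
not circular), assembled into a molecule as
`alpha + linker + insert + rc(linker) + rc(beta)`. The number of reads it
produces is drawn from a family-size distribution; the default is a
discretised log-normal over sizes 1–40 with its mode pinned at 9 reads and
the singleton mass exposed as a parameter (default 1.20 %), since only the
mode and the singleton mass of the original empirical distribution are
known. An option constrains the *realised* assignment to contain exactly
`round(0.012 * n)` singletons, which the zero-error singleton study
requires. Defaults follow the standard in silico duplex experiment: 600-bp
fragments, 250-bp reads, 12-bp tags, a 5-bp linker (the sequence `TGACT`
is an arbitrary constant — only its length matters), 30 PCR cycles, error
probability 0.001 per base per cycle with 0.15 of errors being indels
(geometric length, extension probability 0.3, insertion/deletion
equiprobable), and fixed Phred-40 qualities.

The family's genealogy is a **backward-coalescing PCR tree**: the final
reads start as open lineages at the last cycle; walking cycles backwards,
the open lineages are shuffled and successive disjoint pairs merge with
probability $2^{-c}$ at cycle $c$; everything still open after cycle 2
attaches to one of the two first-cycle daughter strands of the original
molecule, chosen uniformly. The exact pairing scheme for the coalescent is
under-specified in general; the shuffle-and-pair-adjacent rule matches the
stated pairwise probability without quadratic work. A family whose reads
all descend from one daughter is a realistic single-strand-only family and
exercises the unpaired-SSCS policies. Errors accumulate per branch — each
base mutates independently with the per-cycle probability over the
branch's spanned cycles, descendants inherit ancestral mutations — and one
extra error round per leaf models the sequencing reaction. Substitutions
within one branch segment are applied as a batch (duplicate positions are
overwritten rather than chained); indel events are applied sequentially.
Reads are the first `read_length` bases of the molecule (daughter 1) or of
its reverse complement (daughter 2), so tag errors, linker errors and
payload errors all arise from the same process — barcode errors are not a
separate model.

`mutate_reference()` injects substitution variants at positions sampled
uniformly among all configurations with at least 600 bp between sites and
to the sequence ends, and returns the truth table; `simulate_run()` writes
per-fragment truth (origin, strand, tags, canonical barcode, family size,
reads per strand) so that every downstream quantity can be checked against
ground truth.

What the simulator does *not* emulate: quality-score profiles (qualities
are constant), GC or coverage bias, chimeras, adapter read-through, and
polymerase error spectra (all substitutions equiprobable). Passing tests
therefore demonstrate the correctness of the grouping/consensus machinery
and the internal consistency of the error model, not performance on any
particular instrument's error profile.

## Post-processing filters

Downstream of consensus calling, variant screens work on strand-stratified
allele counts (this package deliberately stops before read mapping and
variant calling, and consumes whatever counts a caller emits). `maf()` is
the frequency of the second-most-frequent allele, with ties broken by
count then alphabetically for determinism. The strand-bias score is the
relative difference of the alternate-allele fraction between strands,

$$ SB = \frac{\left| \frac{b}{a+b} - \frac{d}{c+d} \right|}{(b+d)/(a+b+c+d)}, $$

which is exactly 0 for proportionally balanced strands, grows with
imbalance, is invariant under relabelling the strands, is defined as 0 when
there are no alternate reads, and is undefined (site fails) when a strand
has no coverage. Published analyses using this family of scores report
values in the 0.01–6 range with 0 ideal; several variants of the score
exist in the literature, and this package pins the relative-difference
form because it satisfies every property the screening procedure relies
on. `filter_sites()` keeps sites with MAF at or above 0.5 %, SB below 1,
and depth at or above a floor (default 0), reporting each rejection.

## Problem sizes and test design

The package's checks re-derive everything they assert: consensus calls are
compared against an independent brute-force column tally on a thousand
random families, the Smith–Waterman kernel against a textbook
dynamic-programming oracle, and the error-model identities against direct
evaluation. The simulation studies run at reduced scale, chosen so the
qualitative results are stable under the fixed seeds used: the mixing
study uses a synthetic 3,200-bp reference with 4 injected variants and a
1:100 mixture over 20,000 fragments (the original mixed 21 variants
1:10,000 over 25 million fragments — the same machinery at a depth no test
suite should re-run), and the singleton studies use 10,000 fragments of
400 bp with 100-bp reads. At 1:100 and this coverage each injected site
expects several mutant duplex consensi, while false duplex alleles require
the same error on both strands and are orders of magnitude rarer; the
inversion from printed singleton counts is exact arithmetic at any scale.

Degenerate inputs are defined, not rejected: a single-read alignment is
the read itself; an all-gap row scores quality 0; an empty consensus or an
empty strand yields no DCS; a local alignment with no positive-scoring
match is empty, and such a pair produces no duplex consensus.

## Known limitations

- Exact-match grouping only: no mismatch tolerance in barcodes, so reads
  with tag errors are lost to singleton families exactly as the error
  model describes. Tolerant grouping is a separate problem (and would
  invalidate the singleton-based error estimate).
- Center-star alignment does not align insertions of different reads
  against each other within one inter-center slot; for near-identical
  family reads this is immaterial, but the builtin MSA is not a
  general-purpose aligner.
- Consensus output carries no per-base quality model.
- The strand-bias score is one member of a family of published scores;
  absolute values are not comparable across formulas, only the ordering
  and the 0-is-ideal contract.
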