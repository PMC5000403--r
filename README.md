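# duplexr

Reference-free analysis of **duplex sequencing** data, plus the in silico
machinery to validate it.

Duplex sequencing tags both strands of every input DNA fragment with random
barcodes before PCR, so errors introduced during amplification or sequencing
can be removed by consensus — first within each strand's read family, then
between the two strands. This pushes reliable variant detection far below
the ~1 % allele-frequency floor of ordinary sequencing, where mitochondrial
heteroplasmies, sub-clonal tumour mutations and viral variants live.
Standard pipelines lean on alignment to a reference genome; `duplexr`
instead groups and reduces the reads entirely from their barcodes, which
avoids reference bias and keeps indel-bearing or divergent alleles.

The package provides:

- **Family grouping** — each mate starts with a 12-bp random tag (alpha on
  mate 1, beta on mate 2) and a 5-bp constant linker. The order-normalised
  24-bp *canonical barcode* (`alpha+beta` if `alpha <= beta`, else
  `beta+alpha`) is identical for both strands of a fragment; sorting on it
  groups each fragment's two strand families, with the physical tag order
  (`AB`/`BA`) kept alongside.
- **Consensus calling** — reads of one strand family are aligned
  (deterministic center-star, or MAFFT if installed) and reduced to a
  single-stranded consensus (SSCS) by quality-filtered strict-majority vote
  per column (default: Phred ≥ 20 counted, ≥ 3 reads per strand, `N` when
  no majority; gaps vote like bases and score the weighted mean of their
  row's eight nearest bases). The two SSCSs of a fragment are reconciled
  into a duplex consensus (DCS) via Smith–Waterman alignment: agreement
  keeps the base, disagreement becomes the IUPAC two-base code, gap-vs-base
  becomes `N`.
- **The barcode-error model** — `r = 1 − (1 − E)^l` for the fraction of
  barcodes carrying at least one error, its composition across PCR +
  sequencing stages, its inversion, and the singleton-family estimate of
  the error rate.
- **A duplex sequencing simulator** — fragments, tags, backward-coalescing
  PCR trees (`2^-cycle` merge probability), per-branch error accumulation
  with indels, strand-aware read emission, and full ground-truth output.
- **Post-filters** — minor allele frequency and strand bias from
  strand-stratified allele counts (MAF ≥ 0.5 %, SB < 1 screening).

## Worked example

Simulate a small error-free duplex run, group it, and call consensi:

```r
library(duplexr)

set.seed(1)
ref <- random_reference(2000)
cfg <- sim_config(fragment_length = 400, read_length = 100, error_rate = 0,
                  family_dist = data.frame(size = 10, prob = 1))
sim <- simulate_run(cfg, c(ref = ref), c(ref = 20), seed = 7)

tagged <- extract_tags(sim$reads)          # split tag + linker from payload
tbl    <- build_family_table(tagged$pairs) # one row per mate per pair
family_census(tbl)
#>                         stat value
#> 1                 read_pairs   200
#> 2                unique_tags    20
#> 3         unique_tags_single     0
#> ...
#> 10             unique_duplex    20
#> 11   unique_duplex_ge_k_both    17
#> 12 read_pairs_in_duplex_ge_k   170

cons <- call_consensi(tbl)                 # SSCS + DCS
nrow(cons$dcs)                             # 34 = 17 duplex families x 2 mates
```

20 fragments produced 20 barcode families; 17 of them had at least three
read pairs on *both* strands (the default consensus threshold), and each of
those yields one DCS per mate. With the error rate at zero every DCS is
exactly its fragment's sequence — the identity the test suite checks
end-to-end.

The error model reproduces the arithmetic of barcode loss:

```r
E_cum <- cumulative_error(0.001, 31)   # 30 PCR cycles + 1 sequencing reaction
#> 0.03053946                           # "about 3 %"
erroneous_fraction(E_cum, 24)          # 24-bp barcode
#> 0.5249676                            # ~52.5 % of barcodes carry an error
expected_observed_families(10, 100, erroneous_fraction(0.03, 24))
#> 62                                   # 10 real + 52 artifactual singletons
invert_for_E(singleton_error_estimate(1717170, 17385100), 24)
#> 0.004323857                          # ~0.4 % cumulative per-base error
```

A command-line front end wrapping the same functions ships in
`inst/cli/duplexr`:

```sh
duplexr make-families reads_1.fastq reads_2.fastq -o families.tsv
duplexr make-consensi families.tsv --min-reads 3 --out-prefix out
duplexr simulate --ref ref.fa --n-fragments 10000 --seed 1 --out-prefix sim
duplexr barcode-stats --from-families families.tsv --barcode-len 24
```

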