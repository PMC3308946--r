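# edcas

Quantification of A-to-I RNA editing in the serotonin 2C receptor
(5-HT2C) editing cassette from barcoded amplicon sequencing reads.

## The problem

The 5-HT2C pre-mRNA carries five editable adenosines (sites A, B, E, C, D
in 5'→3' order) in a short coding region of the second intracellular
loop.  ADAR-mediated A-to-I editing is read as A→G by reverse
transcription and sequencing, so the five binary sites generate up to
2⁵ = 32 mRNA isoforms that recode three codons into 24 distinct protein
variants, with graded effects on receptor signalling.  Comparing the
isoform spectrum and per-site editing rates between conditions — for
example lean control versus leptin-deficient *ob/ob* mice — requires a
pipeline from pooled, barcoded amplicon reads to tables of isoform counts
and site frequencies with exact group statistics.  `edcas` implements
that pipeline for anyone analysing editing-cassette amplicons:

1. **Demultiplexing** by sequencing adaptor + group barcode (both strands,
   mismatch-tolerant), trimming reads to the cassette insert;
2. **Quality filtering** with two error-probability thresholds (mean per
   read ≤ 0.025; each of the 2 terminal bases ≤ 0.02);
3. **Site calling** against the unedited 21-nt cassette core
   `TAGCAATACGTAATCCTATTG` (sites at offsets 6, 8, 12, 13, 18): A =
   unedited, G = edited, anything else ambiguous;
4. **Quantification**: the 32-row isoform count table with relative
   occurrences, and per-site edited fractions per group with two-sided
   Fisher's exact tests (probability-mass rule, exact at 10⁴-scale
   margins) and Bonferroni correction over the five sites,
   Δ% = case − control;
5. Orthogonal assays: a **Sanger peak-height** editing estimator
   `X = G/(A+G)` with site calibration factors (A: 1.114, B: 1.009) and a
   **qPCR 2^−ΔCt** fold-change module with Welch t-tests;
6. A **synthetic-data generator** (reads, chromatogram traces, qPCR
   records) with known ground truth, so every stage is testable without
   any external data.

## Worked example

Simulate the packaged reference isoform counts (20,951 hypothalamic
cassette reads; lean + *ob/ob*) with a realistic 0.5% substitution error
rate, then run the full pipeline:

```r
library(edcas)
counts <- hypothalamus_isoform_counts()
reads  <- simulate_reads(counts = counts, base_error_rate = 0.005, seed = 42)
res    <- run_pipeline(reads)
res$manifest$counts[c("input", "assigned", "classified", "rejected")]
#> $input      20951
#> $assigned   20670
#> $classified 20361
#> $rejected   309
```

281 reads lose their barcode/primer anchor to injected errors and 309
more carry an error at an editing site (a non-A/G base is ambiguous by
definition), leaving 20,361 classified reads.  The isoform table and the
site comparison:

```r
head(res$isoforms[order(-res$isoforms$count_total),
                  c("label", "protein", "count_lean", "count_obob", "pct_total")], 3)
#>               label protein count_lean count_obob pct_total
#> 26  ABD edited form     VNV       3491       3313  33.41683
#> 25   AB edited form     VNI       1811       2100  19.20829
#> 28 ABCD edited form     VSV       1238       1053  11.25190

res$sites[, c("site", "pct_lean", "pct_obob", "delta_pct", "p_value")]
#>   site  pct_lean  pct_obob  delta_pct      p_value
#> 1    A 87.323944 89.876813  2.5528694 1.105685e-08
#> 2    B 75.162700 76.862706  1.7000058 4.525993e-03
#> 3    E  3.623118  2.930658 -0.6924604 5.856599e-03
#> 4    C 24.031083 23.812835 -0.2182478 7.178089e-01
#> 5    D 55.201554 50.705345 -4.4962094 1.378845e-10
```

Despite the injected noise the pipeline recovers the generating
structure: the VNV (ABD-edited) isoform dominates at ~33% of reads, site
A editing is higher in *ob/ob* (Δ +2.6%, Fisher p ≈ 10⁻⁸) and site D
lower (Δ −4.5%, p ≈ 10⁻¹⁰) — with zero injected error the counts
round-trip exactly.  With `out_dir=` set, `run_pipeline()` writes
`table1.tsv`, `table2.tsv` and a `manifest.json` whose stage counts are
conserved.  A thin command-line front end over the same functions ships
in `inst/cli/edcas` (`run`, `simulate`, `demux`, `call`, `quantify`,
`sanger`, `qpcr`).

The methods vignette
(`vignettes/editing-cassette-methods.Rmd`) documents the model, the
parameter defaults and the design decisions in detail.

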