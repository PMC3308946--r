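---
title: "Quantifying 5-HT2C editing-cassette isoforms from barcoded amplicon reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 5-HT2C editing-cassette isoforms from barcoded amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edcas)
```

## The biology and the model

The serotonin 2C receptor (5-HT2C) pre-mRNA contains a short exonic region
-- the *editing cassette* -- coding for part of the second intracellular
loop, in which five adenosines (labelled A, B, E, C and D in 5' to 3'
order) are deaminated to inosine by ADAR enzymes.  Reverse transcription
reads inosine as guanosine, so in cDNA an edited site appears as an A-to-G
substitution.  Each site is binary, so a transcript carries one of
$2^5 = 32$ *editing codes*.  The five sites fall inside three codons of
the cassette frame (ATA with sites A and B at codon positions 1 and 3; AAT
with E and C at positions 1 and 2; ATT with D at position 1), and because
ATA, GTA and GTG all encode valine-or-isoleucine ambiguities collapse some
states, the 32 mRNA codes translate to only 24 distinct amino-acid
triplets:

```{r combinatorics}
nrow(enumerate_codes())
count_distinct_proteins()
translate_code(c("", "AB", "ABD", "ABECD"))
```

Editing reduces receptor G-protein coupling and constitutive activity, so
shifts in the isoform distribution between conditions (here: lean control
versus leptin-deficient *ob/ob* mice) are the biological signal of
interest.

### The cassette reference

All site calling is anchored on a 21-nt unedited core,
`TAGCAATACGTAATCCTATTG`, with 1-based site offsets A=6, B=8, E=12, C=13,
D=18 and the reading frame starting at position 6.  The core is the
interior of the unedited-isoform (INI) hydrolysis probe; substituting G at
the edited sites of any isoform reproduces the corresponding
edited-isoform probe at every site position, which is the property the
reference is validated against (`test-editing-model.R`).  The full
amplicon flanks between the PCR primers and the core are not part of any
computation; the simulator pads the cassette with fixed arbitrary
non-homopolymeric filler to a realistic ~300 bp amplicon.  Coordinates are
1-based on the sense strand throughout; reverse-orientation handling is
confined to demultiplexing and the chromatogram module.

## Pipeline stages and their parameters

**Demultiplexing** (`demultiplex()`).  A pooled read is recognised by its
`adaptor A + group barcode + forward primer` prefix, on either strand.
The adaptor is anchored at the read start with at most 1 mismatch, the
barcode must be within `max_barcode_mismatches` (default 1) of exactly one
configured barcode, and the forward primer must follow with at most 1
mismatch.  The two default 10-nt barcodes differ at 6 positions, so a
1-mismatch tolerance can never produce an ambiguous assignment.  Reads
whose primer cannot be located are left unassigned rather than guessed:
downstream site calling needs the cassette, and the isoform table's
denominator is the set of classified reads.

**Quality filtering** (`lucy_filter()`).  An accept/reject filter with two
thresholds on Phred-derived error probabilities: mean per-base error at
most 0.025, and every base within 2 bases of either end at most 0.02.
These are the conventional amplicon-cleaning defaults.  The filter does
not trim -- demultiplexing has already removed the technical prefix/suffix
-- and it is monotone: lowering any quality score can never rescue a
failing read (property-tested).

**Site calling** (`call_sites()`).  Each read is placed against the
cassette core and the base over each site offset is read: A means
unedited, G edited, and anything else (C, T, N, or a gap) is ambiguous --
A-to-I editing can only manifest as A-to-G, so any other base is
sequencing error, not signal.  A read ambiguous at *any* site is excluded
from isoform counting as a whole (read-level rejection) but retained in
the reject report; `site_frequencies(tally = "site")` exposes the
alternative per-site tally, whose denominators can be slightly larger.
Placement uses two routes that agree exactly on indel-free reads
(property-tested): a fast degenerate-pattern search (A/G wildcards at the
five sites) and, for reads the search cannot place uniquely, an ends-free
pairwise alignment (match 2, mismatch -1, gap open -4, gap extend -1).
Alignment identity is computed over **non-site positions only**: a fully
edited read differs from the unedited reference at all five sites (16/21 =
76% raw identity) and would otherwise be rejected by the default 80%
identity floor -- site mismatches are biology and must not count against a
read.  Reads whose aligned span misses a site are rejected with reason
`"span"`; low-identity placements with reason `"identity"`.

**Quantification** (`tabulate_isoforms()`, `site_frequencies()`,
`compare_sites()`).  The isoform table keeps all 32 codes, including
zero-count rows, and computes every percentage from counts at output time,
with the combined two-group grand total as the denominator of all three
relative-occurrence columns (that is the convention of the reference count
table this package reconstructs).  Site-wise group comparison uses a
two-sided Fisher's exact test on
`[[edited, unedited] x [control, case]]`, Bonferroni-corrected over the
five sites.  The test sums hypergeometric probabilities not exceeding the
observed table's (the probability-mass rule, with a `1e-7` relative
tolerance for floating-point ties), accumulated in log space so
10^4-scale margins cannot underflow; it matches an exhaustive
enumeration oracle exactly for all margins up to 30 (property-tested) and
the large-sample z-test within an order of magnitude at 10^4.  The signed
difference `delta_pct` is *case minus control*, so a positive value means
more editing in the case group -- the direction convention of the
reference table.

**Sanger chromatogram estimator** (`trace_editing_profile()`).  At a site,
the gross editing frequency is `X = G height / (A height + G height)`; the
reported value multiplies X by a site calibration factor (1.114 for A,
1.009 for B, 1.0 elsewhere -- factors exist only for the two sites that
were ever quantified this way; they are treated as opaque empirical
constants) and clamps to [0, 1], since a frequency cannot exceed 1.
Traces may be supplied in reverse-complement orientation; orientation is
auto-detected by aligning the called-base sequence both ways and the
channels are swapped (A with T, C with G) accordingly, which the tests
verify is an exact invariance.

**qPCR module** (`qpcr_fold_change()`).  Technical replicates are averaged
per sample before anything else; relative expression is
$2^{-\Delta C_t}$ with $\Delta C_t = C_t(\text{target}) -
C_t(\text{control gene})$; fold change is the group mean divided by the
control-group mean; groups are compared per gene by Welch's two-tailed
unpaired t-test on per-sample relative expressions with Bonferroni
correction across the genes tested.  With noise-free input the t-test is
undefined (constant data) and the p-value is reported as `NA`.

## What the synthetic-data generator emulates

`simulate_reads()` builds structurally faithful amplicons -- adaptor,
barcode, primer, flanks, cassette, reverse primer and adaptor B on the
other strand -- in two modes: exact per-isoform counts (for lossless
round-trip checks: with zero injected error the pipeline must and does
reproduce every configured count), or per-site Bernoulli editing
probabilities, optionally correlated across sites through an exchangeable
Gaussian copula (`linkage`), since real transcripts show linkage between
sites edited by the same enzyme.  Errors are iid substitutions at a
configurable per-base rate (default 0; 0.5% is a realistic
pyrosequencing-era figure used in the recovery tests), with an optional
indel rate to exercise the alignment fallback.  Qualities are Gaussian
Phred scores (mean 35, sd 3, clamped to 2..41).

The generator deliberately does **not** model homopolymer-length errors
(the dominant 454 artefact), position-dependent quality decay, chimeras,
or PCR amplification bias.  Passing tests therefore demonstrate
correctness of the analysis given substitution-type noise and exact
barcode structure; they do not certify performance on reads whose errors
are concentrated in homopolymers or whose libraries are chimeric.

`simulate_trace()` produces idealised peak-height tables (template channel
`1 - m`, edited channel `m` of the peak scale at a site with mixture `m`,
Gaussian height noise, clamped at zero), and `simulate_qpcr()` produces
triplicate Ct records around a group-level true delta-Ct with Gaussian
between-animal noise.

## Numerical and design choices

* Canonical code order is lexicographic over (A, B, E, C, D), unedited
  first; the frequency-sorted order of published tables is a rendering
  option (`order = "frequency"`), not the internal order.
* The packaged 32-row taxonomy corrects two internal inconsistencies of
  its printed source: the D-only-edited row's pattern must carry G at the
  D position (the printed pattern duplicates the unedited row while the
  protein column, INV, confirms D editing), and one pattern printed under
  an "ABEC" label is the ABED code (again the protein, VDV, is decisive).
  Proteins and patterns in the taxonomy are machine-checked against
  `translate_code()` / `pattern_for_code()` for all 32 rows.
* Empty denominators yield `NA` percentages, never silent zeros; empty
  Fisher margins yield p = 1 with a warning.
* Fixture scale in the tests: the lossless round-trip runs the full
  pipeline on the complete 20,951-read reconstruction of the reference
  count table (about 6 s); stochastic recovery tests use 10,000 reads per
  group at 0.5% error, within 3 binomial standard errors, under fixed
  seeds.
* With a seed supplied, every generator is byte-reproducible and restores
  the caller's RNG state (`withr::with_seed`).

## Known limitations

* The per-site percentages printed in the reference site table cannot be
  regenerated exactly from the reference isoform counts (discrepancies up
  to ~0.1%), implying its per-site denominators included reads absent from
  the isoform table; consequently the reference p-values are reproducible
  in order of magnitude only.  Both tallies (read-level and per-site) are
  implemented so either convention can be applied to new data.
* Lucy-style cleaning is implemented as the stated two-threshold
  accept/reject criterion on already-trimmed reads, not as a windowed
  trimming algorithm.
* The chromatogram module consumes peak-height tables, not AB1 binaries,
  and no basecalling is performed.
* No chimera detection and no 454 homopolymer correction (see above).
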