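---
title: "Curation and analysis of fecal metabarcoding diet data"
author: "dietbarcodeR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation and analysis of fecal metabarcoding diet data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `dietbarcodeR`, the
parameter choices that matter, what the synthetic-data generator does and
does not emulate, and the design decisions taken where the underlying
methodology left the implementation genuinely open.

## 1. The data model

A sequencing **library** is a matrix of unique amplicon sequences by PCR
wells ("units"). Units carry a type: three replicate wells per fecal
`sample`, plus `blank` wells (deliberately left empty, used to quantify tag
jumps), `extraction_negative` and `pcr_negative` wells (reagent-contaminant
sentinels), and `positive_control` wells (a fixed mix of out-of-area taxa).
Counts are non-negative integers until replicate aggregation, after which
sample-level values are real-valued replicate means.

The analysis currency is **relative read abundance** (RRA): a taxon's reads
in a sample divided by the sample's total retained reads. RRA is
semi-quantitative: it assumes read counts are monotonically related to
ingested biomass within a marker, which is known to be distorted by
gene-copy number and digestion bias; no correction factors are applied
here.

## 2. The curation cascade

Stages run in a fixed order; each reports reads in/out and removed, and the
identity `reads_in = reads_out + reads_removed` is enforced per stage.

| stage | rule | default | rationale for the default |
|---|---|---|---|
| length filter | drop sequences outside the marker's length range | 10–220 bp (plant P6 loop); 76–168 bp for the arthropod 16S assay | amplifiable barcode lengths of the two markers |
| minimum count | drop sequences with < `min_library_reads` over the whole library (samples **and** controls) | 10 | removes singleton-level noise before the quadratic-cost stages |
| denoising | merge a sequence into a more abundant one when within `max_mismatch` edits and at ≤ `child_ratio` of its (current) total | 1 edit, 0.05 | a 1-edit child at <5% of its parent is far more likely a PCR/sequencing error than a real allele; applied iteratively in decreasing-abundance order so absorbed counts strengthen parents |
| clustering | greedy, abundance-sorted; join the first representative with identity ≥ threshold | 0.97 | conventional OTU radius for these markers |
| assignment | best hit ≥ threshold in the local database, else global, else unassigned | 0.97 | the local database wins even when a global hit has higher identity, because vouchered local references carry more trustworthy labels |
| range rules | demote out-of-range species to genus if the genus occurs locally, else family | — | mirrors manual verification against regional floras |
| rank cap | truncate all assignments to a rank | off (set `family` for arthropods) | short 16S fragments are unreliable below family |
| host removal | drop sequences assigned to host taxa | off | the primate host and human handlers dominate the arthropod marker |
| contaminant filter | drop a sequence whose max per-well **relative** abundance in negatives strictly exceeds its max in samples | — | raw counts are incomparable across wells of very different depth |
| tag-jump filter | zero any cell with fewer than `r × T_s` reads, `r` = `quantile` of positive blank leak fractions `b/T_s` | quantile = 1 (max) | the worst observed leak into a deliberately empty well bounds the plausible leak anywhere |
| replicate consensus | keep the mean over all R replicates if present in ≥ `min_replicates` and mean ≥ `min_mean_reads` | 2 of 3, mean ≥ 5 | replicated presence is the strongest single guard against sporadic artifacts |

Notable resolved ambiguities:

* **"mean number of reads … and a minimum of five reads"** — the mean is
  taken over *all* R replicates (zeros included) and the 5-read floor
  applies to that mean. This is deterministic and conservative; applying
  the floor per replicate would keep strictly more.
* **Minimum-count placement** — applied before denoising, following the
  order in which the protocols list the steps.
* **Tag-jump ratio estimator** — the reference tooling leaves the estimator
  to the analyst; we use a quantile (default max) of the pooled positive
  blank leak fractions, exposed as a parameter. The Wilcoxon signed-rank
  diagnostic (blank totals of the more abundant half of sequences paired by
  rank against the less abundant half) is reported but never used as a
  gate, because the original pairing scheme is not described.
* **Identity definition** — matches / global-alignment length under
  match +1, mismatch −1, gap −2 (computed with Biostrings). The internal
  scoring of the original clustering tool is not reproduced; the 0.97
  radius is interpreted under this explicit definition, and tests pin it to
  an independent Needleman–Wunsch oracle.
* **Ties** — everywhere resolved by decreasing abundance, then
  lexicographic sequence order, making demultiplexing, denoising and
  clustering invariant to input row order.

Degenerate inputs are non-fatal by design: a zero-depth well is an all-zero
column; a table with no negative controls makes the contaminant filter a
warning no-op; no blank reads make the tag-jump ratio 0 (identity); reads
too short for tags + primers are counted unassigned.

## 3. Season calendar and profile aggregation

Seasons partition the year with **mid-month boundaries**: spring from
16 August, summer from 16 November, autumn from 16 March, winter from
16 May (southern hemisphere). Day 16 operationalizes "middle of the month";
days ≥ 16 of a boundary month belong to the following season. Temporal
aggregation ignores the year (same months of different years pool), and is
an unweighted mean of profile rows. To avoid pseudo-replication, individual
weighting averages each individual's samples within a season and
renormalizes, so every individual contributes exactly one simplex row per
season; the phrasing "replicate samples sum up to 1 per individual" admits
sum-then-normalize, which differs from mean-then-renormalize only by the
same final normalization. Daily focal observation rates (events / that
day's screenings) are kept as rates for time series and closed to
compositions (`close_profile()`) only when entering compositional
statistics; items observed once in the whole log are dropped before
normalization.

## 4. Statistics

All permutation tests use `p = (1 + hits) / (1 + n_perm)` with seeded,
reproducible permutation streams; defaults are 9999 permutations.

* **Shannon–Wiener** in nats (the base is unstated in common reporting;
  nats are the R convention), with the Hutcheson variance
  `(Σ p ln²p − H²)/N + (S−1)/(2N²)` and a Welch-style-df t-test. The
  variance needs true counts `N`; feeding proportions gives a meaningless
  variance, so the test helpers take counts.
* **ANOSIM** uses the standard Clarke denominator `M/2` with
  `M = n(n−1)/2` (i.e. divisor `n(n−1)/4`), so `R ∈ [−1, 1]` and complete
  separation gives exactly 1. One-sided for separation.
* **Mantel** correlates upper triangles and permutes one matrix's
  rows/columns jointly; one-sided for positive association.
* **PCoA** reports negative eigenvalues (Bray–Curtis matrices are
  generally non-Euclidean) and normalizes relative eigenvalues over the
  positive part only; axis signs are fixed by making the first non-zero
  loading positive.
* **IndVal** uses the original group-equalized specificity (A from group
  *means*, no site-weight correction); a taxon's statistic is its maximum
  over groups.
* **Per-item Spearman** matches monthly series; an eDNA label shared by
  several species is paired with its single observed member species when
  only one was observed, and excluded when two or more were.

## 5. What the synthetic generator emulates — and what it does not

`sim_config()` defaults describe the stated world once, and recovery tests
run against it:

* **Diet structure**: one Dirichlet(0.5) baseline composition per season
  (sparse, uneven diets), one planted indicator taxon per season with mass
  only in its season (share 0.08), per-sample compositions re-drawn with
  precision 100 around the season baseline — within-season variance below
  between-season variance by construction.
* **Sequencing**: log-normal replicate depths (μ = 8, σ = 0.6 on the log
  scale, median ≈ 3000 reads — a mid-size benchtop run split over ~2500
  wells), multinomial reads per well, triplicate PCRs, 4 blanks, 2 + 2
  negatives, 2 positive-control wells of a 70/30 two-taxon out-of-area mix.
* **Artifacts**: tag jumps binomial per read at rate 0.001 with uniform
  destination wells (additive injection — jumped reads are *added*, not
  subtracted from sources, keeping the planted bookkeeping exact at a
  negligible distortion for rates ≪ 1); Poisson contaminants (2 reads per
  control well, 10% of that per sample well); optional host reads at a
  fixed fraction of each sample well. Every planted read is recorded by
  (well, sequence, origin), and origin totals must reconcile with the grand
  total.
* **Observations**: per season, 25 observation days; 5 focal follows a day
  of 10 instantaneous screenings each (so daily screening counts are
  multiples of 10); feeding events at 0.4 per screening drawn from the
  day's season composition, thinned by per-taxon detection probability
  (default 0.7); recorded labels at a per-taxon resolution (70% species,
  20% genus, 10% an undetermined broad category).

Not emulated: chimeras, polymerase error spectra, quality scores (no FASTQ;
read assembly is upstream of this package), primer-bias differences among
taxa, copy-number variation, or correlated observer effort. A green
recovery test therefore establishes that the *pipeline logic* recovers
planted truth under these idealized error processes — not that the defaults
match any particular sequencing platform.

Raw-read simulation writes `8-nt tag + primer + insert + rc(primer) +
rc(tag)` per read and confines substitution errors to primer regions, so
demultiplexing's ≤ 2-mismatch-per-primer tolerance is exercised while tags
and inserts stay exact (tag errors would silently unassign reads, which is
the demultiplexer's documented behavior for real data too).

## 6. Known limitations

* **Tag-jump removal has a hard ceiling.** Under the abundance-proportional
  uniform-destination leak model, most jumped reads land in wells where the
  sequence is genuinely present; they are invisible to any cell-zeroing
  filter, and removing them would require zeroing abundant true cells. In
  simulation at leak rate 0.001, only about a quarter of jumped reads
  create false presences; the filter removes the large majority of those
  while touching well under 1% of true reads (see
  `tests/testthat/test-acceptance.R`). The filter should be judged on
  false-presence removal, not on total leaked-read removal.
* **The relative-abundance contaminant rule is aggressive on near-empty
  negatives.** A single read leaked into an otherwise empty negative well
  has relative abundance 1 and can delete a genuine dietary sequence
  library-wide. With realistic contaminant background in negatives this is
  rare, and positive-control sequences being removed by this stage is
  harmless (their wells are dropped at aggregation), but users with very
  clean negatives may prefer running the tag-jump filter first.
* **Multi-species labels are partial information.** Joined labels
  ("A/B") are treated as single items; range rules demote them only when
  *no* member species is locally valid.
* **The Hutcheson variance is asymptotic**; for very small counts the
  bootstrap disagrees noticeably (tests pin agreement within 20% at
  N = 10,000, not below).

## 7. Reproducibility

Every stochastic function takes an explicit integer seed (or derives one
from `sim_config$rng_seed`); identical seeds give byte-identical outputs,
including permutation streams. The test suite regenerates all fixtures from
code; no binary data ships with the package.
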