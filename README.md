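# dietbarcodeR

Curation and analysis of fecal DNA-metabarcoding diet data, with a
ground-truth synthetic-data generator for validating every step.

## What problem this package addresses

Diet studies of wild vertebrates increasingly sequence short "barcode"
amplicons (e.g. the chloroplast *trnL* P6 loop for plants, a 16S fragment
for arthropods) from fecal samples. Raw amplicon tables are dominated by
artifacts — sequencing errors, chimeric abundance noise, reagent
contaminants, and *tag jumps* (reads mis-assigned to the wrong well during
library preparation, leaking in proportion to a sequence's abundance). The
accepted remedy is a curation cascade over PCR-replicated samples and a
battery of control wells, followed by compositional analysis of **relative
read abundances** (RRA: reads of a taxon in a sample divided by the
sample's total reads).

`dietbarcodeR` implements that workflow for a study design typical of
primate field ecology: triplicate PCRs of each fecal sample, blanks,
extraction/PCR negatives, and positive controls per library; a vouchered
*local* reference database that out-resolves public-repository references;
year-round sampling summarized by mid-month-bounded seasons; and parallel
focal-observation feeding records for method comparison. It is aimed at
molecular ecologists who want each stage of such a pipeline as a tested,
composable R function rather than a black box.

## The methods at its core

**Curation cascade** (fixed order, each stage a pure function on a
`read_table` of sequences x PCR wells):

1. barcode length filter;
2. library-wide minimum count (`< 10` reads per library discarded);
3. abundance-based denoising: a sequence within 1 edit of a more abundant
   sequence, at `<= 5%` of its total, is merged into it;
4. greedy 97% clustering (abundance-sorted; identity = matches / global
   alignment length with match +1, mismatch -1, gap -2);
5. cascading taxonomic assignment: local database first, then global, both
   at 97% identity; reference sequences shared by several species yield
   joined multi-species labels; geographic range rules demote out-of-range
   species to genus or family; an optional rank cap (family for the
   arthropod assay);
6. host (vervet/human) read removal;
7. contaminant removal: any sequence whose maximum per-well relative
   abundance in negative controls exceeds its maximum in samples;
8. tag-jump filter: the maximum blank leak fraction `b/T` defines a
   per-library ratio `r`; any cell below `r * T_s` reads is zeroed;
9. replicate consensus: a sequence's mean count over all replicates is kept
   only if present in `>= 2` of 3 replicates with a mean of `>= 5` reads.

**Statistics** (all formula-level implementations, permutation p-values as
`(1 + hits) / (1 + n_perm)`): Bray-Curtis dissimilarity, PCoA by Gower
double-centering, ANOSIM (`R = (rB - rW) / (M/2)`), Mantel tests,
Dufrene-Legendre indicator values (`IndVal = A x B x 100`), Shannon-Wiener
diversity `H = -sum p ln p` with the Hutcheson variance and t-test, and
per-item Spearman correlations between eDNA and observational monthly
series (with a minimum focal count filter).

**Synthetic data**: seasonal Dirichlet diet compositions with planted
season-indicator taxa, per-sample Dirichlet resampling, log-normal
replicate depths, multinomial reads, and planted tag jumps, contaminants
and host reads — every injected read recorded, so filters can be scored
against exact truth.

## Worked example

```r
library(dietbarcodeR)

cfg   <- sim_config(n_taxa = 12, n_individuals = 6,
                    samples_per_individual_season = 1,
                    tagjump_rate = 0.001, contaminant_rate = 1,
                    rng_seed = 42)
truth <- gen_seasonal_profiles(cfg)
sim   <- gen_read_table(truth, cfg)
sim$table
#> <read_table> library 'lib1': 17 sequences x 82 units (72 sample, 10 control), 270,086 reads

db  <- reference_db(data.frame(
  seq_id = sprintf("t%03d", seq_len(nrow(truth$taxa))),
  sequence = truth$taxa$sequence,
  taxon_path = paste("Viridiplantae", "OrderX", truth$taxa$family,
                     truth$taxa$genus, truth$taxa$taxon, sep = ";"),
  rank = "species", species = truth$taxa$taxon,
  geographic_valid = TRUE), scope = "global")

res <- curate(sim$table, global_db = db, verbose = TRUE)
#> [length_filter] sequences 17 -> 17, reads 270,086 -> 270,086 (removed 0)
#> [min_count_filter] sequences 17 -> 14, reads 270,086 -> 270,066 (removed 20)
#> [denoise_merge] sequences 14 -> 14, reads 270,066 -> 270,066 (removed 0)
#> [cluster_greedy] sequences 14 -> 14, reads 270,066 -> 270,066 (removed 0)
#> [remove_contaminants] sequences 14 -> 12, reads 270,066 -> 219,954 (removed 50,112)
#> [tagjump_filter] sequences 12 -> 12, reads 219,954 -> 219,884 (removed 70)
#> [aggregate_replicates] sequences 12 -> 12, reads 219,884 -> 71,286 (removed 148,598)
```

The 17 sequences are the 12 dietary taxa plus positive-control, host and
contaminant sequences; the contaminant stage removes the two
positive-control sequences (present only in control wells), the tag-jump
stage zeroes the 70 leaked reads that created false presences, and
`aggregate_replicates` returns per-sample replicate *means* (hence the read
total drops to roughly a third).

```r
profiles <- to_rra(res$samples)
season   <- season_of(profiles$meta$collection_date)

anosim(bray_curtis(profiles), season, n_perm = 999, seed = 1)
#> ANOSIM: statistic = 1.0000, p = 0.001 (999 permutations, seed 1)

iv <- indval(profiles, season, n_perm = 999, seed = 1)
head(iv$taxa[order(-iv$taxa$statistic), ], 5)
#>       taxon  group statistic p_value
#> 1 Taxon_001 spring     100.0   0.001
#> 2 Taxon_002 summer     100.0   0.001
#> 3 Taxon_003 autumn     100.0   0.001
#> 4 Taxon_004 winter     100.0   0.001
#> 7 Taxon_008 winter      71.1   0.001
```

The simulated seasons are fully separated (ANOSIM `R = 1`), and the four
planted indicator taxa (one per season) come out with `IndVal = 100` in
exactly their true seasons — the generator's ground truth is recovered.

Printed-table arithmetic helpers reproduce reported study numbers exactly:

```r
identification_rate(19406, 12315)          # 63.46 (% of identified events)
read_accounting(1698439, 961542, 360040)   # 736,897 remaining; 48.86% assigned
refdb_summary(gen_reference_db(43, 4, 1))  # 48 sequences, 54 species
```

## Command line

```sh
Rscript -e 'dietbarcodeR::dietbarcoder_cli()' simulate --out-dir scratch/sim --seed 1
Rscript -e 'dietbarcodeR::dietbarcoder_cli()' curate --counts scratch/sim/library1 \
    --global-db scratch/sim/local_db --out-dir scratch/curated
```

See `vignettes/diet-metabarcoding.Rmd` for the model assumptions, parameter
choices, and known limitations.
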