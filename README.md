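# fmthgt

Horizontal gene transfer (HGT) analysis for faecal microbiota
transplantation (FMT) trials, from per-sample metagenome summaries.

## The problem

After FMT, donor bacterial strains can engraft in the recipient's gut,
and genes can move between donor and recipient bacteria by horizontal
transfer. Distinguishing genuinely transferred genes from vertical
persistence of the same species — and from historical HGT signatures
already present in bacterial genomes — requires a time-course design:
donor samples, a recipient baseline before intervention, and recipient
samples afterwards.

`fmthgt` implements the gene-based detection logic for a two-arm,
sex-stratified FMT trial. A gene cluster (members ≥ 95% nucleotide
identity, clustered upstream) is called a **horizontally transferred
gene cluster (HTGC)** for a participant when, restricted to *analysable*
genes (on metagenome-assembled genomes with completeness > 90%,
contamination < 5%, and a species-level classification):

1. at least one gene of the cluster is present in the participant's
   week-6 sample,
2. no gene of the cluster is present at the participant's baseline,
3. at least one gene of the cluster is present in a sex-matched donor
   sample, and
4. the species of the recipient's MAG differs from the species of at
   least one donor occurrence (taxonomic discordance — same-species
   carriage is vertical persistence, not transfer).

Each distinct qualifying recipient gene is one transfer event. Around
this core the package provides the full downstream analysis:

- per-participant HTGC frequency (% of distinct analysable week-6
  clusters) and Wilcoxon rank-sum arm comparisons, overall and by sex;
- FMT-specific / placebo-specific / shared cluster partitions and
  per-cluster transfer-event histograms (unit bins, terminal "20+");
- restriction to **engraftment-dependent** events, where the donor-side
  species has a strain-level engraftment call for that recipient at
  week 6; donor attribution and species-pair transfer matrices;
- phylum enrichment of engrafted-with-HGT versus engrafted strains:
  Pearson chi-squared, post-hoc standardized residuals
  `r = (O − E) / sqrt(E (1 − rowm/n)(1 − colm/n))` with two-sided normal
  p-values and Benjamini–Hochberg control, plus the background phylum
  distribution of donor genes;
- linear mixed models (`lme4`) of richness-normalised contig-level HGT
  counts (`n_hgt_contigs / species_richness`) with treatment, sex and
  timepoint fixed effects and a participant random intercept,
  interactions screened by likelihood-ratio test;
- retention of engraftment-dependent HTGCs at weeks 12 and 26
  (deduplicated to distinct recipient × cluster units, retained when
  cluster CPM > 0) and a mixed model of their abundance;
- COG functional profiling (four major classes; multi-letter
  annotations counted per category) compared across timepoints by
  one-way PERMANOVA on Bray–Curtis dissimilarities
  `d(x, y) = 1 − 2·Σ min(xᵢ, yᵢ) / (Σx + Σy)` with permutation p-values
  `p = (1 + #{F* ≥ F}) / (1 + n_perm)`;
- a synthetic trial generator with planted ground truth (engraftments,
  transfers, retention, week-26 drift), so the whole pipeline is
  testable without any sequencing data.

## Input format

A *bundle* is a directory of TSV tables (see `?hgt_bundle` for column
schemas): `design`, `samples`, `mags`, `genes` (required),
`donor_assignment`, `engraftment`, `abundance`, `waafle`, `cog`
(optional). One small example file per table ships under
`inst/extdata/example_bundle/`. Thin adapters parse common upstream
dialects: CheckM quality tables (`read_checkm`), GTDB-Tk summaries
(`read_gtdbtk`), cd-hit `.clstr` files (`read_cdhit_clstr`),
eggNOG-mapper annotations (`read_eggnog`) and per-sample WAAFLE contig
calls (`read_waafle_calls`).

## Worked example

```r
library(fmthgt)

sim <- simulate_trial(sim_config(seed = 42))   # 9 donors, 40 recipients
res <- run_pipeline(sim$bundle, run_config(n_perm = 999, seed = 7))
res
#> <hgt_results>
#>   events: 959 (465 clusters); engraftment-dependent: 20
#>   arm comparison (overall) p = 0.0467

res$arm_comparison
#>   comparison n_fmt n_placebo statistic p_value
#> 1 overall       20        20     274    0.0467
#> 2 female        10        10      74.5  0.0695
#> 3 male          10        10      63    0.345
```

959 transfer events across 465 distinct clusters were detected; 20
events involved donor species with a week-6 engraftment call. The
overall Wilcoxon p of 0.047 for this seed sits at the edge of the
null band — under the default generator the two arms acquire background
clusters at the same rate, and across 200 replicate trials the test
rejects at about its nominal level. The richness-normalised
contig-level model recovers the planted week-26 drift of 0.37:

```r
res$rate_lmm$coefficients[4, ]
#>   term            estimate ci_low ci_high
#>   timepointweek26    0.381  0.330   0.432
```

and every planted transfer is recovered exactly
(`sensitivity = precision = 1` against `sim$truth`).

A thin command-line wrapper over the same functions is installed at
`inst/scripts/fmthgt-cli.R` (`simulate`, `detect`, `report`
subcommands); all outputs are TSV/JSON stamped with the package version
and a configuration hash.

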