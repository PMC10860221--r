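---
title: "Detecting horizontally transferred gene clusters in an FMT trial: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontally transferred gene clusters in an FMT trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmthgt)
```

## Scope and inputs

`fmthgt` works entirely from tabular per-sample summaries produced by a
standard metagenomics workflow: assembled and binned genomes with
quality scores and taxonomy, genes assigned to a non-redundant
(≥ 95% identity) cluster catalog, strain-level donor engraftment calls,
cluster-level abundances in copies per million reads (CPM), per-sample
contig-level HGT call counts with species richness, and COG functional
annotations. No sequence data enter the package; the upstream tools'
internals (assembly, binning, quality estimation, taxonomy assignment,
clustering, strain profiling, alignment, annotation) are out of scope
and their outputs are consumed as given.

## The detection model

The central inference is set logic over a time course. For each trial
participant — FMT and placebo recipients pass through the *identical*
code path; the treatment arm is never read during detection — a gene
cluster is called horizontally transferred when, on analysable genes
only:

1. **week-6 presence**: ≥ 1 gene of the cluster in the participant's
   week-6 sample;
2. **baseline absence**: no gene of the cluster in the participant's
   baseline sample;
3. **donor presence**: ≥ 1 gene of the cluster in an in-scope donor
   sample; and
4. **taxonomic discordance**: the species of the recipient gene's MAG
   differs from the species of ≥ 1 in-scope donor occurrence.

*Analysable* means the gene sits on a MAG with completeness strictly
above 90%, contamination strictly below 5%, and a species-level
classification. Both threshold inequalities are strict, as the
customary wording of the high-quality criteria has them; MAGs at
exactly 90/5 are excluded and reported. Whether a boundary MAG should
count is genuinely undecidable from the criteria's usual phrasing, so
the thresholds are arguments (`filter_high_quality`) and boundary hits
are messaged for audit. Genes on high-quality MAGs *without* a species
call are counted and reported as an excluded fraction (two decimals) in
the run summary, since this quality-control statistic is how the
filtering step is conventionally summarised.

Assumptions worth making explicit:

- **Species identity is string equality.** Taxonomy arrives
  pre-resolved; fuzzy matching would invent biology. Unclassified
  species is an explicit boolean, not a sentinel string, avoiding
  `s__`-dialect ambiguity.
- **Presence is evaluated on analysable genes only — including the
  baseline-absence test.** A cluster seen at baseline only on a
  low-quality or unclassified MAG still counts as absent. This keeps
  one consistent gene universe throughout; the alternative (testing
  absence on all genes) would make detection depend on bins the
  analysis has already declared unreliable.
- **Discordance with *any* donor occurrence suffices** (criterion 4).
  A cluster carried by several donor species, one matching the
  recipient species, is still a candidate transfer via the others. A
  stricter all-occurrences mode is available
  (`detect_htgcs(discordance = "all")`).
- **Donor scope defaults to the whole sex-matched donor cohort** for
  both arms, with `assigned` (the participant's own donors) available.
  Placebo participants have no assigned donors, so a single cohort-wide
  scope is the only choice that processes both arms identically, which
  the arm comparison requires. Whether the original analysis scoped FMT
  recipients to their four assigned donors is not decidable from the
  usual methods wording; the cohort default is the more conservative
  (more donor evidence, monotonically more detections).
- **One event per distinct qualifying recipient gene**, judged against
  its own MAG's species. Distinct genes of one cluster are separate
  transfer events; the cluster is counted once in cluster-level
  summaries. Week-12/26 samples are never consulted during detection —
  detection is a week-6 statement; later timepoints only enter
  retention.

## Statistics around the core

**HTGC frequency and arm comparison.** Frequency is
`100 × (distinct detected clusters) / (distinct analysable week-6
clusters)` per participant. Arms are compared with the two-sided
Wilcoxon rank-sum test: exact enumeration when both groups have ≤ 8
untied values, otherwise the normal approximation with tie and
continuity correction (`stats::wilcox.test` supplies both regimes).

**Phylum enrichment.** The contingency compares engrafted donor strains
with engrafted strains contributing to HGT. The counting unit is a
genuinely open choice; the default counts *engraftment instances*
(distinct recipient × species pairs — each engraftment call is one
strain establishing in one gut), with `species` (deduplicated across
recipients) and `events` (event-weighted) modes exposed. The test is
Pearson's chi-squared without continuity correction, with a
zero-expected-cell guard that advises pooling. Post-hoc inference uses
standardized (adjusted) residuals with two-sided normal p-values,
Benjamini–Hochberg-adjusted across all cells — the behaviour of the
standard post-hoc procedure for chi-squared tables. Phyla with zero
counts in both columns are dropped and messaged. The normal reference
for residuals is accurate for cell counts in the hundreds; the test
suite verifies agreement with a fixed-margin Monte-Carlo null (10⁴
`r2dtable` resamples) to within 0.01 at that scale.

**Mixed models.** Richness-normalised contig-level HGT counts
(`n_hgt_contigs / species_richness`, dimensionless events per detected
species) are modelled as
`normalized ~ arm + sex + timepoint + (1 | participant)` with
references placebo / female / baseline; retained-cluster abundance as
`cpm ~ sex + timepoint + (1 | recipient)` with references female /
week6. Estimation is REML via `lme4`; the full model with all
fixed-effect interactions is compared to the additive model by
likelihood-ratio test on ML refits, and the additive model is reported.
Confidence intervals are Wald 95%; p-values use the normal
approximation to the Wald statistic — at trial sample sizes (hundreds
of observations, dozens of participants) the difference from a
t-approximation is far below the reported precision. Singular fits are
flagged, not fatal; a zero-variance random intercept reduces the fit to
OLS (verified against `lm` in the tests). Fixed effects constant in the
data are dropped with a message rather than erroring, so per-stratum
analyses run unchanged.

**Retention.** Engraftment-dependent events are deduplicated to
distinct (recipient, cluster) units because abundance is measured for
the whole cluster. A unit is retained at week 12/26 when its CPM there
is strictly positive; no threshold is imposed beyond > 0 because none
is given in the field's usual description — the most permissive
reading — and the threshold is an argument for sensitivity analyses.
Units with no week-6 abundance record are listed in a QC table and
excluded from denominators. Re-detection is allowed: the week-26
retained set need not be a subset of week 12's.

**Functional profiling.** COG letters map to the four standard major
classes (information storage and processing: A B J K L; cellular
processes and signaling: D M N O T U V W Y Z; metabolism: C E F G H I
P Q; poorly characterised: R S; unannotated clusters are "no
classification"). Multi-letter annotations are counted once per
category. PERMANOVA rows are per-HTGC-per-timepoint composition vectors
over classes (or categories), closed to relative abundance, grouped by
timepoint and run separately per sex; an alternative with
recipient-sample rows is reachable by aggregating the series before the
call. The PERMANOVA itself is authored in the package — one-way
pseudo-F from the squared-dissimilarity partition, label permutations
under a caller-supplied seed, `p = (1 + #{F* ≥ F}) / (1 + n_perm)` so
the smallest attainable p is `1/(n_perm + 1)`, and exhaustive
enumeration of distinct label assignments for n ≤ 10 — because
seed-controlled and exhaustive permutation modes are part of the
contract; `vegan::adonis2` serves as an independent cross-check in the
test suite (statistics agree to 10 decimal places), never as the
implementation. Bray–Curtis is the textbook formula; a scaling of all
features by a common positive constant leaves p unchanged.

## The synthetic trial generator

`simulate_trial(sim_config())` generates a complete desk-scale trial
with planted ground truth. The defaults describe the study conditions
the package targets: nine stool donors (five female, four male) sampled
twice across a donation period, recipients in two arms sampled at
baseline and weeks 6/12/26, four sex-matched donors assigned per
recipient, and a species pool whose phylum weights (Firmicutes 0.682,
Bacteroidetes 0.218, Actinobacteria 0.042, remainder 0.058) match the
high-quality-MAG census of such trials. Default cohort and catalog
sizes — 10 recipients per arm per sex, 60 species × 10 clusters, 22
species per community — are the package's desk-scale choice: large
enough that every downstream statistic is exercised at realistic
relative rates, small enough that hundreds of replicate trials run in a
test suite.

Mechanics, one RNG substream per generated table (so adding a table
never perturbs another, and a fixed seed reproduces the bundle
byte-for-byte):

- Each species carries a disjoint repertoire of gene clusters, so a
  cluster's home species is unambiguous and planted transfers are
  discordant by construction.
- At week 6 every recipient gains novel species from a donor pool of
  identical size in both arms (the assigned donors for FMT; an equally
  sized environmental exposure pool for placebo). In the FMT arm these
  are recorded as engraftments with a carrying donor. This symmetry is
  deliberate: community size and background-acquisition opportunity
  stay arm-balanced, so the arm comparison is approximately null by
  design.
- **Background acquisitions** (both arms, rate per candidate donor-
  cohort cluster) attach a cluster from a non-resident donor species to
  a resident species — detectable HTGCs that occur at equal rates in
  both arms, mirroring the fact that placebo-arm calls arise from
  clusters also present in the sex-matched donor cohort.
- **Engraftment-dependent transfers** (FMT only) let each engrafted
  species transfer clusters to a resident species with probability
  `transfer_rate_given_engraftment`, multiplied for Bacteroidetes
  donors by `bacteroidetes_hgt_multiplier` (default 4) — the planted
  phylum bias the enrichment stage must recover. The default transfer
  rate (0.05) keeps engraftment-dependent events a small minority of
  each FMT recipient's HTGCs, as they are in a real trial; experiments
  that need trial-scale engraftment-dependent counts (retention at
  n ≈ 300, enrichment power) raise the engraftment/transfer rates in
  their own configurations.
- **Retention** draws week-12/26 persistence per planted unit
  (defaults 0.858 and 0.803); `cog_shift_week26 > 0` plants a week-26
  functional shift by retaining non-metabolism clusters less often —
  note that a multiplicative CPM change on one class would be invisible
  to per-HTGC closed compositions, which is why the planted effect acts
  on retention instead.
- **Contig-level HGT counts** are Poisson with mean
  `richness × (base rate + participant intercept + drift × 1[week 26])`
  (defaults: base 0.2, intercept SD 0.08, drift 0.37), so counts
  correlate with richness, carry no arm or sex effect, and drift upward
  at week 26 — the signal the mixed-model stage must recover.
- **Decoy MAGs** (low-quality and high-quality-unclassified) carry
  genes that the quality and taxonomy filters must remove; they never
  host planted transfers, so with the defaults the planted HTGC set is
  recovered with sensitivity and precision exactly 1, and that recovery
  is a standing test.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: mis-binning and chimeric MAGs
(clusters never sit on the wrong species by error), taxonomic
misclassification, shared accessory genes between species (repertoires
are disjoint, so discordance is never ambiguous), within-species strain
variation, read-depth-driven detection dropout, and compositional
sequencing noise in CPM values. On real data these failure modes make
both false positives (mis-binned clusters satisfying discordance) and
false negatives (dropout at baseline mimicking absence) possible; the
synthetic recovery results bound algorithmic correctness, not
biological accuracy.

## Numerical and procedural choices

- Percentages are rounded half-away-from-zero (`pct_of`), one decimal
  for headline rates, two for the gene-exclusion QC fraction, matching
  how such statistics are conventionally printed.
- Benjamini–Hochberg is the step-up procedure via `stats::p.adjust`;
  the hand-executed example `[0.01, 0.04, 0.03] → [0.03, 0.04, 0.04]`
  is frozen in the tests against an independently coded oracle.
- Permutation p-values use the +1 correction; exhaustive enumeration
  replaces sampling for n ≤ 10. With two equal groups the label-swap
  symmetry ties the maximal F, so the `1/(n_perm+1)` floor is only
  reached when group sizes make a random relabelling of the exact
  partition negligible.
- Detection ties: a recipient gene whose cluster also occurs on a
  second recipient MAG of another species is judged against its own
  MAG only; the other gene is its own event.
- When an event's donor side matches several engrafted species it is
  kept once per engrafted species for attribution, while event totals
  count distinct recipient genes. Engraftment matching is on
  (recipient, species); the donor id is reported when unique, else
  flagged ambiguous.
- Degenerate inputs: zero analysable week-6 clusters is an error (the
  frequency is undefined); an all-zero dissimilarity matrix yields NA
  PERMANOVA results rather than an error inside the pipeline; empty
  event sets propagate as empty tables with full schemas.

## Problem sizes

The test suite and the acceptance script run the default trial
(49 subjects, 178 samples, ≈ 55,000 gene rows), 200 replicate default
trials for the arm-null calibration, 100 replicates each for the
week-26 drift coverage and Bacteroidetes enrichment experiments
(boosted configuration: 12 recipients per arm per sex, engraftment rate
0.4, transfer rate 0.3, giving a few hundred engraftment-dependent
units), 500 simulated nulls for the PERMANOVA size check, and
oracle-scale fixtures (< 200 genes) for exhaustive brute-force
comparison. These sizes are the package's own validation design: large
enough for the binomial tolerances quoted in the tests, small enough to
rerun routinely.

## Known limitations

Detection is gene-cluster presence/absence: it cannot see transfer
direction beyond the donor→recipient framing, copy number, or the
mobile element that mediated the transfer. Chromosomally integrated
transfers are the realistic target — binning recovers plasmids poorly,
so episomal transfer is largely invisible to MAG-based detection.
Species-level discordance inherits every upstream taxonomy error, and
a single mis-binned contig can fabricate a discordant pair. The
engraftment join is species-level, so multiple strains of one species
in one recipient are not distinguished. Finally, the Wilcoxon arm
comparison tests frequencies, not event counts; participants with few
analysable clusters get noisy frequencies, which the richness-adjusted
denominator mitigates but does not remove.
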