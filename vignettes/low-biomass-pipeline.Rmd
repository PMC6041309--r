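---
title: "Decontamination and analysis of low-biomass 16S amplicon data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decontamination and analysis of low-biomass 16S amplicon data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lowbiome)
```

## The problem

In low-biomass specimens — meconium, newborn rectal swabs, and similar
near-sterile material — the genuine microbial DNA on a swab is of the same
order of magnitude as the background DNA carried by extraction kits, PCR
reagents and the sampling device itself. Amplicon sequencing cannot tell the
two apart: every library is a mixture of the sample community and a
reagent-contaminant community, mixed roughly in proportion to their 16S
copy numbers. Unless the background is removed, the apparent "microbiota"
of a near-sterile sample is largely reagent flora.

`lowbiome` implements a complete analysis chain for this situation:

1. negative-control based decontamination of a denoised genotype (or OTU)
   count table,
2. a dataset-wide rarity filter,
3. qPCR-based total-load quantification and group comparison,
4. alpha diversity (Shannon, Hill numbers), phylum summaries and core-taxon
   detection,
5. cross-sample similarity: paired Spearman correlations, Friedman and
   Nemenyi blocked tests, Bray–Curtis PCoA, shared-taxon partitions and a
   dam–calf co-existence matrix,
6. a ground-truthed synthetic study generator that emulates the design the
   pipeline targets (21 calves at three time points, 10 dams at three body
   sites, 3 empty-swab controls), so every stage can be validated without
   access to raw sequencing data.

## The decontamination rule

Let $p_{fs}$ be the relative abundance of feature $f$ in sample $s$, and
$c_f$ its relative abundance in the pooled negative controls. Every
(feature, sample) pair is classified as

* **sample_only** if $c_f = 0$ — the feature was never seen in any control
  and is left untouched;
* **accepted_shared** if $c_f > 0$ and $p_{fs} > \tau \, c_f$ with
  $\tau = 4$ by default — the feature is shared with the controls but is
  *more than* four-fold enriched in the sample, so it is kept there;
* **rejected** otherwise — the counts of $f$ in $s$ are zeroed.

Three aspects of this rule deserve emphasis.

**The inequality is strict.** A feature at exactly four times its control
abundance is rejected. The boundary matters for reproducibility and is
pinned by tests.

**The decision is per sample.** A genotype may be accepted in one sample
and rejected in another, because $p_{fs}$ varies across samples while
$c_f$ is fixed. A dataset-wide verdict could not produce the per-sample
mix of accepted and rejected reads that this filter yields, and would
wrongly delete genuinely abundant organisms from high-biomass samples that
happen to share a sequence with the controls (the classic case is a
facultative gut coloniser such as *Escherichia/Shigella* dominating a
first-day sample at a copy number orders of magnitude above the reagent
background).

**Controls are pooled by default.** Negative controls individually carry
very few reads; summing their counts before forming $c_f$ stabilises the
denominator of the ratio. The alternative `max_per_control` summary (the
maximum of the per-control relative abundances) is available in
`decontam_config()` and is stricter, since a feature spuriously
concentrated in one shallow control then blocks acceptance everywhere.

The ratio threshold is configurable. The default is 4 ("more than
four-fold"); descriptions of such filters sometimes quote other multiples
(e.g. six-fold) when summarising particular sample groups, so the
threshold is deliberately exposed rather than hard-coded.

Known limitation: the rule compares *relative* abundances only. It does
not use the qPCR copy numbers, so in samples whose total load is orders of
magnitude above the background the filter is more aggressive than the
physics warrants and will delete some genuinely present taxa. This
conservative bias — minimising false positives at the cost of false
negatives — is inherent to the method, and `evaluate_recovery()` exists
precisely to quantify it on simulated data.

### Rarity filter

After decontamination, every feature whose summed count across all
*analysed* samples is below 250 reads is removed (`rarity_filter()`,
strict `<`, so a feature totalling exactly 250 survives). Control samples
are not part of the analysed dataset and are excluded from the totals; they
also pass through both filters untouched, since they are retained for
reporting only.

## qPCR quantification

Loads are expressed as 16S rDNA copies per swab. When only Ct values are
available, `copies_from_ct()` applies the standard log-linear calibration
$\mathrm{copies} = d \cdot 10^{(C_t - b)/a}$ with slope $a < 0$, intercept
$b$ and dilution factor $d$; values outside the curve's dynamic range are
flagged but returned. The shipped default curve is a perfect-efficiency
assay (slope $-1/\log_{10} 2 \approx -3.32$), intended for synthetic data;
real analyses should supply their instrument's calibration. Group
comparisons use the ratio of medians (midpoint convention for even sizes)
and the two-sided Mann–Whitney U test — exact enumeration when the
combined sample size is at most 16 with no ties, otherwise the normal
approximation with tie and continuity corrections. Absolute quantities per
gram of material are out of scope: a swab is not a defined mass of
specimen.

## Diversity and core taxa

Shannon diversity uses the natural logarithm. The log base is a genuine
free choice — published values are frequently base-e or base-2 without
saying so — and every Shannon value this package reports is in nats. Hill
numbers $\left(\sum_i p_i^q\right)^{1/(1-q)}$ are reported as effective
taxon counts, with the $q \to 1$ limit $\exp(H)$ evaluated explicitly;
$q=0$ is richness and $q=2$ the inverse Simpson index. Diversity is
conventionally computed on OTU/genotype-level decontaminated data, while
compositional analyses (core taxa, correlations, ordination) use
genus-level aggregates. No rarefaction or subsampling is applied before
diversity estimation; with the large per-sample depths the pipeline
targets the bias is modest, but comparisons across groups with very
different depths should be interpreted with that caveat.

A genus-level taxon is **core** for a group when its *median* within-sample
relative abundance is strictly above 0.1% *and* it is detected (at least
one read) in at least 75% of the group's samples. Medians and SDs include
zero-abundance samples; this is what allows a taxon present in 76% of
samples to have a median abundance barely above the threshold. Prevalence
percentages are rounded to the nearest integer. "Detected" means one read
or more; analyses that need a firmer notion of presence (the co-existence
matrix) use an explicit 20-read cutoff instead.

Aggregation to genus or phylum sums counts over the lineage prefix,
conserving per-sample totals exactly. Unknown ranks carry explicit
`unclassified_<deepest known taxon>` placeholders, and placeholders
aggregate by their full string — an unclassified Lachnospiraceae genus and
an unclassified Ruminococcaceae genus are two different taxa, and
placeholder taxa are counted as genus-level taxa throughout.

## Similarity analyses

**Spearman correlations** between two samples are computed over the union
of genera detected in either sample, zeros filled; the many tied zeros
receive average ranks. This union-with-zeros convention is the only one
that makes coefficients comparable across pairs. A vector with zero rank
variance yields a flagged `NA` rather than an arbitrary number.

**Friedman test.** Conditions are ranked within each block (dam–calf
pair), with average ranks for ties, and the tie-corrected statistic
$(k-1)\sum_j (R_j - n(k+1)/2)^2 / (A - C)$ is referred to the
$\chi^2_{k-1}$ upper tail ($A$ = sum of squared ranks, $C = nk(k+1)^2/4$).
Without ties this is the classical $12\sum_j(R_j - n(k+1)/2)^2/(nk(k+1))$.
The chi-squared reference is a large-sample approximation: at very small
block counts it is accurate in the rejection tail but can deviate
substantially from the exact permutation distribution near the null
centre, where the permutation law is discrete with large atoms. The test
suite quantifies this with an exhaustive $(3!)^n$ permutation oracle.

**Nemenyi post-hoc.** For conditions $i,j$ the statistic
$q = (\bar R_i - \bar R_j)/\sqrt{k(k+1)/(6n)}$ is referred, after scaling
by $\sqrt 2$, to the studentized range distribution with $k$ groups and
infinite degrees of freedom — the "q approximation for unreplicated
blocked data". Note that with $k=3$ and $n=10$ blocks an adjacent
mean-rank gap of 1 is *not* significant at the 5% level
($p \approx 0.066$); only the extreme pair is.

**Bray–Curtis and PCoA.** Dissimilarities
$1 - 2\sum_i \min(x_i, y_i)/(\sum x + \sum y)$ are computed on relative
abundances. Classical scaling double-centres $-D^2/2$ and
eigendecomposes. Bray–Curtis matrices are generally non-Euclidean, so
negative eigenvalues occur; the package drops them from the coordinates
and reports variance explained against the sum of *positive* eigenvalues,
flagging their presence. This matches the most common classical-scaling
convention; alternatives (Lingoes/Cailliez corrections) exist and would
change the percentages.

**Shared-taxon partition.** A taxon is "present" in a group when its
median relative abundance across the group's samples is positive —
equivalently, when it is detected in a strict majority of them. Region
counts over all group intersections sum to the size of the taxon universe.

**Co-existence matrix.** Restricted to taxa with at least 20 reads in more
than half of the newborns; for each taxon and dam site it reports the
fraction of dams reaching 20 reads among dams whose own calf carries the
taxon at 20 reads or more. Both cutoffs are inclusive at 20 (a 19-read
observation does not count).

## The synthetic study generator

`generate_study()` produces a complete, ground-truthed dataset with the
statistical structure the analysis assumes. Its generative model is:

* **Two communities per sample.** Every library mixes a sample-specific
  true community with a single reagent-contaminant community shared by all
  samples, in proportion to their 16S copy numbers:
  $w = \mathrm{copies}_{true}/(\mathrm{copies}_{true} +
  \mathrm{copies}_{contam})$, with reads drawn multinomially from
  $w\,\pi_{true} + (1-w)\,\pi_{contam}$. Negative controls have
  $\mathrm{copies}_{true} = 0$ and are pure contaminant.
* **Loads.** The reagent background defaults to $1.3\cdot10^5$ copies per
  swab and the newborn load to $5.7\cdot10^5$ (so roughly 19% of newborn
  reads are contaminant-derived in expectation, and the ratio of medians
  is about 4.4). First-day samples are set three to four orders of
  magnitude above the background (7000-fold the newborn load) and 7-day
  samples higher still, reflecting explosive post-natal colonisation.
  Adult body-site loads are not part of the emulated study's printed
  record; they default to $10^8$–$10^9$ copies per swab, typical
  high-biomass values at which reagent contamination is negligible.
* **Pools.** 160 true-community genotypes and 40 contaminant genotypes are
  drawn over a bank of realistic genera with RDP-style lineages; the
  contaminant bank is composed of typical reagent flora (*Ralstonia*,
  *Sphingomonas*, *Methylobacterium*, *Bradyrhizobium*, ...). A
  configurable fraction (default 10% of the smaller pool) of genotypes
  belongs to both communities ("shared" origin); every feature carries an
  authoritative origin label in the ground truth.
* **Community shapes.** Profiles are log-normal (a standard neutral choice
  for rank-abundance structure; the emulated study states no abundance
  model) with multiplicative role biases that make dam feces
  anaerobe-dominated, dam mouths dominated by oral genera, and the
  vestibule by its own flora; each dam's site profile is an individual
  perturbation of the site's base profile. First-day calf communities are
  collapsed onto a few facultative taxa (one *Escherichia/Shigella*
  genotype near 77%), and 7-day communities are anaerobe-enriched with
  intermediate diversity, so per-sample Shannon ordering newborn > 7 d >
  24 h emerges from the profiles rather than being asserted.
* **Planted vertical transmission.** Each paired newborn's true community
  is a weighted mixture of its own dam's three site profiles. The default
  weights are oral 0.75, vestibule 0.15, feces 0.10. The weighting is
  deliberately strong: rank correlations attenuate mixture weights, and
  the default is chosen so that the planted ordering (own-dam oral
  correlation highest) is recovered in at least 95% of replicate studies
  at the design's n = 10 pairs, making the ordering a property of the
  generator rather than of a lucky seed. Calves beyond the 10 paired ones
  draw from the population-level site profiles.
* **Sequencing depths** default to the per-group raw-read medians of the
  emulated design (about 21000 reads for a newborn sample, 77000 at 24 h,
  4500 for a control), with log-normal depth noise. qPCR measurements are
  the true total copies with log-normal measurement noise (sdlog 0.15);
  biological load variation uses sdlog 0.35.

Everything is deterministic given `seed`: one `set.seed()` at entry, all
draws from R's default Mersenne-Twister stream in a fixed order.

### What the generator does *not* emulate

* Pre-amplification cycle differences (21/18/15 cycles across groups) are
  recorded in the metadata but not modelled as abundance bias — no bias
  model is available to emulate.
* Contaminant-profile dispersion across control replicates: a single
  shared contaminant composition with multinomial noise is used. Real
  kit-lot variation would make the control profile overdispersed and the
  filter slightly less reliable than the simulation suggests.
* Genus-level absence structure: because genus aggregation pools many
  genotypes, most genera end up detectable in most groups, so shared-taxon
  partitions on synthetic data concentrate in the all-groups region,
  unlike real data where sites have exclusive genera. Tests of the
  partition logic therefore use constructed tables with planted absences.
* Sequence-level error, chimeras and classification error — the pipeline
  starts from a denoised count table by design.

Consequently, a passing test suite demonstrates that the *filtering
arithmetic and statistics* behave as specified under the emulated
conditions; it does not certify recovery rates on real data, where shared
taxa are more prevalent and the contaminant profile noisier.

## Numerical choices and degenerate inputs

* All-zero samples are flagged with a warning, never an error; their
  relative abundances are all-zero and their read fractions report as 0.
* All-empty negative controls are a hard error: the control profile, and
  with it decontamination, is undefined.
* Relative-abundance columns sum to 1 within $10^{-9}$; aggregation
  conserves integer totals exactly.
* PCoA treats eigenvalues below $10^{-8}$ of the spectral radius as zero;
  symmetry of the input is required up to $10^{-12}$.
* Studentized-range tail probabilities come from `ptukey`; the test suite
  cross-checks them against direct numerical integration of the range
  distribution.
* Spearman correlations on constant rank vectors, Shannon/Hill on all-zero
  vectors, and ratios over empty groups are explicit errors or flagged
  missing values, never silent numbers.

## Problem sizes used in validation

The shipped tests and the acceptance script run the full default design
(96 samples, roughly 200 genotypes, full per-group depths), 200-table
randomized equivalence checks against a brute-force filter oracle,
exhaustive $(3!)^4$ Friedman permutation enumerations, and 100 replicate
studies for the planted-ordering check. These sizes were chosen to
exercise every code path at the emulated study's scale while remaining
desk-scale computations.
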