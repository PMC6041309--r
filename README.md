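# lowbiome

Decontamination and analysis of low-biomass 16S rDNA amplicon data.

## The problem

Near-sterile specimens — meconium, newborn rectal swabs, biopsies of
supposedly sterile sites — carry so little microbial DNA that the
background DNA present in every extraction kit, PCR reagent and sampling
device contributes a substantial share of the sequenced reads. A library
from such a sample is a mixture of the true community and a
reagent-contaminant community, mixed roughly in proportion to their 16S
copy numbers. `lowbiome` is for microbiome researchers who need to remove
that background using empty-device negative controls, quantify how much
was removed, and then run the standard downstream analyses on the cleaned
table.

## The core rule

For feature *f* in sample *s*, with relative abundance *p(f,s)* in the
sample and *c(f)* in the pooled negative controls, the verdict is

| condition                  | verdict           | effect              |
|----------------------------|-------------------|---------------------|
| *c(f)* = 0                 | `sample_only`     | kept                |
| *p(f,s)* > τ·*c(f)*, τ = 4 | `accepted_shared` | kept in that sample |
| otherwise                  | `rejected`        | zeroed in that sample |

The inequality is strict ("more than four times") and the decision is made
per sample, so a genotype can be accepted where it is genuinely abundant
and rejected where it is background. Decontamination is followed by a
dataset-wide rarity filter (features with fewer than 250 reads across all
animal samples are dropped). Around this core the package provides qPCR
load comparison (ratio of group medians, Mann–Whitney U), Shannon/Hill
diversity, prevalence-and-abundance core-taxon tables, paired Spearman
correlations with Friedman + Nemenyi blocked tests, Bray–Curtis PCoA,
shared-taxon partitions, a dam–calf co-existence matrix, and a
ground-truthed synthetic study generator (21 calves × 3 time points,
10 dams × 3 body sites, 3 controls) for end-to-end validation.

## Worked example

```r
library(lowbiome)

st  <- generate_study(synthetic_config(seed = 42))   # 196 genotypes x 96 samples
res <- decontaminate(st$table, st$metadata, decontam_config())
res
#> decontam_result: 196 features x 93 samples (+3 controls)
#> mean read fractions: 93.9% sample-only, 0.6% accepted, 5.5% rejected

filt <- rarity_filter(res$filtered, 250, controls = control_ids(st$metadata))
nrow(filt$counts)
#> [1] 157

gen <- aggregate_taxa(subset_samples(filt,
         samples = setdiff(colnames(filt$counts), control_ids(st$metadata))),
       "genus")
pc <- paired_group_correlations(gen, st$metadata)
pc
#> paired_correlations: 10 blocks x 3 conditions
#>        dam_oral dam_feces dam_vestibule
#> median    0.647    -0.118         0.255
#> sd        0.051     0.106         0.048
friedman_test(pc$rho)
#> Friedman rank sum test: statistic = 20, df = 2, p = 4.54e-05
```

Reading the output: across all animal samples, 93.9% of reads belong to
genotypes never seen in the controls, 0.6% are shared with the controls
but accepted on the more-than-four-fold rule, and 5.5% are removed as
contamination (in the low-biomass newborn samples alone the removed share
is ~20%, matching their much lower bacterial load). After the rarity
filter, 157 of 196 genotypes remain. The paired Spearman correlations
recover the planted vertical-transmission structure: each newborn's
community correlates most with its own dam's oral community (median
ρ = 0.65) and the difference between dam sites is significant by the
Friedman test (χ² = 20, df = 2, p = 4.5·10⁻⁵).

The step-by-step analysis lives in `analysis/01_simulate.R` …
`analysis/05_similarity.R`; each script prints what it found and writes
its tables under `results/`.

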