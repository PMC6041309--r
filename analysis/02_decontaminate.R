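#!/usr/bin/env Rscript
# Remove reagent-contaminant genotypes using the negative controls: each
# genotype shared with the controls is kept in a sample only if its
# relative abundance there is more than four times its relative abundance
# in the pooled controls. Afterwards, genotypes seen fewer than 250 times
# across all animal samples are dropped. Evaluates the filter against the
# planted ground truth.

suppressPackageStartupMessages(library(lowbiome))

st <- generate_study(synthetic_config(seed = 42))
res <- decontaminate(st$table, st$metadata, decontam_config())
filt <- rarity_filter(res$filtered, 250, controls = control_ids(st$metadata))

rep_ <- decontamination_report(res, st$table, st$metadata)
write.table(rep_$per_sample, "results/decontam_per_sample.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(rep_$per_group, "results/decontam_per_group.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_feature_table(filt, "results/counts_decontaminated.tsv",
                    "results/taxonomy_decontaminated.tsv")

ev <- evaluate_recovery(st, res, st$table)
write.table(ev, "results/decontam_recovery.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

nb <- grepl("_newborn$", ev$sample_id)
cat(sprintf(
  "Newborn read classes (mean): %.1f%% sample-only, %.1f%% accepted-shared, %.1f%% rejected\n",
  100 * mean(res$read_fractions$sample_only[nb]),
  100 * mean(res$read_fractions$accepted_shared[nb]),
  100 * mean(res$read_fractions$rejected[nb])))
cat(sprintf(
  "Planted truth: %.2f%% of contaminant-only reads rejected, %.2f%% of true reads retained in newborns\n",
  100 * sum(ev$contaminant_reads[nb] * ev$contaminant_rejected_frac[nb],
            na.rm = TRUE) / sum(ev$contaminant_reads[nb]),
  100 * sum(ev$true_reads[nb] * ev$true_retained_frac[nb], na.rm = TRUE) /
    sum(ev$true_reads[nb])))
cat("Rarity filter kept", nrow(filt$counts), "of",
    nrow(res$filtered$counts), "genotypes\n")
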