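#!/usr/bin/env Rscript
# Generate the ground-truthed synthetic study that stands in for the raw
# sequencing data: 21 calves sampled at birth / 24 h / 7 d, 10 dams at
# three body sites, 3 empty-swab negative controls. Writes the count,
# taxonomy, metadata, qPCR and ground-truth tables consumed by the later
# steps.

suppressPackageStartupMessages(library(lowbiome))

dir.create("results", showWarnings = FALSE)
st <- generate_study(synthetic_config(seed = 42))

write_feature_table(st$table, "results/counts.tsv",
                    "results/taxonomy.tsv")
write.table(st$metadata, "results/metadata.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(st$qpcr, "results/qpcr.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(feature_id = names(st$truth$origin),
                       origin = unname(st$truth$origin)),
            "results/ground_truth_origin.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Study:", nrow(st$table$counts), "genotypes x",
    ncol(st$table$counts), "samples\n")
print(table(st$metadata$group))
cat("Reagent background:", format(st$config$contamination_copies),
    "16S copies per swab; newborn load",
    format(st$config$load_by_group[["newborn"]]), "copies\n")
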