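#!/usr/bin/env Rscript
# Cross-sample similarity: dam-calf Spearman correlations and their
# Friedman/Nemenyi comparison, Bray-Curtis PCoA of newborn + dam samples,
# shared-taxon Venn partition and the dam-calf co-existence matrix.

suppressPackageStartupMessages(library(lowbiome))

st <- generate_study(synthetic_config(seed = 42))
md <- st$metadata
res <- decontaminate(st$table, md, decontam_config())
filt <- rarity_filter(res$filtered, 250, controls = control_ids(md))
gen <- aggregate_taxa(
  subset_samples(filt, samples = setdiff(colnames(filt$counts),
                                         control_ids(md))), "genus")

pc <- paired_group_correlations(gen, md, calf_group = "newborn")
write.table(data.frame(calf = rownames(pc$rho), pc$rho),
            "results/dam_calf_spearman.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Median own-dam Spearman rho by site:\n")
print(round(pc$medians, 2))
ft <- friedman_test(pc$rho)
cat(sprintf("Friedman across sites: chi2 = %.1f, df = %d, p = %.3g\n",
            ft$statistic, ft$df, ft$p))
print(round(nemenyi_posthoc(pc$rho), 4))

ids <- md$sample_id[md$group %in% c("newborn", "dam_oral", "dam_feces",
                                    "dam_vestibule")]
ord <- pcoa(bray_curtis_matrix(subset_samples(gen, samples = ids)))
coords <- data.frame(sample_id = rownames(ord$coordinates),
                     group = md$group[match(rownames(ord$coordinates),
                                            md$sample_id)],
                     ord$coordinates[, 1:2])
write.table(coords, "results/pcoa_coordinates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("PCoA axis 1 explains %.1f%%, axis 2 %.1f%% of the variance\n",
            ord$variance_explained[1], ord$variance_explained[2]))

part <- shared_taxa_partition(gen, md, c("newborn", "dam_oral",
                                         "dam_feces", "dam_vestibule"))
cat("Shared-taxon regions (taxa with median abundance > 0 per group):\n")
print(part$regions[part$regions > 0])
writeLines(jsonlite::toJSON(as.list(part$regions), auto_unbox = TRUE,
                            pretty = TRUE),
           "results/venn_regions.json")

cx <- coexistence_matrix(gen, md)
write.table(data.frame(taxon = rownames(cx$matrix), cx$matrix,
                       calf_occurrence = cx$calf_occurrence),
            "results/coexistence_matrix.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Co-existence matrix: %d taxa x %d dam sites (cutoff >= 20 reads)\n",
            nrow(cx$matrix), ncol(cx$matrix)))
cat("Mean co-existence fraction by dam site:\n")
print(round(colMeans(cx$matrix, na.rm = TRUE), 2))
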