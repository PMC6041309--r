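Package: lowbiome
Title: Low-Biomass 16S Microbiota Decontamination and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for low-biomass 16S rDNA amplicon studies:
    negative-control based removal of reagent contaminant sequences using a
    per-sample relative-abundance ratio test, dataset-wide rarity filtering,
    qPCR bacterial load quantification, alpha diversity (Shannon and Hill
    numbers), core-taxon detection by prevalence and median abundance,
    Bray-Curtis ordination, blocked nonparametric comparisons (Friedman and
    Nemenyi), shared-taxon partitions and dam-calf co-existence analysis.
    Includes a ground-truthed synthetic study generator that emulates the
    design of a calf meconium / dam body-site microbiota study, so every
    pipeline stage can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), vegan, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
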