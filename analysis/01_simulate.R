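#!/usr/bin/env Rscript
# Simulate the study's band table: 4 groups (normal n=6, fluoxetine n=8,
# MD n=6, fluoxetine+MD n=8), 12 synaptic proteins + GAPDH, 28 animals dealt
# across 4 blots (2 blot sets), multiplicative blot-batch and per-lane
# loading factors, plus a pooled control-sample lane per blot.
library(blotmc)

dir.create("results", showWarnings = FALSE)
design <- default_design(seed = 20260925L)
tab <- generate_table(design)

write_band_table(tab, "results/band_table.tsv")
message("band table: ", nrow(tab), " rows (",
        length(unique(tab$animal_id[tab$group != "control"])), " animals x ",
        length(design$proteins), " proteins + control lanes) -> ",
        "results/band_table.tsv")

truth <- data.frame(group = rep(rownames(design$effect),
                                ncol(design$effect)),
                    protein = rep(colnames(design$effect),
                                  each = nrow(design$effect)),
                    true_mean = as.vector(design$effect),
                    true_sd = as.vector(design$noise_sd))
utils::write.table(truth, "results/design_truth.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("design truth (fold-of-normal effects, SEM-derived SDs) -> ",
        "results/design_truth.tsv")
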