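#!/usr/bin/env Rscript
# Contrast indices of functional protein pairs, computed within animal:
# AMPAR-NMDAR (GluA2 vs GluN1), NMDAR subunits (GluN2A vs GluN2B), GABA-A
# subunits (alpha1 vs alpha3), presynaptic E/I (VGLUT1 vs VGAT) and
# postsynaptic E/I (PSD-95 vs gephyrin).
library(blotmc)

tab <- read_band_table("results/band_table.tsv")
nt <- normalize_blots(tab, blot_sets = c(B1 = 1L, B2 = 1L, B3 = 2L, B4 = 2L),
                      reference_group = "normal")
it <- compute_indices(nt)
is <- summarize_groups(it)
utils::write.table(it, "results/indices.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(is, "results/index_summaries.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
pre <- is[is$measure == "presynaptic_EI", ]
message("per-animal indices for ", length(unique(it$index)), " balances -> ",
        "results/indices.tsv")
message("presynaptic E/I group means: ",
        paste(sprintf("%s %.3f", pre$group, pre$mean), collapse = ", "))
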