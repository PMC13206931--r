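#!/usr/bin/env Rscript
# Stage 3: fold changes on TMM-normalized abundances and UP/DOWN calls at
# |log2FC| > 1 for the three comparisons (six directional sets).
# Reads results/normalization/, writes results/differential/.

library(evcargo)

rc <- read_counts("results/sim/counts.tsv", "results/sim/design.tsv")
norm <- read_table("results/normalization/normalized_counts.tsv")
abund <- as.matrix(norm[, -1])
rownames(abund) <- norm$mirna_id

sets <- classify_all(abund, rc$design)

dir.create("results/differential", recursive = TRUE, showWarnings = FALSE)
for (lab in names(sets)) {
  write_table(sets[[lab]]$table, file.path("results/differential",
                                           paste0("de_", lab, ".tsv")))
  writeLines(sets[[lab]]$up, file.path("results/differential",
                                       paste0("up_", lab, ".txt")))
  writeLines(sets[[lab]]$down, file.path("results/differential",
                                         paste0("down_", lab, ".txt")))
  message(lab, ": ", length(sets[[lab]]$up), " up, ",
          length(sets[[lab]]$down), " down, ",
          sum(sets[[lab]]$table$call == "UNCHANGED"), " unchanged")
}
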