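#!/usr/bin/env Rscript
# Stage 6: per-gene connectivity over the significant muscle-filtered terms
# of every (comparison, direction) column, the annotated top-25 hub matrix
# and head-20 target-frequency tables.
# Reads results/enrichment/, writes results/hubs/.

library(evcargo)

ann <- read_gmt("results/sim/annotation.gmt")
sig_files <- list.files("results/enrichment", pattern = "^significant_.*\\.tsv$")
dir.create("results/hubs", recursive = TRUE, showWarnings = FALSE)

scores <- list()
for (sf in sig_files) {
  col <- sub("^significant_(.*)\\.tsv$", "\\1", sf)
  tab <- read_table(file.path("results/enrichment", sf))
  # member hits were serialized comma-collapsed; rebuild the list column
  tab$member_hits <- strsplit(as.character(tab$member_hits), ",", fixed = TRUE)
  scores[[col]] <- connectivity(tab)
  write_table(target_frequency_table(tab),
              file.path("results/hubs", paste0("target_frequency_", col, ".tsv")))
}

hm <- build_hub_matrix(scores, top_n = 25, family_table = read_family_table())
write_table(as.data.frame(hm), "results/hubs/hub_matrix.tsv")

top <- sort(apply(hm$scores, 1, max), decreasing = TRUE)
message("top hub genes by max connectivity: ",
        paste(sprintf("%s=%d", names(top)[1:5], top[1:5]), collapse = ", "))
message("hub matrix: ", nrow(hm$scores), " genes x ", ncol(hm$scores), " columns")
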