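#!/usr/bin/env Rscript
# Stage 2: TMM normalization and the CPM > 15 low-expression filter.
# Reads results/sim/, writes results/normalization/.

library(evcargo)

rc <- read_counts("results/sim/counts.tsv", "results/sim/design.tsv")
nf <- normalize_and_filter(rc$counts, rc$design)

dir.create("results/normalization", recursive = TRUE, showWarnings = FALSE)
write_table(data.frame(sample_id = rc$counts$sample_ids,
                       library_size = rc$counts$library_sizes,
                       tmm_factor = nf$norm$tmm_factor,
                       effective_library_size = nf$norm$effective_library_size),
            "results/normalization/tmm_factors.tsv")
write_table(data.frame(mirna_id = rownames(nf$filter$group_cpm),
                       nf$filter$group_cpm,
                       kept = rownames(nf$filter$group_cpm) %in% nf$filter$kept_ids,
                       check.names = FALSE),
            "results/normalization/filter_report.tsv")
abund <- nf$norm$normalized[nf$filter$kept_ids, , drop = FALSE]
write_table(data.frame(mirna_id = rownames(abund), abund, check.names = FALSE),
            "results/normalization/normalized_counts.tsv")

message("TMM reference sample: ", nf$norm$reference_sample)
message("TMM factors: ",
        paste(sprintf("%s=%.4f", names(nf$norm$tmm_factor), nf$norm$tmm_factor),
              collapse = ", "))
message("kept ", length(nf$filter$kept_ids), " of ",
        length(rc$counts$mirna_ids), " miRNAs at group CPM > ",
        nf$filter$threshold_cpm)
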