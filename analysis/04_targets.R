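#!/usr/bin/env Rscript
# Stage 4: aggregate the three target-database extracts and map each
# directional miRNA set to its gene branches: suppressed (targets of UP
# miRNAs) and derepressed (targets of DOWN miRNAs).
# Reads results/differential/, writes results/targets/.

library(evcargo)

db_paths <- list.files("results/sim", pattern = "^targets_.*\\.tsv$",
                       full.names = TRUE)
db <- load_target_db(db_paths)

labs <- sub("^up_(.*)\\.txt$", "\\1",
            list.files("results/differential", pattern = "^up_.*\\.txt$"))
sets <- lapply(labs, function(lab) list(
  up = readLines(file.path("results/differential", paste0("up_", lab, ".txt"))),
  down = readLines(file.path("results/differential", paste0("down_", lab, ".txt")))))
names(sets) <- labs

tmap <- map_directional_targets(sets, db)

dir.create("results/targets", recursive = TRUE, showWarnings = FALSE)
for (lab in labs) for (dir in c("suppressed", "derepressed")) {
  ts <- tmap[[lab]][[dir]]
  write_table(ts$records,
              file.path("results/targets", paste0(lab, "_", dir, "_records.tsv")))
  writeLines(ts$genes,
             file.path("results/targets", paste0(lab, "_", dir, "_genes.txt")))
  message(lab, " ", dir, ": ", length(ts$genes), " genes (",
          nrow(ts$records), " supporting records)")
}
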