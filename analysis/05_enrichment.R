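#!/usr/bin/env Rscript
# Stage 5: hypergeometric biological-process enrichment of every directional
# branch, BH adjustment over all tested terms, the two-stage capture
# (p <= 0.5) / report (q < 0.05) split, and muscle keyword filtering.
# Reads results/targets/, writes results/enrichment/.

library(evcargo)

ann <- read_gmt("results/sim/annotation.gmt")
dir.create("results/enrichment", recursive = TRUE, showWarnings = FALSE)

gene_files <- list.files("results/targets", pattern = "_genes\\.txt$")
for (gf in gene_files) {
  col <- sub("_genes\\.txt$", "", gf)
  genes <- readLines(file.path("results/targets", gf))
  rows <- add_q(suppressMessages(hypergeom_enrich(genes, ann)))
  stages <- two_stage_filter(rows)
  captured <- keyword_filter(stages$captured)
  significant <- keyword_filter(stages$significant)
  direction <- if (grepl("suppressed$", col)) "SUPPRESSED" else "DEREPRESSED"
  write_table(captured[setdiff(names(captured), "member_hits")],
              file.path("results/enrichment", paste0("captured_", col, ".tsv")))
  write_table(significant,
              file.path("results/enrichment", paste0("significant_", col, ".tsv")))
  write_table(dotplot_table(significant, direction, col),
              file.path("results/enrichment", paste0("dotplot_", col, ".tsv")))
  message(col, ": ", nrow(rows), " terms tested, ",
          nrow(captured), " captured muscle terms, ",
          nrow(significant), " significant muscle terms (q < 0.05)")
}
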