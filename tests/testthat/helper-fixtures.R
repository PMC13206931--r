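# Small in-code fixtures shared across test files.

toy_counts_matrix <- function() {
  m <- matrix(c(10, 20, 30,
                5, 10, 15,
                100, 200, 300), nrow = 3, byrow = TRUE,
              dimnames = list(c("miR-a", "miR-b", "miR-c"),
                              c("s1", "s2", "s3")))
  m
}

toy_design_df <- function() {
  data.frame(sample_id = c("s1", "s2", "s3"),
             group = c("control", "lowHz", "highHz"),
             stringsAsFactors = FALSE)
}

write_counts_tsv <- function(mat, path, id_col = "mirna") {
  df <- data.frame(mat2 = rownames(mat), as.data.frame(mat), check.names = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_design_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_annotation <- function(terms) {
  # terms: named list term_id -> list(name=, genes=)
  structure(list(term_id = names(terms),
                 term_name = vapply(terms, `[[`, character(1), "name"),
                 genes = lapply(terms, `[[`, "genes"),
                 universe = sort(unique(unlist(lapply(terms, `[[`, "genes"))))),
            class = "ev_annotation")
}

toy_enrich_rows <- function(term_ids, hit_sets, q = NULL) {
  df <- data.frame(term_id = term_ids,
                   term_name = term_ids,
                   p = rep(0.01, length(term_ids)),
                   stringsAsFactors = FALSE)
  df$member_hits <- hit_sets
  df$q <- if (is.null(q)) rep(0.01, length(term_ids)) else q
  df
}
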