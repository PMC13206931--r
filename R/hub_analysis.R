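#' Per-gene connectivity scores from significant enrichment rows
#'
#' A gene's connectivity in one (comparison, direction) column is the number
#' of distinct significant muscle-filtered terms whose hit set contains it,
#' i.e. the total number of discrete biological processes it influences.
#' Genes absent from every term score 0 (and are simply absent from the
#' returned vector).
#'
#' @param rows enrichment rows for one (comparison, direction) with a
#'   `member_hits` list column; duplicate `term_id`s are collapsed first.
#' @return named integer vector gene -> score, sorted by decreasing score
#'   then symbol.
#' @export
connectivity <- function(rows) {
  if (is.null(rows$member_hits)) stop("rows must carry member_hits")
  rows <- rows[!duplicated(rows$term_id), , drop = FALSE]
  if (!nrow(rows)) return(stats::setNames(integer(), character()))
  hits <- unlist(lapply(rows$member_hits, unique))
  tab <- table(hits)
  score <- stats::setNames(as.integer(tab), names(tab))
  score[order(-score, names(score))]
}

#' Build the annotated hub-gene connectivity matrix
#'
#' Assembles the per-column connectivity scores into a genes x
#' (comparison, direction) matrix, selects the `top_n` hub genes ranked by
#' maximum score across columns (ties broken by total score, then by
#' symbol), attaches a signaling-family label per gene, and orders rows by
#' complete-linkage hierarchical clustering of the score vectors (Euclidean
#' distance) so co-regulated hubs cluster together. The clustering input is
#' in alphabetical symbol order, making the leaf order fully deterministic.
#'
#' @param scores named list of connectivity vectors from [connectivity()],
#'   one element per column; names become column names. At least one
#'   column must be non-empty.
#' @param top_n number of hub genes to keep (default 25).
#' @param family_table optional data.frame with columns `gene`, `family`;
#'   genes without an entry are labelled "unannotated".
#' @return object of class `ev_hub_matrix`: list with `scores` (integer
#'   matrix, clustered row order) and `family` (named character vector).
#' @export
build_hub_matrix <- function(scores, top_n = 25L, family_table = NULL) {
  stopifnot(is.list(scores), length(scores) >= 1L)
  genes <- sort(unique(unlist(lapply(scores, names))))
  if (!length(genes)) stop("all connectivity columns are empty")
  mat <- matrix(0L, nrow = length(genes), ncol = length(scores),
                dimnames = list(genes, names(scores)))
  for (j in seq_along(scores)) {
    s <- scores[[j]]
    if (length(s)) mat[names(s), j] <- as.integer(s)
  }
  mx <- apply(mat, 1L, max)
  tot <- rowSums(mat)
  sel <- genes[order(-mx, -tot, genes)]
  sel <- utils::head(sel, top_n)
  sub <- mat[sort(sel), , drop = FALSE]
  if (nrow(sub) > 2L) {
    hc <- stats::hclust(stats::dist(sub, method = "euclidean"), method = "complete")
    sub <- sub[hc$order, , drop = FALSE]
  }
  fam <- rep("unannotated", nrow(sub))
  names(fam) <- rownames(sub)
  if (!is.null(family_table)) {
    stopifnot(all(c("gene", "family") %in% names(family_table)))
    hit <- rownames(sub) %in% family_table$gene
    fam[hit] <- family_table$family[match(rownames(sub)[hit], family_table$gene)]
  }
  structure(list(scores = sub, family = fam), class = "ev_hub_matrix")
}

#' @export
print.ev_hub_matrix <- function(x, ...) {
  cat("ev_hub_matrix:", nrow(x$scores), "hub genes x", ncol(x$scores), "columns\n")
  print(utils::head(cbind(as.data.frame(x$scores), family = x$family), 10L))
  invisible(x)
}

#' @export
as.data.frame.ev_hub_matrix <- function(x, ...) {
  cbind(data.frame(gene = rownames(x$scores), family = unname(x$family),
                   stringsAsFactors = FALSE),
        as.data.frame(x$scores))
}

#' Top target-frequency table for one column
#'
#' The bar-plot backbone: the `head_n` genes with the highest connectivity
#' (target frequency) in one (comparison, direction) column.
#'
#' @param rows enrichment rows, as in [connectivity()].
#' @param head_n number of genes to report (default 20).
#' @return data.frame with columns `gene`, `score`, ranked.
#' @export
target_frequency_table <- function(rows, head_n = 20L) {
  s <- connectivity(rows)
  s <- utils::head(s, head_n)
  data.frame(gene = names(s), score = as.integer(s),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a gene-to-signaling-family lookup table
#'
#' A deterministic, user-editable replacement for semantic grouping of hub
#' genes into signaling families. A small default table covering well-known
#' myogenic hubs (Mef2c, Gata4, Pak1, Camk2d, Igf1, Edn1, Nfatc3) ships with
#' the package under `extdata/families.tsv`.
#'
#' @param path TSV with columns `gene`, `family`; default the shipped table.
#' @return data.frame.
#' @export
read_family_table <- function(path = system.file("extdata", "families.tsv",
                                                 package = "evcargo")) {
  utils::read.delim(path, sep = "\t", header = TRUE, colClasses = "character")
}
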