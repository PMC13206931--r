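#' Load and aggregate miRNA-to-gene target interaction extracts
#'
#' Reads one or more TSV extracts (columns `mirna`, `gene`, `source`,
#' `evidence`, optional `score`) emulating the aggregation of validated
#' (e.g. luciferase/CLIP-supported) and high-confidence predicted
#' interaction databases, and returns their de-duplicated union with full
#' provenance: one record per distinct (mirna, gene, source) triple.
#'
#' @param paths character vector of TSV paths.
#' @param min_score optional numeric; drop PREDICTED records whose `score`
#'   is below it (validated records are never score-filtered).
#' @return data.frame with columns `mirna`, `gene`, `source`, `evidence`,
#'   `score`, de-duplicated and row-ordered deterministically.
#' @export
load_target_db <- function(paths, min_score = NULL) {
  recs <- lapply(paths, function(p) {
    df <- utils::read.delim(p, sep = "\t", header = TRUE, check.names = FALSE,
                            colClasses = "character")
    if (nrow(df) == 0L) {
      warning("empty target extract skipped: ", p)
      return(NULL)
    }
    need <- c("mirna", "gene", "source", "evidence")
    if (!all(need %in% names(df)))
      stop("target extract ", p, " lacks column(s): ",
           paste(setdiff(need, names(df)), collapse = ", "))
    df$score <- if ("score" %in% names(df)) suppressWarnings(as.numeric(df$score)) else NA_real_
    bad <- setdiff(unique(df$evidence), c("VALIDATED", "PREDICTED"))
    if (length(bad))
      stop("unknown evidence label(s) in ", p, ": ", paste(bad, collapse = ", "),
           " (expected VALIDATED or PREDICTED)")
    df[, c("mirna", "gene", "source", "evidence", "score")]
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs) || nrow(recs) == 0L) stop("no target records loaded")
  recs <- recs[!duplicated(recs[, c("mirna", "gene", "source")]), , drop = FALSE]
  if (!is.null(min_score)) {
    drop <- recs$evidence == "PREDICTED" & !is.na(recs$score) & recs$score < min_score
    recs <- recs[!drop, , drop = FALSE]
  }
  recs <- recs[order(recs$mirna, recs$gene, recs$source), , drop = FALSE]
  rownames(recs) <- NULL
  n_src <- table(recs$source)
  message("target DB: ", nrow(recs), " records from ",
          paste(sprintf("%s=%d", names(n_src), as.integer(n_src)), collapse = ", "))
  recs
}

#' Read a symbol alias table
#' @param path TSV with columns `alias`, `canonical`.
#' @return named character vector mapping alias -> canonical symbol.
#' @export
read_alias_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, colClasses = "character")
  stopifnot(all(c("alias", "canonical") %in% names(df)))
  stats::setNames(df$canonical, df$alias)
}

#' Canonicalize gene symbols against an alias table
#' @param genes character vector of symbols.
#' @param alias named vector from [read_alias_table()], or `NULL` (identity).
#' @return character vector with aliases replaced by canonical symbols.
#' @export
canonical_symbols <- function(genes, alias = NULL) {
  if (is.null(alias) || !length(alias)) return(genes)
  hit <- genes %in% names(alias)
  genes[hit] <- unname(alias[genes[hit]])
  genes
}

#' Map a directional miRNA set to its target genes
#'
#' Union of targets over all miRNAs in the set, with the supporting records
#' retained per gene. miRNAs absent from the database contribute nothing
#' (reported via message, not an error). Genes targeted by UPregulated
#' miRNAs feed the "suppressed" branch downstream (predicted inhibitory
#' pressure); genes targeted by DOWNregulated miRNAs feed the "derepressed"
#' branch (release of inhibition).
#'
#' @param mirnas character vector of miRNA identifiers (a directional set).
#' @param db records from [load_target_db()].
#' @param alias optional alias map from [read_alias_table()].
#' @param min_sources keep only genes supported by at least this many
#'   distinct source databases (default 1, pure union).
#' @return object of class `ev_targets`: list with `genes` (sorted unique
#'   symbols) and `records` (the supporting rows, symbols canonicalized).
#' @export
map_targets <- function(mirnas, db, alias = NULL, min_sources = 1L) {
  recs <- db[db$mirna %in% mirnas, , drop = FALSE]
  absent <- setdiff(mirnas, db$mirna)
  if (length(absent))
    message(length(absent), " miRNA(s) absent from target DB: ",
            paste(utils::head(absent, 5L), collapse = ", "),
            if (length(absent) > 5L) ", ..." else "")
  recs$gene <- canonical_symbols(recs$gene, alias)
  recs <- recs[!duplicated(recs[, c("mirna", "gene", "source")]), , drop = FALSE]
  if (min_sources > 1L && nrow(recs)) {
    n_src <- tapply(recs$source, recs$gene, function(s) length(unique(s)))
    recs <- recs[recs$gene %in% names(n_src)[n_src >= min_sources], , drop = FALSE]
  }
  rownames(recs) <- NULL
  structure(list(genes = sort(unique(recs$gene)), records = recs),
            class = "ev_targets")
}

#' @export
print.ev_targets <- function(x, ...) {
  cat("ev_targets:", length(x$genes), "genes,", nrow(x$records), "supporting records\n")
  invisible(x)
}

#' Map UP and DOWN sets of every comparison to directional target branches
#'
#' @param sets result of [classify_all()] (list with `up`/`down` per
#'   comparison label).
#' @param db,alias,min_sources as in [map_targets()].
#' @return nested list `[[comparison]][[c("suppressed","derepressed")]]` of
#'   `ev_targets`: suppressed = targets of UP miRNAs, derepressed = targets
#'   of DOWN miRNAs. A gene may appear in both branches.
#' @export
map_directional_targets <- function(sets, db, alias = NULL, min_sources = 1L) {
  lapply(sets, function(s) list(
    suppressed  = map_targets(s$up,   db, alias, min_sources),
    derepressed = map_targets(s$down, db, alias, min_sources)))
}
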