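#' Construct a validated miRNA count matrix
#'
#' Wraps an integer matrix of raw small-RNA-seq counts (miRNAs in rows,
#' samples in columns) after checking the invariants the downstream
#' normalization assumes: non-negative integral counts, unique miRNA and
#' sample identifiers, and at least two samples. Rows that are all zero are
#' retained; low-expression filtering happens downstream on CPM.
#'
#' @param counts numeric matrix with rownames (mature miRNA identifiers,
#'   treated as case-sensitive opaque strings) and colnames (sample names).
#' @return An object of class `ev_counts`: a list with elements `counts`
#'   (integer matrix), `mirna_ids`, `sample_ids` and `library_sizes`
#'   (per-sample column sums).
#' @export
ev_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must carry miRNA rownames and sample colnames")
  if (ncol(counts) < 2L)
    stop("at least 2 samples are required, got ", ncol(counts))
  dup_r <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup_r))
    stop("duplicate miRNA identifier(s): ", paste(unique(dup_r), collapse = ", "))
  dup_c <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup_c))
    stop("duplicate sample identifier(s): ", paste(unique(dup_c), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-integer or negative count at row '%s', column '%s'",
                 rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]))
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max in pools
  structure(
    list(counts = counts,
         mirna_ids = rownames(counts),
         sample_ids = colnames(counts),
         library_sizes = colSums(counts)),
    class = "ev_counts")
}

#' @export
print.ev_counts <- function(x, ...) {
  cat("ev_counts:", length(x$mirna_ids), "miRNAs x", length(x$sample_ids), "samples\n")
  cat("library sizes:", paste(sprintf("%s=%g", x$sample_ids, x$library_sizes),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Construct a group design
#'
#' Maps each sample to exactly one experimental group and records the ordered
#' pairwise comparisons (numerator group vs denominator group) the analysis
#' will run. In the pooled study design each group is represented by a single
#' pooled column, but replicated groups are supported.
#'
#' @param samples data.frame with columns `sample_id` and `group`.
#' @param comparisons list of length-2 character vectors
#'   `c(numerator, denominator)`, or strings `"numerator:denominator"`.
#'   Defaults to [default_comparisons()] over the groups in order of first
#'   appearance.
#' @return An object of class `ev_design`.
#' @export
ev_design <- function(samples, comparisons = NULL) {
  stopifnot(is.data.frame(samples), all(c("sample_id", "group") %in% names(samples)))
  samples$sample_id <- as.character(samples$sample_id)
  samples$group <- as.character(samples$group)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in design: ",
         samples$sample_id[duplicated(samples$sample_id)][1L])
  groups <- unique(samples$group)
  if (is.null(comparisons)) comparisons <- default_comparisons(groups)
  comparisons <- lapply(comparisons, function(cmp) {
    if (is.character(cmp) && length(cmp) == 1L) cmp <- strsplit(cmp, ":", fixed = TRUE)[[1L]]
    if (length(cmp) != 2L) stop("a comparison must be a (numerator, denominator) pair")
    if (!all(cmp %in% groups))
      stop("comparison references undeclared group: ",
           paste(setdiff(cmp, groups), collapse = ", "))
    if (cmp[1L] == cmp[2L]) stop("numerator and denominator groups must differ: ", cmp[1L])
    as.character(cmp)
  })
  structure(list(samples = samples, groups = groups, comparisons = comparisons),
            class = "ev_design")
}

#' Default pairwise comparisons for a declared group order
#'
#' Every later group against every earlier one, preserving declaration order:
#' for `c("control", "lowHz", "highHz")` this yields lowHz vs control,
#' highHz vs control and highHz vs lowHz -- the three comparison pairs whose
#' UP/DOWN splits form the six comparative groups of the study design.
#'
#' @param groups character vector of group labels in declaration order.
#' @return list of `c(numerator, denominator)` pairs.
#' @export
default_comparisons <- function(groups) {
  out <- list()
  for (j in seq_along(groups)) for (i in seq_len(j - 1L))
    out[[length(out) + 1L]] <- c(groups[j], groups[i])
  out
}

#' @export
print.ev_design <- function(x, ...) {
  cat("ev_design:", nrow(x$samples), "samples,", length(x$groups), "groups (",
      paste(x$groups, collapse = ", "), ")\n")
  for (cmp in x$comparisons) cat("  comparison:", cmp[1L], "vs", cmp[2L], "\n")
  invisible(x)
}

#' Label for a comparison pair
#' @param comparison length-2 character vector `c(numerator, denominator)`.
#' @return a string `"numerator_vs_denominator"`.
#' @export
comparison_label <- function(comparison) paste(comparison, collapse = "_vs_")

#' Read a count matrix and its group design from TSV files
#'
#' The counts file is tab-separated with a header row of sample names and the
#' miRNA identifier in the first column; the design file has columns
#' `sample_id` and `group`. Numbers may carry thousands commas (as in
#' published tables); they are stripped on ingest. Design samples must all be
#' present in the matrix; matrix columns are reordered to design order.
#'
#' @param path counts TSV path.
#' @param design_path design TSV path; `NULL` to return counts only.
#' @param comparisons passed to [ev_design()].
#' @return `list(counts = ev_counts, design = ev_design)`, or just the
#'   `ev_counts` when `design_path` is `NULL`.
#' @export
read_counts <- function(path, design_path = NULL, comparisons = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 3L) stop("counts file needs an ID column plus >=2 sample columns")
  ids <- raw[[1L]]
  num <- vapply(raw[-1L], function(col) {
    col <- gsub(",", "", col, fixed = TRUE)
    suppressWarnings(as.numeric(col))
  }, numeric(nrow(raw)))
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(ids, names(raw)[-1L]))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("unparseable count at row '%s', column '%s' of %s",
                 ids[bad[1L, 1L]], colnames(num)[bad[1L, 2L]], path))
  cm <- ev_counts(num)
  if (is.null(design_path)) return(cm)
  des <- utils::read.delim(design_path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  missing <- setdiff(des$sample_id, cm$sample_ids)
  if (length(missing))
    stop("design sample(s) missing from count matrix: ", paste(missing, collapse = ", "))
  cm <- ev_counts(cm$counts[, des$sample_id, drop = FALSE])
  list(counts = cm, design = ev_design(des, comparisons = comparisons))
}

#' Write a tabular result as TSV
#'
#' Fixed column order (as given), UTF-8, tab separators, `.` decimal mark,
#' newline-terminated, no quoting. Floating point columns are serialized with
#' an explicit precision so reruns are byte-identical; list columns (e.g.
#' enrichment member hits) are collapsed with commas.
#'
#' @param rows data.frame (may have zero rows: a header-only file is written).
#' @param path output path.
#' @param digits significant digits for numeric (non-integer) columns.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, digits = 7L) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out)) {
    col <- out[[j]]
    if (is.list(col)) {
      out[[j]] <- vapply(col, function(v) paste(v, collapse = ","), character(1L))
    } else if (is.double(col)) {
      out[[j]] <- ifelse(is.na(col), "NA", sprintf(paste0("%.", digits, "g"), col))
    }
  }
  con <- file(path, open = "wb")  # binary: fixed '\n' endings on every platform
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

#' Read back a TSV written by [write_table()]
#' @param path TSV path.
#' @return data.frame with `read.delim` type inference.
#' @export
read_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
}
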