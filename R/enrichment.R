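#' Read a gene-set annotation in GMT format
#'
#' One term per line: `term_id TAB term_name TAB gene1 TAB gene2 ...`.
#' The enrichment universe is the union of all member genes.
#'
#' @param path GMT file path.
#' @return object of class `ev_annotation`: list with `term_id`,
#'   `term_name`, `genes` (list of character vectors) and `universe`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("malformed GMT line (need id, name, >=1 gene): line ", short[1L])
  ann <- list(term_id = vapply(fields, `[[`, character(1L), 1L),
              term_name = vapply(fields, `[[`, character(1L), 2L),
              genes = lapply(fields, function(f) unique(f[-(1:2)])))
  if (anyDuplicated(ann$term_id))
    stop("duplicate term_id in GMT: ", ann$term_id[duplicated(ann$term_id)][1L])
  ann$universe <- sort(unique(unlist(ann$genes)))
  structure(ann, class = "ev_annotation")
}

#' Write a gene-set annotation in GMT format
#' @param ann `ev_annotation` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(ann, path) {
  stopifnot(inherits(ann, "ev_annotation"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(vapply(seq_along(ann$term_id), function(i) {
    paste(c(ann$term_id[i], ann$term_name[i], ann$genes[[i]]), collapse = "\t")
  }, character(1L)), con)
  invisible(path)
}

#' @export
print.ev_annotation <- function(x, ...) {
  cat("ev_annotation:", length(x$term_id), "terms,",
      length(x$universe), "genes in universe\n")
  invisible(x)
}

#' Hypergeometric over-representation test per term
#'
#' For a query of n genes (after intersecting with the universe of N
#' annotated genes) and a term of K members with k query hits, the
#' upper-tail probability is
#' `p = sum_{i=k}^{min(K,n)} C(K,i) C(N-K, n-i) / C(N,n)`,
#' evaluated via [stats::phyper()]. Terms with no hits (k = 0) are not
#' reported. Two gene-ratio conventions are emitted: `gene_ratio` is k/K
#' (query hits over term size, the convention used for the dot plots here)
#' and `gene_ratio_query` is k/n.
#'
#' @param query character vector of gene symbols; genes outside the universe
#'   are dropped with a message.
#' @param ann [read_gmt()] annotation.
#' @param min_size,max_size term-size bounds K in `[min_size, max_size]`
#'   (defaults 5 and 2000) applied before testing.
#' @return data.frame with columns `term_id`, `term_name`, `k`, `K`, `n`,
#'   `N`, `p`, `gene_ratio`, `gene_ratio_query` and list column
#'   `member_hits` (the k hit genes, sorted).
#' @export
hypergeom_enrich <- function(query, ann, min_size = 5L, max_size = 2000L) {
  stopifnot(inherits(ann, "ev_annotation"))
  N <- length(ann$universe)
  sizes <- lengths(ann$genes)
  if (any(sizes > N)) stop("annotation corrupt: term larger than universe")
  query <- unique(query)
  eff <- intersect(query, ann$universe)
  n_out <- length(query) - length(eff)
  if (n_out > 0L) message(n_out, " query gene(s) outside the annotation universe dropped")
  empty <- data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(), N = integer(),
                      p = numeric(), gene_ratio = numeric(),
                      gene_ratio_query = numeric(), stringsAsFactors = FALSE)
  empty$member_hits <- list()
  if (!length(eff)) {
    warning("empty effective query: no enrichment computed")
    return(empty)
  }
  n <- length(eff)
  use <- which(sizes >= min_size & sizes <= max_size)
  hits <- lapply(ann$genes[use], function(g) sort(intersect(g, eff)))
  k <- lengths(hits)
  keep <- k >= 1L
  use <- use[keep]; hits <- hits[keep]; k <- k[keep]
  if (!length(use)) return(empty)
  K <- sizes[use]
  out <- data.frame(term_id = ann$term_id[use], term_name = ann$term_name[use],
                    k = as.integer(k), K = as.integer(K), n = n, N = N,
                    p = stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
                    gene_ratio = k / K, gene_ratio_query = k / n,
                    stringsAsFactors = FALSE)
  out$member_hits <- hits
  rownames(out) <- NULL
  out[order(out$p, out$term_id), , drop = FALSE]
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min_{j >= i} (p_(j) * m / j)`, clipped to 1, returned in input
#' order (delegates to [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Attach BH q-values to an enrichment table
#'
#' Adjustment is over all supplied rows (every tested term with k >= 1), so
#' apply it before any keyword filtering: adjusting after filtering would
#' understate the number of hypotheses m.
#'
#' @param rows table from [hypergeom_enrich()].
#' @return the table with a `q` column, re-sorted by `p`.
#' @export
add_q <- function(rows) {
  rows$q <- bh_adjust(rows$p)
  rows
}

#' Two-stage significance split
#'
#' Stage one keeps a deliberately relaxed capture set (`p <= capture_p`,
#' default 0.5) used for network/hub topology so intermediate signaling
#' nodes are not lost prematurely; stage two keeps the reported significant
#' set (`q < report_q`, default 0.05).
#'
#' @param rows enrichment table with `p` and `q` columns (see [add_q()]).
#' @param capture_p relaxed p cutoff, non-strict (default 0.5).
#' @param report_q BH q cutoff, strict (default 0.05).
#' @return list with data.frames `captured` and `significant`.
#' @export
two_stage_filter <- function(rows, capture_p = 0.5, report_q = 0.05) {
  stopifnot(!is.null(rows$p), !is.null(rows$q))
  list(captured = rows[rows$p <= capture_p, , drop = FALSE],
       significant = rows[rows$q < report_q, , drop = FALSE])
}

#' Default muscle keyword list
#'
#' The seven muscle-biology phrases used to filter biological-process terms,
#' plus the bare token "muscle" so that broader terms such as "muscle tissue
#' development" or "cardiac muscle cell differentiation" are retained.
#'
#' @return character vector of keywords.
#' @export
muscle_keywords <- function() {
  c("satellite cell", "myoblast", "myogenic", "sarcomere", "actin filament",
    "muscle fusion", "skeletal muscle", "muscle")
}

#' Keep enrichment rows whose term name matches a keyword
#'
#' Case-insensitive substring match of any keyword against `term_name`.
#'
#' @param rows enrichment table.
#' @param keywords non-empty character vector (default [muscle_keywords()]).
#' @return the matching rows.
#' @export
keyword_filter <- function(rows, keywords = muscle_keywords()) {
  if (!length(keywords)) stop("keywords must be non-empty")
  nm <- tolower(rows$term_name)
  hit <- Reduce(`|`, lapply(tolower(keywords), function(kw) grepl(kw, nm, fixed = TRUE)))
  if (is.null(hit)) hit <- logical(nrow(rows))
  rows[hit, , drop = FALSE]
}

#' Dot-plot backbone table
#'
#' Emits every plotted aesthetic of the enrichment dot plots (term, gene
#' ratio, hit count, q, direction) so any renderer can reproduce the figure
#' style. Gene ratios are emitted uncapped; `gene_ratio_display` carries the
#' axis display cap.
#'
#' @param rows significant, keyword-filtered enrichment rows.
#' @param direction `"SUPPRESSED"` or `"DEREPRESSED"`.
#' @param comparison comparison label string.
#' @param cap display cap for the gene-ratio axis (default 0.06).
#' @return data.frame ready for [write_table()].
#' @export
dotplot_table <- function(rows, direction, comparison, cap = 0.06) {
  data.frame(term_id = rows$term_id, term_name = rows$term_name,
             gene_ratio = rows$gene_ratio,
             gene_ratio_display = pmin(rows$gene_ratio, cap),
             count = rows$k, q = rows$q,
             direction = rep_len(direction, nrow(rows)),
             comparison = rep_len(comparison, nrow(rows)),
             stringsAsFactors = FALSE)
}
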