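#' Per-miRNA fold changes between two groups
#'
#' Fold change of TMM-scaled abundances, numerator group over denominator
#' group. With one pooled column per group (the study design) the group
#' abundance is that column's normalized count; with replicates it is the
#' group mean. A pseudocount `delta` is added to both abundances only when
#' either falls below `delta`, protecting against zeros while leaving the
#' published table values untouched (those tables contain no zeros). When
#' both abundances are zero the fold change is undefined: the miRNA is
#' reported with `fc = NA`, call UNCHANGED, and `flagged = TRUE`.
#'
#' @param x an `ev_norm` object (its `normalized` matrix is used) or a
#'   numeric matrix of normalized abundances (miRNA x sample).
#' @param design [ev_design()] covering the columns of `x`.
#' @param comparison `c(numerator_group, denominator_group)` or
#'   `"num:den"`; must be declared in the design.
#' @param pseudocount `delta`, default 0.5.
#' @return data.frame of class `ev_comparison` with columns `mirna_id`,
#'   `fc`, `log2fc`, `flagged`, plus attributes `comparison` and
#'   `pseudocount`. `fc` is kept at full precision; round only for display.
#' @export
fold_changes <- function(x, design, comparison, pseudocount = 0.5) {
  abund <- if (inherits(x, "ev_norm")) x$normalized else as.matrix(x)
  stopifnot(inherits(design, "ev_design"))
  if (is.character(comparison) && length(comparison) == 1L)
    comparison <- strsplit(comparison, ":", fixed = TRUE)[[1L]]
  if (!all(comparison %in% design$groups))
    stop("comparison group absent from design: ",
         paste(setdiff(comparison, design$groups), collapse = ", "))
  grp_mean <- function(g) {
    cols <- design$samples$sample_id[design$samples$group == g]
    if (!length(cols)) stop("no samples for group ", g)
    rowMeans(abund[, cols, drop = FALSE])
  }
  num <- grp_mean(comparison[1L])
  den <- grp_mean(comparison[2L])
  both_zero <- num == 0 & den == 0
  use_pc <- !both_zero & (num < pseudocount | den < pseudocount)
  fc <- ifelse(use_pc, (num + pseudocount) / (den + pseudocount), num / den)
  fc[both_zero] <- NA_real_
  out <- data.frame(mirna_id = rownames(abund),
                    fc = fc, log2fc = log2(fc),
                    flagged = both_zero,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "comparison") <- comparison
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("ev_comparison", class(out))
  out
}

#' Classify miRNAs as UP / DOWN / UNCHANGED
#'
#' Strict thresholds on the log2 fold change: UP iff `log2fc > up_thr`,
#' DOWN iff `log2fc < down_thr` (defaults +1 / -1, i.e. a greater than
#' two-fold change). Everything else -- including the boundary values and
#' undefined fold changes -- is the explicit third state UNCHANGED, so
#' `|UP| + |DOWN| + |UNCHANGED|` always equals the number of miRNAs tested.
#'
#' @param cr result of [fold_changes()].
#' @param up_thr,down_thr strict log2FC thresholds (default +1, -1).
#' @return list with `up` and `down` (character vectors of miRNA ids, the
#'   two directional sets) and `table` (the input with a `call` column).
#' @export
classify <- function(cr, up_thr = 1, down_thr = -1) {
  stopifnot(inherits(cr, "ev_comparison"), up_thr > down_thr)
  lf <- cr$log2fc
  call <- rep("UNCHANGED", nrow(cr))
  call[!is.na(lf) & lf > up_thr] <- "UP"
  call[!is.na(lf) & lf < down_thr] <- "DOWN"
  tab <- cr
  tab$call <- call
  list(up = cr$mirna_id[call == "UP"],
       down = cr$mirna_id[call == "DOWN"],
       table = tab)
}

#' Fold changes and calls for every declared comparison
#'
#' @param x,design,pseudocount as in [fold_changes()].
#' @param up_thr,down_thr as in [classify()].
#' @return named list (one element per comparison label) of [classify()]
#'   results.
#' @export
classify_all <- function(x, design, pseudocount = 0.5, up_thr = 1, down_thr = -1) {
  out <- lapply(design$comparisons, function(cmp) {
    classify(fold_changes(x, design, cmp, pseudocount), up_thr, down_thr)
  })
  names(out) <- vapply(design$comparisons, comparison_label, character(1L))
  out
}
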