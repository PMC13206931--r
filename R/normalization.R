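#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Estimates a relative scale factor per sample from precision-weighted,
#' doubly trimmed log-ratios against a reference sample, implemented from
#' first principles.
#'
#' For reference sample r and each sample k, restricted to miRNAs with
#' positive counts in both: the per-gene log-ratio is
#' `M_g = log2((y_gk/N_k) / (y_gr/N_r))`, the average log-abundance is
#' `A_g = (log2(y_gk/N_k) + log2(y_gr/N_r)) / 2`, and the delta-method
#' precision weight is `1/v_g` with
#' `v_g = (N_k - y_gk)/(N_k y_gk) + (N_r - y_gr)/(N_r y_gr)`.
#' Genes in the top/bottom `trim_m` tails of M and top/bottom `trim_a` tails
#' of A (rank-based, bounds `floor(n*trim)+1 .. n+1-(floor(n*trim)+1)`, tied
#' values sharing their average rank) are discarded;
#' `log2(factor_k) = sum(M_g/v_g) / sum(1/v_g)` over the survivors. The
#' reference is the sample whose upper-quartile count/library-size ratio is
#' closest to the across-sample mean of those ratios (computed after dropping
#' all-zero rows); its factor before rescaling is 1. All factors are finally
#' rescaled to geometric mean 1.
#'
#' @param cm [ev_counts()] object (>= 2 samples, positive library sizes).
#' @param trim_m two-sided trim fraction on M (default 0.30).
#' @param trim_a two-sided trim fraction on A (default 0.05).
#' @return object of class `ev_norm`: list with `tmm_factor` (named, product
#'   1), `effective_library_size` (`library_size * tmm_factor`),
#'   `normalized` (counts rescaled to a common effective library:
#'   `count / (eff_lib_k / geomean(eff_lib))`, a count-scale, depth- and
#'   composition-corrected abundance -- the TMM-scaled abundance used for
#'   fold changes), `library_sizes`, `reference_sample`, and the trim
#'   fractions.
#' @export
tmm_factors <- function(cm, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(inherits(cm, "ev_counts"))
  counts <- cm$counts
  lib <- cm$library_sizes
  if (ncol(counts) < 2L) stop("TMM needs at least 2 samples")
  if (any(lib <= 0)) stop("zero library size for sample(s): ",
                          paste(names(lib)[lib <= 0], collapse = ", "))
  if (!(trim_m >= 0 && trim_m < 0.5) || !(trim_a >= 0 && trim_a < 0.5))
    stop("trim fractions must lie in [0, 0.5)")
  x <- counts[rowSums(counts > 0) > 0L, , drop = FALSE]
  if (nrow(x) == 0L) stop("all-zero count matrix")
  uq <- apply(x, 2L, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(x)), function(k) {
    tmm_pair_factor(x[, k], x[, ref], lib[k], lib[ref], trim_m, trim_a)
  }, numeric(1L))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  eff <- lib * f
  structure(
    list(tmm_factor = f,
         effective_library_size = eff,
         normalized = sweep(counts, 2L, eff / exp(mean(log(eff))), "/"),
         library_sizes = lib,
         reference_sample = colnames(counts)[ref],
         trim_m = trim_m, trim_a = trim_a),
    class = "ev_norm")
}

# Single pairwise TMM factor (obs vs ref), before geometric-mean rescaling.
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a)  # excludes genes with a zero in either sample
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (length(m) == 0L || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1L; hi_m <- n + 1L - lo_m
  lo_a <- floor(n * trim_a) + 1L; hi_a <- n + 1L - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m & rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep))
    stop("no genes survive TMM trimming; use smaller trim_m/trim_a")
  2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
}

#' @export
print.ev_norm <- function(x, ...) {
  cat("ev_norm: TMM factors (reference ", x$reference_sample, ")\n", sep = "")
  print(round(x$tmm_factor, 4))
  invisible(x)
}

#' Counts per million
#'
#' `cpm_gk = y_gk / effective_library_size_k * 1e6`. With `ne = NULL` the raw
#' library sizes are used (all factors 1), the scale on which the
#' low-expression filter operates by default.
#'
#' @param cm [ev_counts()] object.
#' @param ne optional `ev_norm` from [tmm_factors()] computed on the same
#'   matrix dimensions.
#' @return numeric matrix of CPM values, same dimnames as the counts.
#' @export
cpm <- function(cm, ne = NULL) {
  stopifnot(inherits(cm, "ev_counts"))
  eff <- if (is.null(ne)) cm$library_sizes else {
    if (!identical(names(ne$tmm_factor), cm$sample_ids))
      stop("normalization factors do not match the count matrix samples")
    ne$effective_library_size
  }
  sweep(cm$counts, 2L, eff, "/") * 1e6
}

#' Low-expression filter on group-level CPM
#'
#' Keeps a miRNA iff its group-mean CPM strictly exceeds `threshold` in at
#' least `min_groups` experimental groups. With one pooled column per group
#' (the study design) the group CPM is simply that column's CPM.
#'
#' @param cpm_table CPM matrix from [cpm()].
#' @param design [ev_design()] covering the CPM columns.
#' @param threshold CPM threshold, strict `>` (default 15).
#' @param min_groups minimum number of groups above threshold (default 1).
#' @return object of class `ev_filter`: list with `kept_ids`, `dropped_ids`,
#'   `threshold_cpm`, `min_groups`, and the group-level CPM matrix.
#' @export
filter_low_expression <- function(cpm_table, design, threshold = 15, min_groups = 1L) {
  stopifnot(is.matrix(cpm_table), inherits(design, "ev_design"))
  if (!all(design$samples$sample_id %in% colnames(cpm_table)))
    stop("design samples missing from CPM table")
  grp_cpm <- vapply(design$groups, function(g) {
    cols <- design$samples$sample_id[design$samples$group == g]
    rowMeans(cpm_table[, cols, drop = FALSE])
  }, numeric(nrow(cpm_table)))
  keep <- rowSums(grp_cpm > threshold) >= min_groups
  structure(
    list(kept_ids = rownames(cpm_table)[keep],
         dropped_ids = rownames(cpm_table)[!keep],
         threshold_cpm = threshold, min_groups = min_groups,
         group_cpm = grp_cpm),
    class = "ev_filter")
}

#' @export
print.ev_filter <- function(x, ...) {
  cat("ev_filter: kept", length(x$kept_ids), "of",
      length(x$kept_ids) + length(x$dropped_ids),
      sprintf("miRNAs (group CPM > %g in >= %d group(s))\n",
              x$threshold_cpm, x$min_groups))
  invisible(x)
}

#' Normalize and filter in one pass
#'
#' Convenience wrapper running the default ordering: CPM on raw library
#' sizes, the low-expression filter on group CPM, then TMM factors. By
#' default (`factors_on = "all"`, single pass) factors are estimated on the
#' full matrix; `factors_on = "kept"` re-estimates them on the filtered
#' subset (with library sizes recomputed from the kept rows).
#'
#' @param cm [ev_counts()] object.
#' @param design [ev_design()] object.
#' @param threshold,min_groups passed to [filter_low_expression()].
#' @param trim_m,trim_a passed to [tmm_factors()].
#' @param factors_on `"all"` (default) or `"kept"`.
#' @return list with `norm` (`ev_norm`), `filter` (`ev_filter`), and
#'   `kept` (`ev_counts` restricted to kept miRNAs).
#' @export
normalize_and_filter <- function(cm, design, threshold = 15, min_groups = 1L,
                                 trim_m = 0.30, trim_a = 0.05,
                                 factors_on = c("all", "kept")) {
  factors_on <- match.arg(factors_on)
  flt <- filter_low_expression(cpm(cm), design, threshold, min_groups)
  kept <- ev_counts(cm$counts[flt$kept_ids, , drop = FALSE])
  ne <- if (factors_on == "all") tmm_factors(cm, trim_m, trim_a)
        else tmm_factors(kept, trim_m, trim_a)
  list(norm = ne, filter = flt, kept = kept)
}
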