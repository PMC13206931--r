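#' Simulate a pooled-group miRNA count matrix with planted truth
#'
#' Emulates the structure of pooled EV small-RNA-seq counts: one pooled
#' column per experimental group (replicates optional), a heavy-tailed
#' log-normal baseline abundance law with a forced dominant miRNA at `skew`
#' times the second-ranked baseline, planted up/down miRNAs with known
#' log2 fold changes against the first (control) group, optionally a set of
#' always-low miRNAs for exercising the CPM filter, and negative-binomial
#' count noise around `baseline * depth * 2^log2fc`. `dispersion = 0` is the
#' noise-free limit (counts are the rounded means).
#'
#' @param n_mirna number of miRNAs (>= 50).
#' @param groups group labels; the first is the unstimulated reference.
#' @param n_per_group pooled columns per group (default 1, the study design).
#' @param depth_range per-sample sequencing-depth multipliers drawn uniform
#'   from this range.
#' @param skew ratio of the dominant miRNA's baseline to the second-ranked
#'   baseline (exact, by construction).
#' @param planted_de list with `n_up`, `n_down` (per non-reference group)
#'   and `lfc_range` (magnitude of planted log2 fold changes, drawn
#'   uniform); planted miRNAs are restricted to baselines with expected CPM
#'   at least `min_de_cpm` so the planted signal is on robustly detected
#'   cargo. `NULL` plants nothing.
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 means noise-free, negative is an error.
#' @param n_low number of planted always-low miRNAs (expected CPM
#'   `low_cpm`, far below the filter threshold).
#' @param low_cpm expected CPM of planted low miRNAs (default 1).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline parameters.
#' @param lib_scale multiplies all baselines (sets overall library size).
#' @param min_de_cpm minimum expected CPM for DE eligibility (default 150).
#' @param seed RNG seed (recorded in the manifest).
#' @return list with `counts` ([ev_counts()]), `design` ([ev_design()]) and
#'   `truth` (baselines, depths, the full log2FC matrix, planted id sets,
#'   low ids, dominant id, seed).
#' @export
simulate_counts <- function(n_mirna = 350L,
                            groups = c("control", "lowHz", "highHz"),
                            n_per_group = 1L,
                            depth_range = c(0.8, 1.25),
                            skew = 4.8,
                            planted_de = list(n_up = 25L, n_down = 25L,
                                              lfc_range = c(1.5, 2.5)),
                            dispersion = 0.05,
                            n_low = 0L, low_cpm = 1,
                            baseline_meanlog = log(2000), baseline_sdlog = 1.6,
                            lib_scale = 1, min_de_cpm = 150,
                            seed = NULL) {
  if (n_mirna < 50L) stop("n_mirna must be >= 50")
  if (dispersion < 0) stop("dispersion must be >= 0 (0 = noise-free limit)")
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("miR-sim-%04d", seq_len(n_mirna))
  baseline <- stats::rlnorm(n_mirna, baseline_meanlog, baseline_sdlog) * lib_scale
  names(baseline) <- ids
  # force the dominant miRNA to exactly skew x the runner-up
  ord <- order(baseline, decreasing = TRUE)
  baseline[ord[1L]] <- skew * baseline[ord[2L]]
  dominant_id <- ids[ord[1L]]
  exp_cpm <- baseline / sum(baseline) * 1e6
  low_ids <- character()
  if (n_low > 0L) {
    cand <- setdiff(ids[order(baseline)], dominant_id)  # lowest baselines first
    low_ids <- utils::head(cand, n_low)
    baseline[low_ids] <- low_cpm * sum(baseline) / 1e6
    exp_cpm <- baseline / sum(baseline) * 1e6
  }
  lfc <- matrix(0, nrow = n_mirna, ncol = length(groups),
                dimnames = list(ids, groups))
  planted <- list()
  if (!is.null(planted_de) && (planted_de$n_up + planted_de$n_down) > 0L) {
    if (planted_de$n_up + planted_de$n_down >= n_mirna)
      stop("cannot plant more DE miRNAs than miRNAs simulated")
    eligible <- setdiff(ids[exp_cpm >= min_de_cpm], c(dominant_id, low_ids))
    for (g in groups[-1L]) {
      if (length(eligible) < planted_de$n_up + planted_de$n_down)
        stop("not enough DE-eligible miRNAs; lower min_de_cpm or plant fewer")
      pick <- sample(eligible, planted_de$n_up + planted_de$n_down)
      up <- pick[seq_len(planted_de$n_up)]
      down <- setdiff(pick, up)
      lfc[up, g] <- stats::runif(length(up), planted_de$lfc_range[1L],
                                 planted_de$lfc_range[2L])
      lfc[down, g] <- -stats::runif(length(down), planted_de$lfc_range[1L],
                                    planted_de$lfc_range[2L])
      planted[[g]] <- list(up = up, down = down)
    }
  }
  samples <- data.frame(
    sample_id = unlist(lapply(groups, function(g)
      if (n_per_group == 1L) paste0(g, "_pool")
      else paste0(g, "_pool", seq_len(n_per_group)))),
    group = rep(groups, each = n_per_group),
    stringsAsFactors = FALSE)
  depth <- stats::runif(nrow(samples), depth_range[1L], depth_range[2L])
  names(depth) <- samples$sample_id
  counts <- vapply(seq_len(nrow(samples)), function(s) {
    mu <- baseline * depth[s] * 2^lfc[, samples$group[s]]
    if (dispersion == 0) round(mu)
    else stats::rnbinom(n_mirna, mu = mu, size = 1 / dispersion)
  }, numeric(n_mirna))
  dimnames(counts) <- list(ids, samples$sample_id)
  list(counts = ev_counts(counts),
       design = ev_design(samples),
       truth = list(seed = seed, baseline = baseline, depth = depth,
                    lfc = lfc, planted = planted, low_ids = low_ids,
                    dominant_id = dominant_id, skew = skew,
                    dispersion = dispersion))
}

#' Simulate a multi-source miRNA-to-gene target database
#'
#' Random bipartite edges (per-miRNA degree ~ Poisson(`mean_degree`) over a
#' gene pool), split across sources so that every pair of sources shares the
#' requested overlap fraction of its records (a shared core present in all
#' sources plus equal source-unique remainders). Hub genes are additionally
#' wired to a fixed fraction of a specified miRNA set (typically the planted
#' UP miRNAs) and recorded in the truth manifest.
#'
#' @param mirnas miRNA identifiers to wire.
#' @param n_genes size of the generated gene pool (ignored when `gene_pool`
#'   is supplied).
#' @param gene_pool optional explicit gene symbols.
#' @param sources named character vector `source_name = evidence`, evidence
#'   in {VALIDATED, PREDICTED}.
#' @param mean_degree expected targets per miRNA.
#' @param hub_genes genes to wire as hubs (must lie in the pool).
#' @param hub_mirnas miRNA set the hubs are wired to.
#' @param hub_fraction fraction of `hub_mirnas` each hub is wired to, in
#'   (0, 1]; an infeasible fraction errors.
#' @param overlap pairwise source overlap fraction in \[0, 1).
#' @param seed RNG seed.
#' @return list with `records` (data.frame mirna/gene/source/evidence/score;
#'   PREDICTED records carry a confidence score), `genes` (the pool) and
#'   `truth` (hub wiring, realized mean degree, requested overlap).
#' @export
simulate_target_db <- function(mirnas, n_genes = 500L, gene_pool = NULL,
                               sources = c(dbA = "VALIDATED", dbB = "VALIDATED",
                                           dbC = "PREDICTED"),
                               mean_degree = 20, hub_genes = character(),
                               hub_mirnas = character(), hub_fraction = 0.75,
                               overlap = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(gene_pool)) gene_pool <- sprintf("Gene%04d", seq_len(n_genes))
  if (!all(hub_genes %in% gene_pool)) stop("hub genes must lie in the gene pool")
  if (length(hub_genes) && (hub_fraction <= 0 || hub_fraction > 1))
    stop("infeasible hub fraction: ", hub_fraction)
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  stopifnot(all(sources %in% c("VALIDATED", "PREDICTED")))
  deg <- pmax(1L, stats::rpois(length(mirnas), mean_degree))
  edges <- do.call(rbind, lapply(seq_along(mirnas), function(i) {
    data.frame(mirna = mirnas[i],
               gene = sample(gene_pool, min(deg[i], length(gene_pool))),
               stringsAsFactors = FALSE)
  }))
  edges <- edges[sample.int(nrow(edges)), , drop = FALSE]
  k <- length(sources)
  n_shared <- round(nrow(edges) * overlap / (overlap + k * (1 - overlap)))
  shared <- edges[seq_len(n_shared), , drop = FALSE]
  rest <- if (n_shared > 0L) edges[-seq_len(n_shared), , drop = FALSE] else edges
  alloc <- rep_len(seq_len(k), nrow(rest))
  recs <- do.call(rbind, lapply(seq_len(k), function(j) {
    e <- rbind(shared, rest[alloc == j, , drop = FALSE])
    data.frame(mirna = e$mirna, gene = e$gene,
               source = rep_len(names(sources)[j], nrow(e)),
               evidence = rep_len(unname(sources[j]), nrow(e)),
               stringsAsFactors = FALSE)
  }))
  hub_wiring <- list()
  if (length(hub_genes)) {
    hub_rows <- do.call(rbind, lapply(hub_genes, function(h) {
      wired <- sample(hub_mirnas, max(1L, round(hub_fraction * length(hub_mirnas))))
      hub_wiring[[h]] <<- wired
      data.frame(mirna = wired, gene = h, source = names(sources)[1L],
                 evidence = unname(sources[1L]), stringsAsFactors = FALSE)
    }))
    recs <- rbind(recs, hub_rows)
  }
  recs <- recs[!duplicated(recs[, c("mirna", "gene", "source")]), , drop = FALSE]
  recs$score <- ifelse(recs$evidence == "PREDICTED",
                       round(stats::runif(nrow(recs), 80, 100), 2), NA_real_)
  recs <- recs[order(recs$mirna, recs$gene, recs$source), , drop = FALSE]
  rownames(recs) <- NULL
  list(records = recs, genes = gene_pool,
       truth = list(hub_wiring = hub_wiring,
                    realized_mean_degree = nrow(edges) / length(mirnas),
                    overlap = overlap))
}

#' Simulate a GO-biological-process-style annotation in memory
#'
#' Term names are drawn from templates; an exact fraction of them contain
#' muscle keywords. Planted enriched terms draw a stated fraction of their
#' members from a supplied query pool (e.g. the suppressed-branch truth
#' genes of one comparison) so their hypergeometric enrichment is real, and
#' can be forced to include hub genes.
#'
#' @param genes the gene pool (the eventual universe).
#' @param n_terms number of terms.
#' @param size_range term sizes drawn uniform over this integer range.
#' @param muscle_term_fraction exact fraction of term names carrying a
#'   muscle keyword.
#' @param planted `NULL`, or a list of planting groups, each a list with
#'   `query_pool` (genes the planted terms over-sample), `n` (number of
#'   terms), `size` (term size K), and either `member_fraction` (fraction of
#'   members drawn from the pool) or `fold_enrichment` (converted via
#'   `min(0.95, fe * |pool|/|genes|)`), plus optional `must_include` genes.
#' @param seed RNG seed.
#' @return list with `annotation` (an `ev_annotation`) and `truth`
#'   (planted term ids per group, muscle term ids).
#' @export
simulate_annotation <- function(genes, n_terms = 300L, size_range = c(10L, 80L),
                                muscle_term_fraction = 0.2, planted = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (size_range[2L] > length(genes)) stop("size_range exceeds gene pool")
  muscle_cores <- c("skeletal muscle", "muscle", "myoblast", "satellite cell",
                    "sarcomere", "actin filament", "muscle fusion", "myogenic cell",
                    "striated muscle", "cardiac muscle", "smooth muscle",
                    "muscle tissue")
  other_cores <- c("ribosome", "lipid", "DNA repair", "mitochondrial",
                   "vesicle", "ion", "protein folding", "RNA splicing",
                   "cell cycle", "oxidative phosphorylation", "chromatin",
                   "autophagy", "telomere", "cilium", "peroxisome", "Golgi",
                   "nuclear envelope", "tRNA", "proteasome", "spindle")
  suffixes <- c("development", "differentiation", "organization", "regulation",
                "morphogenesis", "assembly", "maintenance", "homeostasis",
                "dynamics", "remodeling", "signaling", "turnover")
  name_grid <- function(cores) {
    g <- expand.grid(core = cores, suffix = suffixes, stringsAsFactors = FALSE)
    c(paste(g$core, g$suffix), paste("regulation of", g$core, g$suffix))
  }
  muscle_names <- sample(name_grid(muscle_cores))
  other_names <- sample(name_grid(other_cores))
  n_muscle <- round(muscle_term_fraction * n_terms)
  planted_specs <- list()
  if (!is.null(planted)) {
    for (gi in seq_along(planted)) {
      p <- planted[[gi]]
      frac <- if (!is.null(p$member_fraction)) p$member_fraction
              else min(0.95, p$fold_enrichment *
                         length(intersect(p$query_pool, genes)) / length(genes))
      for (j in seq_len(p$n))
        planted_specs[[length(planted_specs) + 1L]] <-
          list(group = gi, size = p$size, frac = frac,
               pool = intersect(p$query_pool, genes),
               must = if (is.null(p$must_include)) character() else p$must_include)
    }
  }
  n_planted <- length(planted_specs)
  if (n_planted > n_muscle)
    stop("planted terms (", n_planted, ") exceed the muscle-name budget (", n_muscle, ")")
  if (n_muscle > length(muscle_names) || n_terms - n_muscle > length(other_names))
    stop("name template pool exhausted; reduce n_terms")
  term_id <- sprintf("T%04d", seq_len(n_terms))
  term_name <- character(n_terms)
  is_muscle <- seq_len(n_terms) <= n_muscle  # planted first, then shuffled below
  term_name[is_muscle] <- muscle_names[seq_len(n_muscle)]
  term_name[!is_muscle] <- other_names[seq_len(n_terms - n_muscle)]
  members <- vector("list", n_terms)
  for (i in seq_len(n_terms)) {
    if (i <= n_planted) {
      sp <- planted_specs[[i]]
      n_q <- round(sp$frac * sp$size)
      mem <- unique(c(sp$must,
                      sample(setdiff(sp$pool, sp$must),
                             max(0L, min(n_q - length(sp$must),
                                         length(setdiff(sp$pool, sp$must)))))))
      fill <- setdiff(genes, mem)
      mem <- c(mem, sample(fill, max(0L, sp$size - length(mem))))
      members[[i]] <- sample(mem)
    } else {
      sz <- sample(seq(size_range[1L], size_range[2L]), 1L)
      members[[i]] <- sample(genes, sz)
    }
  }
  perm <- sample.int(n_terms)  # detach planted terms from low term ids
  ann <- structure(list(term_id = term_id,
                        term_name = term_name[perm],
                        genes = members[perm]),
                   class = "ev_annotation")
  ann$universe <- sort(unique(unlist(ann$genes)))
  planted_ids <- lapply(seq_along(planted), function(gi) {
    term_id[which(perm %in% which(vapply(seq_len(n_planted), function(j)
      planted_specs[[j]]$group == gi, logical(1L))))]
  })
  list(annotation = ann,
       truth = list(planted_term_ids = planted_ids,
                    muscle_term_ids = term_id[which(perm <= n_muscle)],
                    muscle_term_fraction = muscle_term_fraction))
}

#' Simulate a complete paper-scale study
#'
#' One call producing every input of the full workflow at the default study
#' conditions: 350 miRNAs across control/lowHz/highHz pooled columns with 30
#' always-low miRNAs and 25 up + 25 down planted per stimulated group at
#' |log2FC| in \[1.5, 2.5\]; a 3-source target database (two validated, one
#' predicted) over 2000 genes with mean degree 20, pairwise source overlap
#' 0.3 and 5 hub genes wired to 75% of the planted UP miRNAs; and a 300-term
#' annotation with 20% muscle-keyword names and 8 planted enriched terms per
#' stimulated comparison (member fraction 0.92 from the suppressed-branch
#' truth pool, hubs force-included).
#'
#' @param seed RNG seed (sub-seeds for the three generators derive from it).
#' @param out_dir optional directory; when given, all inputs are written as
#'   TSV/GMT plus a `truth.json` manifest, and the paths are returned too.
#' @return list with `counts`, `design`, `db`, `annotation`, `truth` (merged
#'   manifest incl. `hub_genes`), and `paths` when `out_dir` was given.
#' @export
simulate_study <- function(seed = 1L, out_dir = NULL) {
  set.seed(seed)
  sub <- sample.int(2^31 - 1L, 3L)
  sim <- simulate_counts(n_mirna = 350L, n_low = 30L, seed = sub[1L])
  hub_genes <- c("Mef2c", "Gata4", "Pak1", "Camk2d", "Igf1")
  pool <- c(hub_genes, sprintf("Gene%04d", seq_len(1995L)))
  up_all <- unique(unlist(lapply(sim$truth$planted, `[[`, "up")))
  db <- simulate_target_db(sim$counts$mirna_ids, gene_pool = pool,
                           hub_genes = hub_genes, hub_mirnas = up_all,
                           hub_fraction = 0.75, overlap = 0.3, seed = sub[2L])
  planted_groups <- lapply(names(sim$truth$planted), function(g) {
    up <- sim$truth$planted[[g]]$up
    list(query_pool = unique(db$records$gene[db$records$mirna %in% up]),
         n = 8L, size = 40L, member_fraction = 0.92, must_include = hub_genes)
  })
  names(planted_groups) <- names(sim$truth$planted)
  ann <- simulate_annotation(pool, n_terms = 300L, planted = planted_groups,
                             seed = sub[3L])
  truth <- c(sim$truth, db$truth, ann$truth,
             list(hub_genes = hub_genes, study_seed = seed,
                  planted_group_names = names(planted_groups)))
  out <- list(counts = sim$counts, design = sim$design, db = db$records,
              annotation = ann$annotation, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(counts = file.path(out_dir, "counts.tsv"),
                  design = file.path(out_dir, "design.tsv"),
                  gmt = file.path(out_dir, "annotation.gmt"),
                  truth = file.path(out_dir, "truth.json"))
    write_table(data.frame(mirna = sim$counts$mirna_ids,
                           as.data.frame(sim$counts$counts),
                           check.names = FALSE),
                paths$counts)
    write_table(sim$design$samples, paths$design)
    paths$target_dbs <- vapply(unique(db$records$source), function(s) {
      p <- file.path(out_dir, paste0("targets_", s, ".tsv"))
      write_table(db$records[db$records$source == s, , drop = FALSE], p)
      p
    }, character(1L))
    write_gmt(ann$annotation, paths$gmt)
    jsonlite::write_json(
      list(seed = seed,
           dominant_id = truth$dominant_id, skew = truth$skew,
           planted = lapply(truth$planted, function(p) p[c("up", "down")]),
           low_ids = truth$low_ids, hub_genes = hub_genes,
           planted_term_ids = truth$planted_term_ids,
           muscle_term_ids = truth$muscle_term_ids),
      paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$paths <- paths
  }
  out
}
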