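#' Assemble a run configuration
#'
#' Collects every path and threshold of the workflow in one structured list
#' so a full run is reproducible from a single object. Defaults are the
#' analysis defaults: CPM filter > 15 in at least one group, |log2FC| > 1,
#' relaxed capture p <= 0.5, reported q < 0.05, top 25 hub genes, head-20
#' target frequency, TMM trims 0.30/0.05, pseudocount 0.5.
#'
#' @param counts,design,target_dbs,gmt input paths (`target_dbs` may name
#'   several extracts).
#' @param alias,families optional alias-table / family-table paths
#'   (`families` defaults to the shipped table).
#' @param comparisons optional comparison spec for [ev_design()].
#' @param ... threshold overrides (see defaults in the function body).
#' @return named list of class `ev_config`.
#' @export
ev_config <- function(counts, design, target_dbs, gmt,
                      alias = NULL,
                      families = system.file("extdata", "families.tsv",
                                             package = "evcargo"),
                      comparisons = NULL, ...) {
  cfg <- list(counts = counts, design = design, target_dbs = target_dbs,
              gmt = gmt, alias = alias, families = families,
              comparisons = comparisons,
              cpm_threshold = 15, min_groups = 1L,
              trim_m = 0.30, trim_a = 0.05, factors_on = "all",
              pseudocount = 0.5, up_thr = 1, down_thr = -1,
              min_sources = 1L, min_score = NULL,
              min_term = 5L, max_term = 2000L,
              capture_p = 0.5, report_q = 0.05,
              keywords = muscle_keywords(),
              top_n = 25L, head_n = 20L, hub_rows = "significant",
              gene_ratio_cap = 0.06)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  for (p in c("counts", "design", "gmt", cfg$target_dbs,
              cfg$alias, cfg$families)) {
    pp <- if (p %in% c("counts", "design", "gmt")) cfg[[p]] else p
    if (!is.null(pp) && nzchar(pp) && !file.exists(pp))
      stop("config path does not exist: ", pp)
  }
  structure(cfg, class = "ev_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full workflow end to end
#'
#' Executes, in order: ingest -> normalization + CPM filter -> fold changes
#' and UP/DOWN classification for every declared comparison -> directional
#' target mapping (suppressed = targets of UP miRNAs, derepressed = targets
#' of DOWN miRNAs) -> hypergeometric enrichment with BH adjustment, the
#' two-stage capture/report split and muscle keyword filtering -> hub
#' connectivity matrix and target-frequency tables. Every stage writes its
#' outputs under `out_dir` as TSV (plus a machine-readable `manifest.json`),
#' and reruns with identical inputs are byte-identical.
#'
#' @param config an [ev_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "ev_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(out_dir, paste0(...))

  rc <- run_stage("ingest",
    read_counts(config$counts, config$design, config$comparisons))
  cm <- rc$counts; design <- rc$design

  nf <- run_stage("normalization", {
    normalize_and_filter(cm, design, threshold = config$cpm_threshold,
                         min_groups = config$min_groups,
                         trim_m = config$trim_m, trim_a = config$trim_a,
                         factors_on = config$factors_on)
  })
  write_table(data.frame(sample_id = cm$sample_ids,
                         library_size = cm$library_sizes,
                         tmm_factor = nf$norm$tmm_factor,
                         effective_library_size = nf$norm$effective_library_size,
                         reference = cm$sample_ids == nf$norm$reference_sample),
              pth("tmm_factors.tsv"))
  write_table(data.frame(mirna_id = rownames(nf$filter$group_cpm),
                         nf$filter$group_cpm,
                         kept = rownames(nf$filter$group_cpm) %in% nf$filter$kept_ids,
                         check.names = FALSE),
              pth("filter_report.tsv"))
  abund <- nf$norm$normalized[nf$filter$kept_ids, , drop = FALSE]
  write_table(data.frame(mirna_id = rownames(abund), abund, check.names = FALSE),
              pth("normalized_counts.tsv"))

  sets <- run_stage("differential",
    classify_all(abund, design, pseudocount = config$pseudocount,
                 up_thr = config$up_thr, down_thr = config$down_thr))
  for (lab in names(sets)) {
    write_table(sets[[lab]]$table, pth("de_", lab, ".tsv"))
    writeLines(sets[[lab]]$up, pth("up_", lab, ".txt"))
    writeLines(sets[[lab]]$down, pth("down_", lab, ".txt"))
  }

  tmap <- run_stage("target_mapping", {
    db <- load_target_db(config$target_dbs, min_score = config$min_score)
    alias <- if (!is.null(config$alias)) read_alias_table(config$alias) else NULL
    map_directional_targets(sets, db, alias, min_sources = config$min_sources)
  })

  ann <- run_stage("enrichment_input", read_gmt(config$gmt))
  enrich <- list()
  for (lab in names(tmap)) for (dir in c("suppressed", "derepressed")) {
    col <- paste0(lab, ".", dir)
    enrich[[col]] <- run_stage(paste0("enrichment:", col), {
      genes <- tmap[[lab]][[dir]]$genes
      rows <- if (length(genes))
        add_q(hypergeom_enrich(genes, ann, config$min_term, config$max_term))
      else add_q(suppressWarnings(hypergeom_enrich(character(), ann)))
      stages <- two_stage_filter(rows, config$capture_p, config$report_q)
      res <- list(captured = keyword_filter(stages$captured, config$keywords),
                  significant = keyword_filter(stages$significant, config$keywords),
                  all_tested = nrow(rows))
      direction <- if (dir == "suppressed") "SUPPRESSED" else "DEREPRESSED"
      write_table(res$captured[setdiff(names(res$captured), "member_hits")],
                  pth("captured_", lab, "_", dir, ".tsv"))
      write_table(res$significant, pth("significant_", lab, "_", dir, ".tsv"))
      write_table(dotplot_table(res$significant, direction, lab,
                                cap = config$gene_ratio_cap),
                  pth("dotplot_", lab, "_", dir, ".tsv"))
      res
    })
  }

  hub <- run_stage("hub_analysis", {
    use <- if (config$hub_rows == "captured") "captured" else "significant"
    scores <- lapply(enrich, function(e) connectivity(e[[use]]))
    hm <- build_hub_matrix(scores, top_n = config$top_n,
                           family_table = if (!is.null(config$families) &&
                                              nzchar(config$families))
                             read_family_table(config$families) else NULL)
    write_table(as.data.frame(hm), pth("hub_matrix.tsv"))
    for (col in names(enrich))
      write_table(target_frequency_table(enrich[[col]][[use]], config$head_n),
                  pth("target_frequency_", sub("\\.", "_", col), ".tsv"))
    hm
  })

  manifest <- run_stage("manifest", {
    de_counts <- lapply(sets, function(s) {
      n_up <- length(s$up); n_down <- length(s$down)
      n_unch <- sum(s$table$call == "UNCHANGED")
      stopifnot(n_up + n_down + n_unch == nrow(s$table),
                nrow(s$table) == length(nf$filter$kept_ids))
      list(up = n_up, down = n_down, unchanged = n_unch)
    })
    m <- list(
      package_version = as.character(utils::packageVersion("evcargo")),
      config = config[setdiff(names(config), "keywords")],
      keywords = config$keywords,
      n_mirna = length(cm$mirna_ids),
      n_kept = length(nf$filter$kept_ids),
      reference_sample = nf$norm$reference_sample,
      tmm_factors = as.list(round(nf$norm$tmm_factor, 6)),
      de_counts = de_counts,
      enrichment = lapply(enrich, function(e)
        list(tested = e$all_tested, captured_muscle = nrow(e$captured),
             significant_muscle = nrow(e$significant))),
      hub_genes = rownames(hub$scores))
    jsonlite::write_json(m, pth("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    m
  })
  invisible(manifest)
}
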