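write_target_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("loading aggregates sources with union semantics and full provenance", {
  p1 <- write_target_tsv(data.frame(mirna = "miR-1", gene = "Igf1",
                                    source = "dbA", evidence = "VALIDATED"),
                         withr::local_tempfile(fileext = ".tsv"))
  p2 <- write_target_tsv(data.frame(mirna = c("miR-1", "miR-1"),
                                    gene = c("Igf1", "Igf1"),
                                    source = c("dbB", "dbB"),
                                    evidence = "VALIDATED"),
                         withr::local_tempfile(fileext = ".tsv"))
  db <- suppressMessages(load_target_db(c(p1, p2)))
  expect_equal(nrow(db), 2L)  # duplicate within dbB collapsed
  ts <- suppressMessages(map_targets("miR-1", db))
  expect_equal(ts$genes, "Igf1")
  expect_equal(nrow(ts$records), 2L)  # one provenance record per source
})

test_that("unknown evidence labels are a hard error", {
  p <- write_target_tsv(data.frame(mirna = "miR-1", gene = "G1",
                                   source = "dbA", evidence = "maybe"),
                        withr::local_tempfile(fileext = ".tsv"))
  expect_error(suppressMessages(load_target_db(p)), "maybe")
})

test_that("directional branches are unions of per-miRNA targets, overlap allowed", {
  db <- data.frame(mirna = c("miR-X", "miR-X", "miR-Y", "miR-Y"),
                   gene = c("G1", "G2", "G2", "G3"),
                   source = "dbA", evidence = "VALIDATED", score = NA_real_,
                   stringsAsFactors = FALSE)
  sets <- list(cmp = list(up = "miR-X", down = "miR-Y"))
  tm <- suppressMessages(map_directional_targets(sets, db))
  expect_setequal(tm$cmp$suppressed$genes, c("G1", "G2"))
  expect_setequal(tm$cmp$derepressed$genes, c("G2", "G3"))
  empty <- suppressMessages(map_targets(character(), db))
  expect_length(empty$genes, 0L)
})

test_that("alias canonicalization and min_sources filtering apply", {
  db <- data.frame(mirna = c("miR-1", "miR-1", "miR-1"),
                   gene = c("Igf-I", "Igf1", "G2"),
                   source = c("dbA", "dbB", "dbA"),
                   evidence = "VALIDATED", score = NA_real_,
                   stringsAsFactors = FALSE)
  alias <- c("Igf-I" = "Igf1")
  ts <- suppressMessages(map_targets("miR-1", db, alias = alias))
  expect_setequal(ts$genes, c("Igf1", "G2"))
  expect_equal(sum(ts$records$gene == "Igf1"), 2L)
  ts2 <- suppressMessages(map_targets("miR-1", db, alias = alias, min_sources = 2))
  expect_equal(ts2$genes, "Igf1")
})

test_that("adding a miRNA to a directional set never removes target genes", {
  sim <- simulate_target_db(sprintf("m%02d", 1:20), n_genes = 100,
                            mean_degree = 8, seed = 5)
  mirnas <- sprintf("m%02d", 1:20)
  prev <- character()
  for (i in seq_along(mirnas)) {
    cur <- suppressMessages(map_targets(mirnas[1:i], sim$records))$genes
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  # provenance completeness: per-gene records sum to matching DB rows
  ts <- suppressMessages(map_targets(mirnas, sim$records))
  expect_equal(nrow(ts$records), sum(sim$records$mirna %in% mirnas))
})

test_that("generated target DBs honour overlap, degree and hub wiring", {
  mirnas <- sprintf("m%02d", 1:30)
  zero <- simulate_target_db(mirnas, n_genes = 200, overlap = 0, seed = 6)
  by_src <- split(paste(zero$records$mirna, zero$records$gene), zero$records$source)
  expect_length(intersect(by_src$dbA, by_src$dbB), 0L)
  expect_length(intersect(by_src$dbA, by_src$dbC), 0L)

  ov <- simulate_target_db(mirnas, n_genes = 200, overlap = 0.3, seed = 6)
  bs <- split(paste(ov$records$mirna, ov$records$gene), ov$records$source)
  realized <- length(intersect(bs$dbA, bs$dbB)) /
    mean(c(length(bs$dbA), length(bs$dbB)))
  expect_equal(realized, 0.3, tolerance = 0.05)

  deg <- simulate_target_db(sprintf("m%03d", 1:100), n_genes = 500,
                            mean_degree = 20, seed = 7)
  expect_equal(deg$truth$realized_mean_degree, 20, tolerance = 0.1 * 20)

  hub <- simulate_target_db(mirnas, n_genes = 200, hub_genes = "Gene0001",
                            hub_mirnas = mirnas[1:12], hub_fraction = 10 / 12,
                            seed = 8)
  wired <- hub$truth$hub_wiring$Gene0001
  expect_length(wired, 10L)
  ts <- suppressMessages(map_targets(wired, hub$records))
  expect_true("Gene0001" %in% ts$genes)
  expect_equal(sum(ts$records$gene == "Gene0001" & ts$records$source == "dbA"), 10L)
  expect_error(simulate_target_db(mirnas, hub_genes = "nope",
                                  hub_mirnas = mirnas, seed = 1),
               "gene pool")
})
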