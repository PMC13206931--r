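test_that("hypergeometric p matches exhaustive enumeration for all universes up to N = 12", {
  # every (N, K, n) with a handful of k values, against counting all C(N, n) draws
  for (N in c(5, 8, 10, 12)) {
    for (K in c(1, 3, N %/% 2, N - 1)) {
      for (n in c(1, N %/% 2, N - 1)) {
        for (k in unique(c(1, min(K, n) %/% 2 + 1, min(K, n)))) {
          if (k < 1 || k > min(K, n)) next
          expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                       oracle_hyper_p(N, K, n, k),
                       tolerance = 1e-12,
                       info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("enrichment rows carry the textbook example and both gene-ratio conventions", {
  # N=10, K=4, n=5, k=3: p = (C(4,3)C(6,2)+C(4,4)C(6,1))/C(10,5) = 66/252
  ann <- toy_annotation(list(
    T1 = list(name = "muscle term", genes = sprintf("g%02d", 1:4)),
    T2 = list(name = "background spread", genes = sprintf("g%02d", 1:10))))
  query <- c("g01", "g02", "g03", "g06", "g07")
  rows <- hypergeom_enrich(query, ann, min_size = 1)
  r1 <- rows[rows$term_id == "T1", ]
  expect_equal(r1$p, 66 / 252, tolerance = 1e-12)
  expect_equal(r1$k, 3L)
  expect_equal(r1$gene_ratio, 3 / 4)
  expect_equal(r1$gene_ratio_query, 3 / 5)
  expect_setequal(r1$member_hits[[1]], c("g01", "g02", "g03"))

  # query = entire universe: every term has k = K and p = 1
  all_rows <- hypergeom_enrich(ann$universe, ann, min_size = 1)
  expect_equal(all_rows$k, all_rows$K)
  expect_equal(all_rows$p, c(1, 1))

  # k = 0 terms are absent
  none <- hypergeom_enrich(c("g09", "g10"), ann, min_size = 1)
  expect_false("T1" %in% none$term_id)
})

test_that("p is monotone non-increasing in k and empty/invalid inputs are handled", {
  for (k in 2:5)
    expect_lte(phyper(k - 1, 6, 14, 8, lower.tail = FALSE),
               phyper(k - 2, 6, 14, 8, lower.tail = FALSE))
  ann <- toy_annotation(list(T1 = list(name = "a", genes = c("g1", "g2"))))
  expect_warning(out <- hypergeom_enrich(c("zz"), ann, min_size = 1), "empty")
  expect_equal(nrow(out), 0L)
  bad <- ann; bad$genes[[1]] <- c("g1", "g2", "g3")  # member outside universe
  expect_error(hypergeom_enrich("g1", bad, min_size = 1), "corrupt")
})

test_that("BH adjustment matches the hand step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)            # m = 1: q = p
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(14)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    # monotone non-decreasing in sorted-p order
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("the two-stage split separates captured (p <= 0.5) from significant (q < 0.05)", {
  rows <- data.frame(term_id = c("a", "b", "c"),
                     p = c(0.4, 0.6, 0.001), q = c(0.2, 0.7, 0.01))
  st <- two_stage_filter(rows)
  expect_setequal(st$captured$term_id, c("a", "c"))
  expect_equal(st$significant$term_id, "c")
})

test_that("keyword filtering is case-insensitive substring matching on term names", {
  rows <- data.frame(
    term_id = sprintf("T%d", 1:4),
    term_name = c("striated muscle tissue development",
                  "ribosome biogenesis",
                  "Myoblast fusion",
                  "regulation of actin filament polymerization"),
    stringsAsFactors = FALSE)
  kept <- keyword_filter(rows)
  expect_setequal(kept$term_id, c("T1", "T3", "T4"))
  expect_equal(keyword_filter(rows, "myoblast")$term_id, "T3")
  expect_error(keyword_filter(rows, character()), "non-empty")
})

test_that("planted enriched terms reach p < 0.05 in at least 95% of seeds", {
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    genes <- sprintf("g%03d", 1:500)
    pool <- sample(genes, 30)
    ann <- simulate_annotation(genes, n_terms = 50, size_range = c(10, 40),
                               planted = list(list(query_pool = pool, n = 1,
                                                   size = 30,
                                                   fold_enrichment = 5)),
                               seed = seed)
    rows <- suppressMessages(hypergeom_enrich(pool, ann$annotation))
    planted <- rows[rows$term_id == ann$truth$planted_term_ids[[1]], ]
    if (nrow(planted) == 1L && planted$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})
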