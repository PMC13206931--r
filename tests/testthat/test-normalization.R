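test_that("TMM factors are 1 for identical columns and for pure depth differences", {
  m <- toy_counts_matrix()
  same <- cbind(s1 = m[, 1], s2 = m[, 1])
  ne <- tmm_factors(ev_counts(same))
  expect_equal(unname(ne$tmm_factor), c(1, 1))

  doubled <- cbind(s1 = m[, 1], s2 = 2 * m[, 1])
  ne2 <- tmm_factors(ev_counts(doubled))
  expect_equal(unname(ne2$tmm_factor), c(1, 1))
  expect_equal(unname(ne2$effective_library_size), unname(colSums(doubled)))
})

test_that("TMM factors match the brute-force oracle and an independent implementation", {
  skip_if_not_installed("edgeR")
  for (seed in c(3, 11, 42)) {
    x <- random_nb_counts(seed)
    mine <- tmm_factors(ev_counts(x))$tmm_factor
    expect_equal(mine, oracle_tmm_factors(x), tolerance = 1e-9)
    expect_equal(unname(mine),
                 unname(edgeR::normLibSizes(x, method = "TMM")),
                 tolerance = 1e-9)
  }
})

test_that("TMM is scale-invariant and equivariant under sample permutation", {
  x <- random_nb_counts(5)
  base <- tmm_factors(ev_counts(x))$tmm_factor
  # scaling one column leaves the post-rescale factor ratios of the others unchanged
  y <- x; y[, 2] <- y[, 2] * 3
  scaled <- tmm_factors(ev_counts(y))$tmm_factor
  expect_equal(scaled["s1"] / scaled["s3"], base["s1"] / base["s3"],
               tolerance = 1e-9)
  perm <- c(3, 1, 2)
  permuted <- tmm_factors(ev_counts(x[, perm]))$tmm_factor
  expect_equal(permuted, base[perm], tolerance = 1e-12)
})

test_that("TMM recovers known depth multipliers within 5% at 400 genes", {
  sim <- simulate_counts(n_mirna = 400, depth_range = c(0.6, 1.6),
                         planted_de = list(n_up = 10, n_down = 10,
                                           lfc_range = c(1.5, 2.5)),
                         dispersion = 0.02, seed = 99)
  ne <- tmm_factors(sim$counts)
  # depth is absorbed jointly by library size and factor: the effective
  # library sizes must be proportional to the true depths
  truth <- sim$truth$depth / exp(mean(log(sim$truth$depth)))
  est <- ne$effective_library_size / exp(mean(log(ne$effective_library_size)))
  expect_lt(max(abs(est / truth - 1)), 0.05)
  expect_gt(cor(est, truth), 0.99)
})

test_that("TMM error handling covers degenerate inputs", {
  m <- toy_counts_matrix()
  zero <- m; zero[, 2] <- 0
  expect_error(tmm_factors(ev_counts(zero)), "library size")
  expect_error(tmm_factors(ev_counts(m), trim_m = 0.6), "trim")
})

test_that("cpm follows its definition on raw and effective library sizes", {
  m <- matrix(c(100, 999900, 30, 1999970), nrow = 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  cm <- ev_counts(m)
  cp <- cpm(cm)
  expect_equal(cp["g1", "a"], 100)   # y=100, lib 1e6
  expect_equal(cp["g1", "b"], 15)    # y=30, lib 2e6
  expect_equal(unname(colSums(cp)), c(1e6, 1e6))
  x <- random_nb_counts(8)
  cmx <- ev_counts(x)
  ne <- tmm_factors(cmx)
  expect_equal(cpm(cmx, ne),
               sweep(x, 2, colSums(x) * ne$tmm_factor, "/") * 1e6)
})

test_that("low-expression filter keeps >15 CPM in at least one group, strictly", {
  gc <- matrix(c(16, 0, 0,
                 15, 15, 15,
                 15.01, 0, 0), nrow = 3, byrow = TRUE,
               dimnames = list(c("kept1", "boundary", "kept2"),
                               c("s1", "s2", "s3")))
  design <- ev_design(toy_design_df())
  fl <- filter_low_expression(gc, design, threshold = 15)
  expect_setequal(fl$kept_ids, c("kept1", "kept2"))
  expect_equal(fl$dropped_ids, "boundary")
})

test_that("planted always-low miRNAs are exactly the ones dropped by the CPM filter", {
  sim <- simulate_counts(n_mirna = 400, n_low = 40, seed = 4)
  fl <- filter_low_expression(cpm(sim$counts), sim$design)
  expect_setequal(fl$dropped_ids, sim$truth$low_ids)
  expect_equal(length(fl$kept_ids), 360L)
})
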