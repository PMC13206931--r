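test_that("fold changes reproduce the published abundance-table ratios to +/-0.01", {
  pub <- published_abundance_matrix("top30")
  low <- fold_changes(pub$abund, pub$design, c("lowHz", "control"))
  expect_true(all(abs(round(low$fc, 2) - pub$table$lowhz_fc) <= 0.01 + 1e-9))
  expect_equal(round(low$fc[low$mirna_id == "miR-206-3p"], 2), 1.16)
  expect_equal(round(low$fc[low$mirna_id == "miR-486a-5p"], 2), 0.43)
  high <- fold_changes(pub$abund, pub$design, c("highHz", "control"))
  expect_equal(round(high$fc[high$mirna_id == "miR-206-3p"], 2), 1.40)

  myo <- published_abundance_matrix("myomir")
  mlow <- fold_changes(myo$abund, myo$design, "lowHz:control")
  expect_equal(round(mlow$fc[myo$table$mirna == "miR-133a-3p"], 2), 2.84)
})

test_that("identical abundances give fc 1 and UNCHANGED; zeros are flagged", {
  ab <- matrix(c(10, 10, 0, 0, 2, 0.1), nrow = 3, byrow = TRUE,
               dimnames = list(c("same", "both_zero", "low"), c("s1", "s2")))
  design <- ev_design(data.frame(sample_id = c("s1", "s2"),
                                 group = c("g2", "g1")))
  cr <- fold_changes(ab, design, c("g2", "g1"))
  expect_equal(cr$fc[cr$mirna_id == "same"], 1)
  expect_equal(cr$log2fc[cr$mirna_id == "same"], 0)
  expect_true(is.na(cr$fc[cr$mirna_id == "both_zero"]))
  expect_true(cr$flagged[cr$mirna_id == "both_zero"])
  # pseudocount active only when an abundance is below it
  expect_equal(cr$fc[cr$mirna_id == "low"], (2 + 0.5) / (0.1 + 0.5))
  cl <- classify(cr)
  expect_true("both_zero" %in% setdiff(cr$mirna_id, c(cl$up, cl$down)))
})

test_that("classification uses strict log2FC thresholds", {
  ab <- matrix(c(2.84, 1, 2, 1, 0.43, 1, 0.5, 1), nrow = 4, byrow = TRUE,
               dimnames = list(c("up_284", "exact_2", "down_043", "exact_half"),
                               c("num", "den")))
  design <- ev_design(data.frame(sample_id = c("num", "den"),
                                 group = c("stim", "control")))
  cl <- classify(fold_changes(ab, design, c("stim", "control"), pseudocount = 0))
  expect_equal(cl$up, "up_284")       # log2(2.84) > 1
  expect_equal(cl$down, "down_043")   # log2(0.43) < -1
  expect_setequal(cl$table$call[cl$table$mirna_id %in% c("exact_2", "exact_half")],
                  "UNCHANGED")        # boundary values are not calls
})

test_that("the published top-30 lowHz comparison yields exactly 3 DOWN and 0 UP", {
  pub <- published_abundance_matrix("top30")
  cl <- classify(fold_changes(pub$abund, pub$design, c("lowHz", "control")))
  expect_setequal(cl$down, c("miR-486a-5p", "miR-486b-5p", "miR-615-3p"))
  expect_length(cl$up, 0L)
})

test_that("log2 fold changes are antisymmetric and direction swap exchanges UP/DOWN", {
  set.seed(21)
  ab <- matrix(exp(rnorm(60, 5, 2)), nrow = 30,
               dimnames = list(sprintf("m%02d", 1:30), c("a", "b")))
  design <- ev_design(data.frame(sample_id = c("a", "b"), group = c("ga", "gb")))
  fwd <- fold_changes(ab, design, c("ga", "gb"), pseudocount = 0)
  rev <- fold_changes(ab, design, c("gb", "ga"), pseudocount = 0)
  expect_equal(fwd$log2fc, -rev$log2fc)
  cf <- classify(fwd); cr <- classify(rev)
  expect_setequal(cf$up, cr$down)
  expect_setequal(cf$down, cr$up)
})

test_that("noise-free planted log2FC of +/-2 is classified with perfect recall and precision", {
  sim <- simulate_counts(n_mirna = 200, dispersion = 0,
                         planted_de = list(n_up = 15, n_down = 15,
                                           lfc_range = c(2, 2)),
                         seed = 13)
  ne <- tmm_factors(sim$counts)
  sets <- classify_all(ne, sim$design)
  for (g in names(sim$truth$planted)) {
    cl <- sets[[paste0(g, "_vs_control")]]
    expect_setequal(cl$up, sim$truth$planted[[g]]$up)
    expect_setequal(cl$down, sim$truth$planted[[g]]$down)
  }
})

test_that("undeclared comparison groups are an error", {
  pub <- published_abundance_matrix("top30")
  expect_error(fold_changes(pub$abund, pub$design, c("highHz", "none")), "none")
})
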