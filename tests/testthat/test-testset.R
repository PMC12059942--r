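cluster_of_test <- function(cl, accs) unname(unclass(cl)[accs])

ts_entry <- function(id, acc = "P1", mclass = "small_molecule",
                     n_res = 500L, nucleic = FALSE) {
  allosteric_entry(id, paste0("1", substr(id, 2, 4)), acc,
                   list(site_annotation("allosteric", "A:1",
                                        modulator_alias = "LIG",
                                        modulator_class = mclass)),
                   list(site_annotation("active", "A:9")),
                   n_protein_residues = n_res, has_nucleic = nucleic)
}

test_that("training-cluster exclusion drops any-match entries", {
  cl <- cluster_table(c("P1", "P2", "P3"), c("C1", "C1", "C2"))
  entries <- list(ts_entry("E001", "P2"), ts_entry("E002", "P3"),
                  ts_entry("E003", c("P3", "P2")))
  res <- exclude_training_clusters(entries, cl, "P1")
  expect_equal(vapply(res$kept, `[[`, character(1), "entry_id"), "E002")
  expect_setequal(vapply(res$dropped, `[[`, character(1), "drop_reason"),
                  "training_overlap")
  # empty training set keeps everything
  all_kept <- exclude_training_clusters(entries, cl, character())
  expect_length(all_kept$kept, 3)
  # unknown cluster: conservative drop, flagged
  res2 <- exclude_training_clusters(list(ts_entry("E004", "P9")), cl, "P1")
  expect_length(res2$kept, 0)
  expect_true("unknown_cluster" %in% res2$dropped[[1]]$flags)
})

test_that("modulator-class, size and nucleic filters apply their boundaries", {
  entries <- list(ts_entry("M001"), ts_entry("M002", mclass = "ion"),
                  ts_entry("M003", mclass = "peptide"))
  res <- filter_modulator_type(entries)
  expect_equal(vapply(res$kept, `[[`, character(1), "entry_id"), "M001")

  sz <- filter_size(list(ts_entry("S001", n_res = 8000L),
                         ts_entry("S002", n_res = 8001L),
                         ts_entry("S003", n_res = 500L)))
  expect_equal(vapply(sz$kept, `[[`, character(1), "entry_id"),
               c("S001", "S003"))  # exactly 8000 kept: "more than" is strict
  expect_equal(sz$dropped[[1]]$drop_reason, "size")

  nu <- filter_nucleic(list(ts_entry("N001", nucleic = TRUE),
                            ts_entry("N002")))
  expect_equal(vapply(nu$kept, `[[`, character(1), "entry_id"), "N002")
})

test_that("nucleic detection is scoped to polymer residues", {
  pdb <- plant_modulator(make_synthetic_structure(n_residues = 10), 5:6,
                         alias = "DA", het_resno = 950)
  s <- parse_lines(pdb)  # DA present only as a hetero ligand
  expect_false(has_nucleic_chains(s))
})

test_that("the kept set is invariant under filter order", {
  cl <- cluster_table(c("P1", "P2", "P3", "P4"), c("C1", "C1", "C2", "C3"))
  entries <- list(ts_entry("O001", "P2"),
                  ts_entry("O002", "P3", mclass = "ion"),
                  ts_entry("O003", "P3", n_res = 9000L),
                  ts_entry("O004", "P4", nucleic = TRUE),
                  ts_entry("O005", "P3"),
                  ts_entry("O006", "P2", mclass = "ion", n_res = 9000L))
  filters <- list(
    function(e) exclude_training_clusters(e, cl, "P1"),
    filter_modulator_type,
    filter_size,
    filter_nucleic)
  apply_in_order <- function(ord) {
    kept <- entries
    for (f in filters[ord]) kept <- f(kept)$kept
    sort(vapply(kept, `[[`, character(1), "entry_id"))
  }
  ref <- apply_in_order(1:4)
  expect_equal(ref, "O005")
  for (perm in list(c(2, 1, 4, 3), c(4, 3, 2, 1), c(3, 1, 4, 2)))
    expect_equal(apply_in_order(perm), ref)
  # canonical order attributes the first-triggered reason
  res <- apply_testset_filters(entries, cl, "P1")
  reasons <- setNames(vapply(res$dropped, `[[`, character(1), "drop_reason"),
                      vapply(res$dropped, `[[`, character(1), "entry_id"))
  expect_equal(unname(reasons["O006"]), "training_overlap")
  expect_equal(unname(reasons["O002"]), "modulator_class")
  expect_length(c(res$kept, res$dropped), length(entries))
})

test_that("test-set assembly samples deterministically with cluster uniqueness", {
  cl <- cluster_table(sprintf("P%03d", 1:40),
                      sprintf("C%03d", rep(1:20, each = 2)))
  entries <- lapply(1:40, function(i)
    ts_entry(sprintf("A%03d", i), sprintf("P%03d", i)))
  # fewer survivors than requested: all returned
  expect_length(assemble_testset(entries[1:5], cl, n = 100), 5)
  sub1 <- assemble_testset(entries, cl, n = 10, seed = 7)
  sub2 <- assemble_testset(entries, cl, n = 10, seed = 7)
  expect_identical(sub1, sub2)
  expect_length(sub1, 10)
  # at most one entry per cluster
  accs <- vapply(sub1, function(e) e$accessions[1], character(1))
  expect_false(anyDuplicated(cluster_of_test(cl, accs)) > 0)
  expect_error(assemble_testset(entries, cl, n = 0), "positive")
})
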