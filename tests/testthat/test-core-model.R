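test_that("residue tokens round-trip and validate", {
  toks <- res_token(c("A", "B"), c(10, 52), c("", "A"))
  expect_equal(toks, c("A:10", "B:52A"))
  df <- parse_res_tokens(toks)
  expect_equal(df$chain, c("A", "B"))
  expect_equal(df$number, c(10L, 52L))
  expect_equal(df$icode, c("", "A"))
  expect_error(res_token("", 1), "non-empty")
  expect_error(parse_res_tokens("A10"), "unparseable")
  # identity ignores the advisory residue name: tokens carry no name at all
  expect_equal(sort_res_tokens(c("A:2", "A:10", "A:2")), c("A:10", "A:2"))
})

test_that("site annotations enforce their invariants", {
  expect_error(site_annotation("allosteric", character()), "no residues")
  expect_error(site_annotation("active", "A:1", modulator_alias = "ATP"),
               "no modulator alias")
  s <- site_annotation("allosteric", c("A:2", "A:1"),
                       modulator_alias = "ATP",
                       modulator_class = "small_molecule")
  expect_equal(s$residues, c("A:1", "A:2"))
})

test_that("entry status and drop reason must coincide", {
  site_a <- site_annotation("allosteric", "A:1")
  site_o <- site_annotation("active", "A:9")
  e <- allosteric_entry("E1", "1ABC", "P1", list(site_a), list(site_o))
  expect_equal(e$status, "kept")
  expect_error(allosteric_entry("E2", "1ABC", "P1", list(site_a),
                                list(site_o), drop_reason = "x"),
               "coincide")
  expect_error(allosteric_entry("E3", "1ABC", "P1", status = "dropped"),
               "coincide")
  expect_error(allosteric_entry("E4", "1ABC", "P1"), "at least one")
  d <- drop_entry(e, "resolution")
  expect_equal(d$status, "dropped")
})

make_fixture_entries <- function() {
  site <- function(res, ...) site_annotation("allosteric", res,
                                             modulator_alias = "LIG",
                                             modulator_class = "small_molecule",
                                             source = "derived_geometric", ...)
  act <- function(res, src = "UniProt") site_annotation("active", res,
                                                        source = src)
  list(
    allosteric_entry("E1", "1AAA", "P00001", list(site(c("A:8", "A:9"))),
                     list(act(c("A:3", "A:15"))), resolution = 2.1,
                     n_protein_residues = 30L),
    allosteric_entry("E2", "1BBB", c("P00002", "P00003"),
                     list(site(c("A:8", "B:8")), site(c("B:40", "B:41"))),
                     list(act("A:3"), act("B:3", src = "MCSA")),
                     resolution = 3.5, lddt = 0.91,
                     n_protein_residues = 60L,
                     flags = c("has_gaps", "modeled")),
    allosteric_entry("E3", "1CCC", "P00004", list(site("A:12")),
                     list(act("A:2")), resolution = NA,
                     flags = "no_resolution"),
    allosteric_entry("E4", "1DDD", "P00005", status = "dropped",
                     drop_reason = "pdb_removed")
  )
}

test_that("dataset CSV writes one row per (entry, allosteric site)", {
  entries <- make_fixture_entries()
  path <- withr::local_tempfile(fileext = ".csv")
  # 3 kept entries with 1+2+1 sites, plus one drop row
  expect_equal(write_dataset_csv(entries, path), 5L)
  expect_equal(write_dataset_csv(list(), path), 0L)
  lines <- readLines(path)
  expect_equal(lines[1], "# allobench-dataset-v1")
  expect_length(lines, 2L)  # marker + header only
})

test_that("dataset CSV round-trips losslessly", {
  entries <- make_fixture_entries()
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(entries, path)
  back <- read_dataset_csv(path)
  expect_identical(back, entries)
})

test_that("dataset reader rejects schema violations", {
  entries <- make_fixture_entries()
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(entries, path)
  df <- read.csv(path, comment.char = "#")
  df$allosteric_residues <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# allobench-dataset-v1",
               capture.output(write.csv(df, row.names = FALSE))), path2)
  expect_error(read_dataset_csv(path2), "allosteric_residues")

  df2 <- read.csv(path, comment.char = "#")
  df2$allosteric_residues[df2$entry_id == "E1"] <- ""
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# allobench-dataset-v1",
               capture.output(write.csv(df2, row.names = FALSE))), path3)
  expect_error(read_dataset_csv(path3), "empty allosteric_residues")
})

test_that("config round-trips through its file format", {
  cfg <- allobench_config(distance_cutoff_A = 5, min_lddt = 0.7)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$distance_cutoff_A, 5)
  expect_equal(cfg2$min_lddt, 0.7)
  expect_equal(cfg2$lddt_thresholds, c(0.5, 1, 2, 4))
  writeLines("nonsense_key=1", path)
  expect_error(read_config(path), "unknown config key")
})
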