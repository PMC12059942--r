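entry_xml <- function(id = "ASD001", pdb = "1ABC", acc = "P00001",
                      site = 'residues="A:10;A:11"', modulator = TRUE) {
  paste0('<allosteric_entry id="', id, '">',
         "<pdb_id>", pdb, "</pdb_id>",
         "<uniprot><accession>", acc, "</accession></uniprot>",
         if (!is.null(site)) paste0("<allosteric_site ", site, "/>"),
         if (modulator) '<modulator alias="ATP" class="small_molecule"/>',
         "</allosteric_entry>")
}

test_that("XML entries parse with verbatim site text", {
  e <- parse_asd_xml(entry_xml())
  expect_s3_class(e, "raw_asd_entry")
  expect_equal(e$entry_id, "ASD001")
  expect_equal(e$pdb_id, "1ABC")
  expect_equal(e$accessions, "P00001")
  expect_equal(e$allosteric_residue_text, "A:10;A:11")
  expect_equal(e$modulator_alias, "ATP")
  expect_equal(e$modulator_class, "small_molecule")
  expect_length(e$flags, 0)
})

test_that("missing site element flags the entry instead of dropping it", {
  e <- parse_asd_xml(entry_xml(site = NULL))
  expect_equal(e$allosteric_residue_text, "")
  expect_true("missing_site" %in% e$flags)
  expect_equal(e$status, "kept")
})

test_that("a batch of N files yields N entries and rejects duplicate ids", {
  dir <- withr::local_tempdir()
  for (i in 1:4)
    writeLines(entry_xml(id = sprintf("ASD%03d", i)),
               file.path(dir, sprintf("e%d.xml", i)))
  entries <- parse_asd_batch(dir)
  expect_length(entries, 4)
  writeLines(entry_xml(id = "ASD001"), file.path(dir, "dup.xml"))
  expect_error(parse_asd_batch(dir), "duplicate entry id")
  expect_error(parse_asd_xml("<open><unclosed>"), "malformed XML")
})

make_test_resolver <- function() {
  fixture_resolver(
    pdb_map = c(OLD1 = "NEW1", GONE = NA),
    chain_maps = list(NEW1 = c(A = "P00001", B = "P00002"),
                      "2XYZ" = c(A = "P99999")))
}

test_that("identifier reconciliation updates, drops and is idempotent", {
  r <- make_test_resolver()
  e <- parse_asd_xml(entry_xml(pdb = "OLD1"))
  e1 <- reconcile_identifiers(e, r)
  expect_equal(e1$pdb_id, "NEW1")
  expect_equal(e1$status, "kept")
  expect_true("pdb_id_updated" %in% e1$flags)
  expect_identical(reconcile_identifiers(e1, r)[c("pdb_id", "status")],
                   e1[c("pdb_id", "status")])

  gone <- reconcile_identifiers(parse_asd_xml(entry_xml(pdb = "GONE")), r)
  expect_equal(gone$status, "dropped")
  expect_equal(gone$drop_reason, "pdb_removed")

  mism <- reconcile_identifiers(parse_asd_xml(entry_xml(pdb = "2XYZ")), r)
  expect_equal(mism$drop_reason, "id_discrepancy")
})

test_that("active-site merge is the per-accession union, commutative and idempotent", {
  uni <- data.frame(accession = "P1", position = c(10L, 20L))
  mcsa <- data.frame(accession = c("P1", "P1", "P2"),
                     position = c(20L, 30L, 30L))
  m <- merge_active_sites(uni, mcsa)
  expect_equal(active_site_positions(m, "P1"), c(10L, 20L, 30L))
  expect_equal(active_site_positions(m, "P2"), 30L)
  expect_equal(m$sources[m$accession == "P1" & m$position == 20L],
               "MCSA;UniProt")
  # commutative in the two sources (up to the provenance labels)
  m2 <- merge_active_sites(mcsa, uni)
  expect_equal(m2[, c("accession", "position")],
               m[, c("accession", "position")])
  # idempotent: merging the merge with itself changes nothing
  m3 <- merge_active_sites(m[, c("accession", "position")],
                           m[, c("accession", "position")])
  expect_equal(m3[, c("accession", "position")],
               m[, c("accession", "position")])
  empty <- merge_active_sites(NULL, NULL)
  expect_equal(nrow(empty), 0L)
})

test_that("site text parses both dialects and flags ambiguity", {
  expect_equal(parse_site_text("A:10; A:11")$residues, c("A:10", "A:11"))
  expect_equal(parse_site_text("10;11", default_chain = "B")$residues,
               c("B:10", "B:11"))
  amb <- parse_site_text("10;11", default_chain = c("A", "B"))
  expect_equal(amb$flags, "ambiguous_chain_assignment")
  expect_length(amb$residues, 0)
})

test_that("completeness and resolution filters partition without loss", {
  site <- site_annotation("allosteric", "A:1")
  act <- site_annotation("active", "A:9")
  entries <- list(
    allosteric_entry("C1", "1AAA", "P1", list(site), list(act), resolution = 3.9),
    allosteric_entry("C2", "1BBB", "P1", list(site), list(act), resolution = 4.1),
    allosteric_entry("C3", "1CCC", "P1", list(site), list(act), resolution = 4.0),
    allosteric_entry("C4", "1DDD", "P1", list(site), list(act), resolution = NA))

  res <- filter_resolution(entries, cutoff = 4.0)
  expect_equal(vapply(res$kept, `[[`, character(1), "entry_id"),
               c("C1", "C4"))
  expect_equal(vapply(res$dropped, `[[`, character(1), "entry_id"),
               c("C2", "C3"))  # exactly 4.0 is dropped: strictly better than
  expect_true(all(vapply(res$dropped, `[[`, character(1), "drop_reason") ==
                    "resolution"))
  expect_true("no_resolution" %in% res$kept[[2]]$flags)
  expect_length(c(res$kept, res$dropped), length(entries))
})

test_that("completeness selection requires both site kinds", {
  site <- site_annotation("allosteric", "A:1")
  act <- site_annotation("active", "A:9")
  e_ok <- allosteric_entry("S1", "1AAA", "P1", list(site), list(act))
  e_no_act <- allobench:::new_entry(entry_id = "S2", pdb_id = "1BBB",
                                    allosteric_sites = list(site))
  e_no_allo <- allobench:::new_entry(entry_id = "S3", pdb_id = "1CCC",
                                     active_sites = list(act))
  e_none <- allobench:::new_entry(entry_id = "S4", pdb_id = "1DDD")
  e_ok2 <- allosteric_entry("S5", "1EEE", "P1", list(site), list(act))
  res <- select_complete_entries(list(e_ok, e_no_act, e_no_allo, e_none, e_ok2))
  expect_length(res$kept, 2)
  expect_length(res$dropped, 3)
  expect_setequal(vapply(res$dropped, `[[`, character(1), "drop_reason"),
                  "incomplete_annotation")
})
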