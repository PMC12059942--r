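test_that("synthetic PDB parses with correct chains, atoms and metadata", {
  pdb <- make_synthetic_structure(n_chains = 2, n_residues = 20,
                                  resolution = 2.5)
  s <- parse_lines(pdb)
  expect_setequal(unique(s$atoms$chain), c("A", "B"))
  # 2 chains x 20 residues x 5 heavy atoms, matching the ATOM record count
  expect_equal(nrow(s$atoms), sum(grepl("^ATOM", pdb)))
  expect_equal(nrow(s$atoms), 200L)
  expect_equal(s$resolution, 2.5)
  expect_equal(s$n_models, 1L)
  expect_equal(nchar(seqres_sequence(s, "A")), 20L)
})

test_that("multi-MODEL files report their model count", {
  pdb <- make_synthetic_structure(n_residues = 10, n_models = 3)
  s <- parse_lines(pdb)
  expect_equal(s$n_models, 3L)
})

test_that("mmCIF input raises the dedicated drop signal", {
  cif <- "data_1ABC\nloop_\n_atom_site.group_PDB\nATOM 1"
  expect_error(parse_structure(cif), class = "allobench_mmcif")
  cond <- tryCatch(parse_structure(cif),
                   allobench_mmcif = function(c) c)
  expect_match(conditionMessage(cond), "mmcif_only")
})

test_that("merging models preserves atoms exactly and relabels chains", {
  one <- parse_lines(make_synthetic_structure(n_residues = 10))
  expect_identical(merge_models(one), one)

  two <- parse_lines(make_synthetic_structure(n_residues = 10, n_models = 2))
  m2 <- merge_models(two)
  expect_equal(m2$n_models, 1L)
  expect_setequal(unique(m2$atoms$chain), c("A", "B"))
  expect_equal(nrow(m2$atoms), nrow(two$atoms))

  six <- parse_lines(make_synthetic_structure(n_chains = 2, n_residues = 8,
                                              n_models = 3))
  m6 <- merge_models(six)
  expect_setequal(unique(m6$atoms$chain), c("A", "B", "C", "D", "E", "F"))
  expect_equal(nrow(m6$atoms), 3L * 2L * 8L * 5L)
  # per-atom coordinates preserved exactly (model k shifted by 10(k-1) A)
  zs <- sort(unique(round(m6$atoms$z[m6$atoms$atom == "CA"], 3)))
  expect_equal(zs, c(0, 10, 20))
  # SEQRES replicated onto the relabeled chains
  expect_equal(seqres_sequence(m6, "F"), seqres_sequence(six, "B"))
})

test_that("gap detection reports exactly the missing SEQRES ranges", {
  s <- parse_lines(make_synthetic_structure(n_residues = 20,
                                            gap_ranges = list(c(8, 10))))
  rep_ <- find_missing_residues(s)
  expect_equal(rep_$A$gaps$start, 8L)
  expect_equal(rep_$A$gaps$end, 10L)
  expect_equal(nchar(rep_$A$gaps$missing_sequence), 3L)
  expect_false(rep_$A$sequence_conflict)

  full <- parse_lines(make_synthetic_structure(n_residues = 20))
  expect_equal(nrow(find_missing_residues(full)$A$gaps), 0L)

  nterm <- parse_lines(make_synthetic_structure(n_residues = 20,
                                                gap_ranges = list(c(1, 2))))
  g <- find_missing_residues(nterm)$A$gaps
  expect_equal(c(g$start, g$end), c(1L, 2L))
})

test_that("target/template strings are equal length and invert to the observed sequence", {
  # randomized gap patterns; gap runs are kept >= 4 residues apart so the
  # optimal alignment is the pure-deletion one (merging two nearby gaps
  # into one plus substitutions could otherwise score higher)
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(15:40, 1)
    starts <- seq(3, n - 4, by = 7)
    starts <- sort(sample(starts, min(length(starts), sample(0:2, 1))))
    gaps <- lapply(starts, function(st) c(st, st + sample(0:2, 1)))
    s <- parse_lines(make_synthetic_structure(n_residues = n,
                                              gap_ranges = gaps))
    aln <- build_target_template_alignment(s)
    expect_equal(nchar(aln$A$target), nchar(aln$A$template))
    obs <- paste(aa_three_to_one(observed_residues(s, "A")$name),
                 collapse = "")
    expect_equal(gsub("-", "", aln$A$template), obs)
    expect_equal(aln$A$target, seqres_sequence(s, "A"))
  }
})

test_that("alignment JSON serializes per chain with gap symbols", {
  s <- parse_lines(make_synthetic_structure(n_residues = 20,
                                            gap_ranges = list(c(8, 10))))
  aln <- build_target_template_alignment(s)
  path <- withr::local_tempfile(fileext = ".json")
  write_alignment_json(aln, path)
  j <- jsonlite::read_json(path)
  expect_equal(substr(j$A$template, 8, 10), "---")
  expect_equal(j$A$target, seqres_sequence(s, "A"))
})

test_that("stripping heteroatoms removes ligands and empty chains, idempotently", {
  pdb <- plant_modulator(make_synthetic_structure(n_residues = 20), 5:7)
  s <- parse_lines(pdb)
  n_het <- sum(s$atoms$hetero)
  expect_gt(n_het, 0)
  st <- strip_heteroatoms(s)
  expect_equal(nrow(st$atoms), nrow(s$atoms) - n_het)
  expect_identical(strip_heteroatoms(st), st)

  clean <- parse_lines(make_synthetic_structure(n_residues = 10))
  expect_equal(nrow(strip_heteroatoms(clean)$atoms), nrow(clean$atoms))
})

test_that("altloc duplicates resolve to the highest-occupancy conformer", {
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CA  ALA A   2       3.800   0.000   0.000  1.00 10.00           C",
    "END")
  s <- parse_structure(paste(lines, collapse = "\n"))
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(s$atoms$x[s$atoms$resno == 1], 5.0)  # occupancy 0.60 wins
})
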