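test_that("identical sequences align gaplessly with score = length", {
  a <- align_sequences("MKTAYIAKQR", "MKTAYIAKQR")
  expect_equal(a$score, 10)
  expect_equal(a$a_aln, a$b_aln)
  expect_equal(a$identity, 1)
  expect_equal(align_sequences("W", "W")$score, 1)
  expect_error(align_sequences("", "A"), "empty")
})

test_that("a middle deletion opens a single contiguous gap", {
  a <- align_sequences("ACDEFGHIKL", "ACDEFGKL")  # HI deleted... 3-residue case
  expect_equal(gsub("[^-]", "", a$b_aln), "--")
  b <- align_sequences("ACDEFGHIKLMN", "ACDEFGKLMN")
  expect_equal(a$score, oracle_align_score("ACDEFGHIKL", "ACDEFGKL"))
  expect_equal(b$score, oracle_align_score("ACDEFGHIKLMN", "ACDEFGKLMN"))
  expect_match(b$b_aln, "^ACDEFG--KLMN$|ACDEFG-.KLMN")
})

test_that("alignment scores match the exhaustive recursion oracle on short strings", {
  set.seed(101)
  for (trial in 1:120) {
    la <- sample(1:12, 1); lb <- sample(1:12, 1)
    a <- random_seq(la); b <- random_seq(lb)
    expect_equal(align_sequences(a, b)$score, oracle_align_score(a, b),
                 info = paste(a, b))
  }
  # including sequences containing the wildcard X (matches nothing)
  for (trial in 1:30) {
    a <- random_seq(sample(2:10, 1), alphabet = c("A", "C", "X"))
    b <- random_seq(sample(2:10, 1), alphabet = c("A", "C", "X"))
    expect_equal(align_sequences(a, b)$score, oracle_align_score(a, b),
                 info = paste(a, b))
  }
})

test_that("alignment scores agree with an independent aligner", {
  mat <- matrix(-1, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(mat) <- 1
  set.seed(77)
  for (trial in 1:25) {
    a <- random_seq(sample(5:40, 1), alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
    b <- random_seq(sample(5:40, 1), alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = mat, gapOpening = 5, gapExtension = 1,
      type = "global"))
    expect_equal(align_sequences(a, b)$score, ref, info = paste(a, b))
  }
})

obs_df <- function(seq1, numbers, chain = "A") {
  data.frame(chain = chain, number = numbers,
             icode = "", name = bio3d::aa123(strsplit(seq1, "")[[1]]),
             stringsAsFactors = FALSE)
}

test_that("identity numbering yields the identity mapping", {
  canon <- "ACDEFGHIKLMNPQRSTVWY"
  m <- map_residue_numbers(canon, obs_df(canon, 1:20))
  expect_equal(m$pairs$canonical_pos, 1:20)
  expect_equal(m$pairs$number, 1:20)
  expect_equal(m$coverage, 1)
  expect_false(m$unalignable)
  r <- remap_site(c(10, 20), m)
  expect_equal(r$site, sort_res_tokens(c("A:10", "A:20")))
  expect_length(r$unmapped, 0)
})

test_that("a constant author-numbering offset is recovered everywhere", {
  canon <- "ACDEFGHIKLMNPQRSTVWY"
  m <- map_residue_numbers(canon, obs_df(canon, 1:20 + 24L))
  expect_equal(m$pairs$number, m$pairs$canonical_pos + 24L)
  r <- remap_site(10, m)
  expect_equal(r$site, "A:34")
})

test_that("positions inside structural gaps come back unmapped, never lost", {
  canon <- "ACDEFGHIKLMNPQRSTVWY"
  obs <- obs_df(canon, 1:20)[-(8:10), ]  # residues 8-10 unobserved
  m <- map_residue_numbers(canon, obs)
  expect_equal(sort(setdiff(1:20, m$pairs$canonical_pos)), 8:10)
  r <- remap_site(c(5, 9, 15), m)
  expect_equal(r$unmapped, 9L)
  expect_equal(r$site, sort_res_tokens(c("A:5", "A:15")))
  # conservation of positions: |mapped| + |unmapped| == |input|
  expect_equal(length(r$site) + length(r$unmapped), 3L)
})

test_that("mapping is injective and low-identity chains are flagged", {
  set.seed(5)
  for (trial in 1:20) {
    canon <- random_seq(sample(10:30, 1),
                        alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
    drop <- sort(sample(nchar(canon), sample(0:3, 1)))
    obs_seq <- paste(strsplit(canon, "")[[1]][setdiff(seq_len(nchar(canon)),
                                                      drop)], collapse = "")
    m <- map_residue_numbers(canon, obs_df(obs_seq,
                                           seq_len(nchar(obs_seq))))
    expect_false(anyDuplicated(m$pairs$canonical_pos) > 0)
    expect_false(anyDuplicated(paste(m$pairs$chain, m$pairs$number,
                                     m$pairs$icode)) > 0)
  }
  unrelated <- map_residue_numbers("AAAAAAAAAAAA",
                                   obs_df("WWWWWWWWWWWW", 1:12))
  expect_true(unrelated$unalignable)
})

test_that("nonstandard residues translate via the documented table", {
  expect_equal(aa_three_to_one(c("ALA", "MSE", "SEP", "ZZZ")),
               c("A", "M", "S", "X"))
})
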