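test_that("the Jaccard index matches its definition at the anchors", {
  K <- res_token("A", 1:10)
  expect_equal(jaccard_index(K, K), 1)
  expect_equal(jaccard_index(K, res_token("B", 1:10)), 0)
  expect_equal(jaccard_index(K, character()), 0)
  expect_error(jaccard_index(character(), K), "empty_known_site")
  # symmetric
  P <- res_token("A", 6:15)
  expect_equal(jaccard_index(K, P), jaccard_index(P, K))
})

test_that("the Jaccard index equals brute-force set arithmetic on random pairs", {
  set.seed(11)
  pool <- res_token(rep(c("A", "B"), each = 50), rep(1:50, 2))
  for (trial in 1:300) {
    K <- sample(pool, sample(1:30, 1))
    P <- sample(pool, sample(0:30, 1))
    expect_equal(jaccard_index(K, P), oracle_ji(K, P))
  }
})

test_that("equal-size sets with overlap m score m/(2n - m)", {
  for (n in 1:20) {
    for (m in 0:n) {
      K <- res_token("A", 1:n)
      P <- res_token("A", c(seq_len(m), n + seq_len(n - m)))
      expect_equal(jaccard_index(K, P), m / (2 * n - m))
    }
  }
})

test_that("the topmost prediction is matched to the best known site", {
  top <- res_token("A", 1:5)
  s1 <- res_token("B", 1:5)
  s2 <- res_token("A", 1:5)
  m <- best_ji_match(top, list(s1, s2))
  expect_equal(m$ji, 1)
  expect_equal(m$index, 2L)
  expect_equal(best_ji_match(top, list(s2))$ji, jaccard_index(s2, top))
  empty <- best_ji_match(character(), list(s1, s2))
  expect_equal(empty$ji, 0)
  expect_equal(empty$index, 1L)  # ties resolve to the lowest index
})

test_that("centroid distances follow hand-constructed coordinates", {
  s <- parse_lines(make_synthetic_structure(n_residues = 20))
  # CA atoms sit at x = 3.8 * resno: single-residue sites 10 residues apart
  cd <- centroid_distance("A:2", "A:12", s)
  expect_equal(cd$distance, 38)
  expect_equal(cd$inverse, 1 / 38)
  same <- centroid_distance(res_token("A", 1:4), res_token("A", 1:4), s)
  expect_equal(same$distance, 0)
  expect_true(same$coincident)
  expect_true(is.na(same$inverse))
  # 3-4-5 triangle built from two synthetic single-atom sites
  cl <- cloud_structure(2, 1, 1)
  cl$s$atoms$atom <- "CA"
  cl$s$atoms$x[1:3] <- 0; cl$s$atoms$y[1:3] <- 0; cl$s$atoms$z[1:3] <- 0
  cl$s$atoms$x[4:6] <- 3; cl$s$atoms$y[4:6] <- 4; cl$s$atoms$z[4:6] <- 0
  cd2 <- centroid_distance("A:1", "A:2", cl$s)
  expect_equal(cd2$distance, 5)
  expect_equal(cd2$inverse, 0.2)
  expect_error(centroid_distance("Z:99", "A:1", s), "site_a")
})

test_that("spurious residues are removed while correct ones are retained", {
  s <- parse_lines(make_synthetic_structure(n_residues = 20))
  p <- prediction_record("toolA", "SYN1",
                         list(list(residues = c("A:10", "A:9999"))))
  np <- normalize_prediction(p, s)
  expect_equal(np$ranked_sites[[1]]$residues, "A:10")
  expect_equal(attr(np, "n_spurious"), 1L)
  ok <- prediction_record("toolA", "SYN1", list(list(residues = "A:10")))
  expect_equal(attr(normalize_prediction(ok, s), "n_spurious"), 0L)
  all_bad <- prediction_record("toolA", "SYN1",
                               list(list(residues = c("B:5", "A:9999"))))
  nb <- normalize_prediction(all_bad, s)
  expect_length(nb$ranked_sites, 0)
})

test_that("accuracy curves count strictly-above fractions and never increase", {
  results <- data.frame(protein_id = paste0("p", 1:3), tool = "t",
                        ji = c(0, 0.2, 0.6), failed = FALSE)
  cv <- accuracy_curve(results, cutoffs = c(0, 0.5))
  expect_equal(cv$percent_above, c(100 * 2 / 3, 100 * 1 / 3))
  allpos <- data.frame(protein_id = paste0("p", 1:4), tool = "t",
                       ji = c(0.2, 0.4, 0.6, 0.9), failed = FALSE)
  expect_equal(accuracy_curve(allpos, 0)$percent_above, 100)
  zeros <- data.frame(protein_id = paste0("p", 1:4), tool = "t", ji = 0,
                      failed = TRUE)
  expect_true(all(accuracy_curve(zeros, c(0, 0.3))$percent_above == 0))
  dup <- rbind(results, results[1, ])
  expect_error(accuracy_curve(dup), "duplicate")
  # non-increasing for randomized result sets
  set.seed(3)
  rnd <- data.frame(protein_id = paste0("p", 1:50), tool = "t",
                    ji = round(runif(50), 2), failed = FALSE)
  cv2 <- accuracy_curve(rnd, seq(0, 1, 0.05))
  expect_true(all(diff(cv2$percent_above) <= 0))
})

test_that("summaries report median and mean including assigned zeros", {
  res <- data.frame(protein_id = paste0("p", 1:3), tool = "t",
                    ji = c(0, 0, 1), failed = c(TRUE, TRUE, FALSE))
  sm <- summarize_benchmark(res)
  expect_equal(sm$median_ji, 0)
  expect_equal(sm$mean_ji, 1 / 3)
  expect_equal(sm$n_failed, 2L)
  one <- summarize_benchmark(data.frame(protein_id = "p", tool = "t",
                                        ji = 0.42, failed = FALSE))
  expect_equal(c(one$median_ji, one$mean_ji), c(0.42, 0.42))
  same <- summarize_benchmark(data.frame(protein_id = paste0("p", 1:4),
                                         tool = "t", ji = 0.5,
                                         failed = FALSE))
  expect_equal(same$median_ji, same$mean_ji)
})

test_that("chain-less predictions are scored via inferred chains", {
  pdb <- plant_modulator(make_synthetic_structure(n_chains = 2,
                                                  n_residues = 20),
                         5:8, chain = "B")
  s <- parse_lines(pdb)
  K <- extract_site(s, resolve_modulator(s = s, alias = "LIG")[[1]])
  p <- prediction_record("bare", "SYN1",
                         list(list(residues = as.character(5:8))))
  res <- score_predictions(list(p), list(SYN1 = list(K)),
                           list(SYN1 = s))
  expect_equal(res$ji, 1)
  expect_true(res$chain_inferred)
})

test_that("prediction files round-trip through both on-disk formats", {
  dir <- withr::local_tempdir()
  jsonlite::write_json(list(tool = "tj", protein_id = "P1",
                            ranked_sites = list(list(residues = c("A:1", "A:2"),
                                                     score = 0.9))),
                       file.path(dir, "a.json"), auto_unbox = TRUE)
  writeLines(c("tool\tprotein_id\trank\tresidues\tscore",
               "tt\tP2\t2\tA:7;A:8\t0.1",
               "tt\tP2\t1\tA:5;A:6\t0.7"),
             file.path(dir, "b.tsv"))
  preds <- read_predictions(dir)
  expect_length(preds, 2)
  expect_equal(preds[[1]]$tool, "tj")
  expect_equal(preds[[1]]$ranked_sites[[1]]$residues, c("A:1", "A:2"))
  # TSV rows are ordered by rank
  expect_equal(preds[[2]]$ranked_sites[[1]]$residues, c("A:5", "A:6"))
})
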