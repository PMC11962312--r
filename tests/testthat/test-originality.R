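test_that("LCS length matches hand-enumerated and degenerate cases", {
  expect_equal(lcs_length(letters[1:5], letters[1:5]), 5L)
  expect_equal(lcs_length(c("a", "b"), c("x", "y")), 0L)
  expect_equal(lcs_length(c("a", "b", "c", "d"), c("a", "x", "b", "y", "d")), 3L)
  expect_equal(lcs_length(character(), c("a")), 0L)
  # symmetry
  expect_equal(lcs_length(c("a", "b", "c"), c("c", "a", "b")),
               lcs_length(c("c", "a", "b"), c("a", "b", "c")))
})

test_that("LCS score normalizes by generated length", {
  expect_equal(lcs_score(letters[1:5], letters[1:5]), 1)
  expect_equal(lcs_score(c("a", "b", "c", "d"), c("a", "x", "b", "y", "d")), 0.75)
  expect_equal(lcs_score(c("a", "b"), c("x", "y")), 0)
  expect_error(lcs_score(character(), c("a")), "non-empty")
})

test_that("penalized score follows the gap/k rule with a cap of one", {
  gen <- c("a", "b", "c", "d", "e", "f")
  train <- c("a", "b", "x", "x", "x", "x", "c", "d")
  expect_equal(penalized_lcs_score(gen, train, k = 20), (4 - 4 / 20) / 6)
  expect_equal(penalized_lcs_score(gen, train, k = 1), (4 - 1) / 6)
  # a contiguous verbatim substring incurs zero penalty
  sub <- c("c", "d", "e")
  train2 <- c("x", "c", "d", "e", "y")
  expect_equal(penalized_lcs_score(sub, train2, k = 20), lcs_score(sub, train2))
  expect_error(penalized_lcs_score(character(), train, 20), "non-empty")
  expect_error(penalized_lcs_score(gen, train, k = 0), "k")
})

test_that("both LCS variants agree with exhaustive enumeration on small pairs", {
  set.seed(101)
  for (i in 1:60) {
    a <- random_token_seq(); b <- random_token_seq()
    expect_equal(lcs_length(a, b), oracle_lcs_length(a, b))
    if (length(a) > 0) {
      for (k in c(1, 3, 20)) {
        expect_equal(penalized_lcs_score(a, b, k),
                     oracle_penalized_score(a, b, k), tolerance = 1e-12)
      }
    }
  }
})

test_that("penalized score is monotone in k and bounded by [0, 1]", {
  set.seed(202)
  ks <- c(1, 2, 5, 20, 100)
  for (i in 1:50) {
    a <- random_token_seq(12, letters[1:5]); b <- random_token_seq(12, letters[1:5])
    if (length(a) == 0) next
    sc <- vapply(ks, function(k) penalized_lcs_score(a, b, k), 0)
    expect_true(all(diff(sc) >= -1e-12))
    expect_true(all(sc >= 0 & sc <= 1))
  }
})

test_that("classic-path mode never exceeds the optimizing chain", {
  set.seed(303)
  for (i in 1:40) {
    a <- random_token_seq(10); b <- random_token_seq(10)
    if (length(a) == 0) next
    expect_lte(penalized_lcs_score(a, b, 5, mode = "classic_path"),
               penalized_lcs_score(a, b, 5, mode = "optimal") + 1e-12)
  }
})

test_that("k = 1 scores track the longest common contiguous run approximately", {
  # with k = 1 every nonzero gap costs a full token, so a single contiguous
  # run of length L scores L; multiple runs can only add (run - 1) each
  a <- c("p", "q", "r", "z1", "s", "t")
  b <- c("p", "q", "r", "z2", "s", "t")
  run <- longest_common_run(a, b)
  expect_equal(run, 3L)
  expect_gte(penalized_lcs_score(a, b, k = 1) * length(a), run)
})

test_that("best match selects the highest-scoring training text, first on ties", {
  gen <- tibble::tibble(doc_id = "g", text = "a b c d")
  training <- tibble::tibble(
    doc_id = c("t1", "t2", "t3"),
    text = c("a q q q", "a b c q", "a b c q"))
  rep <- best_match(gen, training)
  expect_equal(rep$best_training_id, "t2")
  expect_equal(rep$lcs_score, 0.75)

  # corpus containing the generated text itself scores 1 on both
  rep2 <- best_match(gen, dplyr::bind_rows(training, tibble::tibble(doc_id = "t4", text = "a b c d")))
  expect_equal(rep2$best_training_id, "t4")
  expect_equal(rep2$lcs_score, 1)
  expect_equal(rep2$penalized_score, 1)

  disjoint <- tibble::tibble(doc_id = "t", text = "x y z")
  expect_equal(best_match(gen, disjoint)$lcs_score, 0)
  expect_error(best_match(gen, training[0, ]), "empty")
})

test_that("case folding is a config switch", {
  gen <- tibble::tibble(doc_id = "g", text = "Metforal võetud")
  tr <- tibble::tibble(doc_id = "t", text = "metforal võetud")
  expect_equal(originality_score(gen, tr)$lcs_score, 0.5)
  expect_equal(originality_score(gen, tr, case_sensitive = FALSE)$lcs_score, 1)
})

test_that("filtering partitions reports at the threshold and keeps order", {
  reports <- tibble::tibble(
    doc_id = c("g1", "g2", "g3"),
    best_training_id = "t",
    lcs_score = c(1, 0.4, 0.95), penalized_score = c(1, 0.2, 0.7), k = 20)
  out <- filter_corpus(reports, threshold = 0.9, score_field = "plain")
  expect_equal(out$removed, c("g1", "g3"))
  expect_equal(out$kept, "g2")
  out2 <- filter_corpus(reports, threshold = 1)
  expect_equal(out2$removed, "g1")
  expect_equal(filter_corpus(reports[0, ], 0.5), list(kept = character(), removed = character()))
  expect_error(filter_corpus(reports, 0), "threshold")
  expect_error(filter_corpus(reports, 1.2), "threshold")
})
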