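test_that("chunk extraction uses lenient starts and exact boundaries", {
  expect_equal(extract_chunks(c("B-DRUG", "I-DRUG", "O", "B-DISEASE")),
               tibble::tibble(class = c("DRUG", "DISEASE"),
                              start = c(0L, 3L), end = c(2L, 4L)))
  expect_equal(nrow(extract_chunks(rep("O", 5))), 0L)
  expect_equal(nrow(extract_chunks(character())), 0L)
  # orphan I starts a chunk; B always starts a new one
  expect_equal(extract_chunks(c("I-DRUG", "B-DRUG")),
               tibble::tibble(class = c("DRUG", "DRUG"),
                              start = c(0L, 1L), end = c(1L, 2L)))
  expect_equal(extract_chunks(c("I-DRUG", "I-DISEASE", "I-DISEASE"))$start, c(0L, 1L))
  expect_error(extract_chunks(c("B-FOO")), "unknown tag")
})

test_that("harmonic mean honors the printed-result relationships", {
  expect_equal(round(f1_harmonic(0.75, 0.64), 2), 0.69)
  expect_equal(f1_harmonic(1, 1), 1)
  expect_equal(f1_harmonic(0, 0.9), 0)
  expect_equal(f1_harmonic(0, 0), 0)
  expect_equal(f1_harmonic(c(0.5, 1), c(0.5, 0)), c(0.5, 0))
})

test_that("Wilson interval matches the root-finding oracle on a grid", {
  wi <- wilson_interval(8, 10)
  expect_equal(round(wi$low, 3), 0.490)
  expect_equal(round(wi$high, 3), 0.943)
  expect_equal(wilson_interval(10, 10)$high, 1)
  expect_equal(wilson_interval(0, 10)$low, 0)

  for (n in c(1, 2, 10, 57, 300)) {
    for (s in unique(c(0, 1, floor(n / 2), n))) {
      wi <- wilson_interval(s, n)
      or <- oracle_wilson(s, n)
      expect_equal(wi$low, unname(or["low"]), tolerance = 1e-6)
      expect_equal(wi$high, unname(or["high"]), tolerance = 1e-6)
      expect_lte(wi$low, s / n + 1e-12)
      expect_gte(wi$high, s / n - 1e-12)
    }
  }
  expect_error(wilson_interval(1, 0), "trials")
  expect_error(wilson_interval(5, 3), "successes")
})

test_that("Wilson width shrinks with more trials at fixed proportion", {
  widths <- vapply(c(10, 40, 160, 640), function(n) {
    wi <- wilson_interval(0.7 * n, n)
    wi$high - wi$low
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("entity-level evaluation counts exact span+class matches", {
  gold <- tibble::tibble(
    doc_id = "d", token = sprintf("t%d", 1:8),
    tag = c("B-DRUG", "I-DRUG", "O", "O", "O", "B-DISEASE", "O", "O"))
  pred <- tibble::tibble(
    doc_id = "d", token = sprintf("t%d", 1:8),
    tag = c("B-DRUG", "I-DRUG", "O", "O", "O", "O", "O", "B-DRUG"))
  ev <- evaluate_ner(pred, gold)
  m <- tidy(ev)
  drug <- m[m$class == "DRUG", ]
  expect_equal(drug$precision, 0.5)
  expect_equal(drug$recall, 1)
  expect_equal(drug$f1, 2 / 3)
  dis <- m[m$class == "DISEASE", ]
  expect_equal(dis$precision, 0)
  expect_equal(dis$recall, 0)
  expect_equal(glance(ev)$tp, 1L)
  expect_equal(glance(ev)$support, 2L)

  # identity scores 1 everywhere; empty predictions score 0
  ev2 <- evaluate_ner(gold, gold)
  expect_true(all(tidy(ev2)$f1[tidy(ev2)$support > 0] == 1))
  empty <- dplyr::mutate(gold, tag = "O")
  ev3 <- evaluate_ner(empty, gold)
  expect_true(all(tidy(ev3)$recall == 0))
  expect_true(all(tidy(ev3)$precision == 0))

  expect_error(evaluate_ner(pred[-1, ], gold), "token count mismatch")
  expect_error(evaluate_ner(dplyr::mutate(pred, doc_id = "x"), gold), "same document ids")
})

test_that("micro counts are the sums of per-class counts", {
  set.seed(99)
  pred <- random_tag_tbl(12)
  gold <- dplyr::mutate(pred, tag = random_label_seq(nrow(pred)))
  ev <- evaluate_ner(pred, gold)
  expect_equal(glance(ev)$tp, sum(tidy(ev)$tp))
  expect_equal(glance(ev)$fp, sum(tidy(ev)$fp))
  expect_equal(glance(ev)$fn, sum(tidy(ev)$fn))
})

test_that("evaluation agrees with the reference-scheme oracle on random pairs", {
  set.seed(123)
  for (rep in 1:25) {
    pred <- random_tag_tbl(6)
    gold <- dplyr::mutate(pred, tag = random_label_seq(nrow(pred)))
    ev <- tidy(evaluate_ner(pred, gold))
    or <- oracle_class_metrics(split(pred$tag, pred$doc_id),
                               split(gold$tag, gold$doc_id), ner_classes)
    expect_equal(ev$precision, or$precision, tolerance = 1e-9)
    expect_equal(ev$recall, or$recall, tolerance = 1e-9)
    expect_equal(ev$f1, or$f1, tolerance = 1e-9)
  }
})

test_that("interannotator agreement is symmetric and 1 on identity", {
  set.seed(7)
  a <- random_tag_tbl(8)
  b <- dplyr::mutate(a, tag = random_label_seq(nrow(a)))
  aa <- interannotator_agreement(a, a)
  sup <- tidy(evaluate_ner(a, a))$support
  expect_true(all(aa$f1[seq_along(sup)][sup > 0] == 1))
  ab <- interannotator_agreement(a, b)
  ba <- interannotator_agreement(b, a)
  expect_equal(ab$f1, ba$f1, tolerance = 1e-12)
  one <- tibble::tibble(doc_id = "d", token = "x", tag = "B-DRUG")
  none <- dplyr::mutate(one, tag = "O")
  expect_equal(interannotator_agreement(one, none)$f1[1], 0)
})
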