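test_that("surfaces map to whole-token spans, all occurrences, case-insensitively", {
  doc <- list(doc_id = "d", text = "võttis Metforal 500mg")
  out <- map_entities_to_spans(doc, tibble::tibble(class = "DRUG", surface = "Metforal"))
  expect_equal(nrow(out$mentions), 1L)
  expect_equal(out$mentions$start, 7L)
  expect_equal(out$mentions$end, 15L)
  expect_equal(out$mentions$token_start, 1L)
  expect_equal(out$mentions$token_end, 2L)

  out2 <- map_entities_to_spans(doc, tibble::tibble(class = "DRUG", surface = "Aspirin"))
  expect_equal(nrow(out2$mentions), 0L)
  expect_equal(out2$dropped$reason, "not_found")

  doc3 <- list(doc_id = "d", text = "EKG tehtud , EKG korratud")
  out3 <- map_entities_to_spans(doc3, tibble::tibble(class = "PROCEDURE", surface = "ekg"))
  expect_equal(nrow(out3$mentions), 2L)
  expect_equal(out3$mentions$surface, c("EKG", "EKG"))  # document-side casing
  out3f <- map_entities_to_spans(doc3, tibble::tibble(class = "PROCEDURE", surface = "ekg"),
                                 all_occurrences = FALSE)
  expect_equal(nrow(out3f$mentions), 1L)
  out3cs <- map_entities_to_spans(doc3, tibble::tibble(class = "PROCEDURE", surface = "ekg"),
                                  case_insensitive = FALSE)
  expect_equal(nrow(out3cs$mentions), 0L)

  # whitespace in the reported surface is normalized before matching
  out4 <- map_entities_to_spans(doc, tibble::tibble(class = "DRUG", surface = " Metforal   500mg "))
  expect_equal(out4$mentions$start, 7L)
  expect_equal(out4$mentions$end, 21L)

  # partial-token matches are not spans
  out5 <- map_entities_to_spans(doc, tibble::tibble(class = "DRUG", surface = "Metfora"))
  expect_equal(out5$dropped$reason, "not_found")
})

test_that("overlap resolution is greedy by length, start, then class priority", {
  m <- tibble::tibble(doc_id = "d", class = c("DRUG", "DRUG"),
                      surface = c("a b c", "b"), start = c(0L, 3L), end = c(10L, 6L),
                      token_start = c(0L, 1L), token_end = c(3L, 2L))
  expect_equal(resolve_overlaps(m)$start, 0L)

  tie <- tibble::tibble(doc_id = "d", class = c("DISEASE", "DRUG"),
                        surface = "x", start = 0L, end = 5L,
                        token_start = 0L, token_end = 1L)
  expect_equal(resolve_overlaps(tie)$class, "DRUG")

  disjoint <- tibble::tibble(doc_id = "d", class = "DRUG", surface = c("x", "y"),
                             start = c(0L, 6L), end = c(5L, 9L),
                             token_start = c(0L, 1L), token_end = c(1L, 2L))
  expect_equal(nrow(resolve_overlaps(disjoint)), 2L)
})

test_that("overlap resolution always yields pairwise disjoint spans", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(1:12, 1)
    start <- sample(0:30, n, replace = TRUE)
    len <- sample(1:8, n, replace = TRUE)
    m <- tibble::tibble(doc_id = sample(c("d1", "d2"), n, replace = TRUE),
                        class = sample(ner_classes, n, replace = TRUE),
                        surface = "s", start = start, end = start + len,
                        token_start = 0L, token_end = 1L)
    r <- resolve_overlaps(dplyr::arrange(m, doc_id, start, end))
    for (d in split(r, r$doc_id)) {
      if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
    }
  }
})

test_that("span-to-tag conversion follows IOB2 and covers partial tokens fully", {
  toks <- tokenize("a bb ccc dddd")
  m <- tibble::tibble(doc_id = "d", class = "DRUG", surface = "bb ccc",
                      start = 2L, end = 8L, token_start = 1L, token_end = 3L)
  tags <- spans_to_tags(toks, m, doc_id = "d")
  expect_equal(tags$tag, c("O", "B-DRUG", "I-DRUG", "O"))
  expect_true(is_valid_iob2(tags$tag))

  expect_equal(spans_to_tags(toks, m[0, ], doc_id = "d")$tag, rep("O", 4))

  # char span ending mid-token covers the whole token
  m2 <- dplyr::mutate(m, end = 7L)
  expect_equal(spans_to_tags(toks, m2, doc_id = "d")$tag,
               c("O", "B-DRUG", "I-DRUG", "O"))

  overlapping <- dplyr::bind_rows(m, dplyr::mutate(m, start = 5L, end = 12L))
  expect_error(spans_to_tags(toks, overlapping), "overlap")
})

test_that("training-set construction inverts the generator under zero noise", {
  g <- small_gold_fixture(n = 40, seed = 31)
  res <- batch_annotate(g$corpus, gazetteer_annotator(weakner:::default_vocab()))
  built <- build_training_set(g$corpus, res)
  expect_equal(nrow(built$dropped), 0L)
  expect_length(built$skipped, 0L)
  expect_setequal(chunk_key(built$tags),
                  with(g$gold, paste(doc_id, class, token_start, token_end)))
  # every token of every document is present
  expect_equal(nrow(built$tags), nrow(tokenize_corpus(g$corpus)))
})

test_that("unparsed and unmatched responses are logged, mismatched ids error", {
  corpus <- tibble::tibble(doc_id = c("d1", "d2"),
                           text = c("võttis Metforal", "EKG tehtud"))
  responses <- tibble::tibble(
    doc_id = c("d1", "d2"), parsed = c(TRUE, FALSE), raw = "",
    entities = list(tibble::tibble(class = "DRUG", surface = c("Metforal", "Aspirin")),
                    tibble::tibble(class = character(), surface = character())))
  built <- build_training_set(corpus, responses)
  expect_equal(built$skipped, "d2")
  expect_equal(nrow(built$dropped), 1L)
  expect_equal(built$dropped$reason, "not_found")
  expect_equal(sort(unique(built$tags$doc_id)), "d1")

  bad <- dplyr::mutate(responses, doc_id = c("d1", "zz"))
  expect_error(build_training_set(corpus, bad), "unknown document")
})

test_that("alignment never invents text", {
  g <- small_gold_fixture(n = 20, seed = 55)
  noisy <- noisy_annotator(g$gold, noise_config(drop_prob = 0.2, spurious_prob = 1,
                                                boundary_shift_prob = 0.2, seed = 8))
  res <- batch_annotate(g$corpus, noisy)
  built <- build_training_set(g$corpus, res)
  txt <- stats::setNames(g$corpus$text, g$corpus$doc_id)
  ch <- built$tags |>
    dplyr::group_by(doc_id) |>
    dplyr::group_modify(~ extract_chunks(.x$tag)) |>
    dplyr::ungroup()
  toks <- split(built$tags, built$tags$doc_id)
  for (i in seq_len(nrow(ch))) {
    d <- toks[[ch$doc_id[i]]]
    surf <- substr(txt[ch$doc_id[i]], d$start[ch$start[i] + 1] + 1, d$end[ch$end[i]])
    expect_true(grepl(surf, txt[ch$doc_id[i]], fixed = TRUE))
  }
})
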