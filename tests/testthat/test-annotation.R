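test_that("prompt templates reproduce the four styles", {
  z <- render_prompt(prompt_spec("zero_shot"), "Tekst.")
  expect_true(startsWith(z, "In the text below, give the list of:"))
  expect_true(grepl("DRUG for drug named entity", z, fixed = TRUE))
  expect_true(grepl("Words need to be in exactly the same format as in input text.", z, fixed = TRUE))
  expect_true(endsWith(z, "Text below:\nTekst."))

  e <- render_prompt(prompt_spec("estonian"), "Tekst.")
  expect_true(startsWith(e, "Loetle järgnevas tekstis"))
  expect_true(grepl("RAVIM ravimite nimeolemite jaoks", e, fixed = TRUE))
  expect_true(endsWith(e, "Tekst on järgmine:\nTekst."))

  d <- render_prompt(prompt_spec("definitions"), "Tekst.")
  expect_true(grepl("The annotation guidelines are the following:", d, fixed = TRUE))
  expect_true(grepl("DRUG - any names or active ingredients", d, fixed = TRUE))

  f <- render_prompt(prompt_spec("few_shot"), "Tekst.")
  expect_true(grepl("Here are a few examples:", f, fixed = TRUE))
  ex <- prompt_spec("few_shot")$examples
  expect_length(ex, 5)
  pos <- vapply(unlist(lapply(ex, function(p) c(p$input, p$output))),
                function(s) regexpr(s, f, fixed = TRUE)[1], 0L)
  expect_true(all(diff(pos) > 0))            # all 5 pairs, in order
  expect_true(all(pos < regexpr("Text below:", f, fixed = TRUE)[1]))
})

test_that("prompt rendering is pure and required parts are enforced", {
  s <- prompt_spec("few_shot")
  expect_identical(render_prompt(s, "abc"), render_prompt(s, "abc"))
  expect_error(prompt_spec("definitions", definitions = character()), "guideline")
  expect_error(prompt_spec("few_shot", examples = list()), "example")
})

test_that("response parsing extracts the first valid JSON object", {
  r <- parse_response('{"DRUG":["Metforal"],"PROCEDURE":[],"DISEASE":[],"SMOKING":[]}')
  expect_true(r$parsed)
  expect_equal(r$entities$surface, "Metforal")

  r2 <- parse_response('Here you go: {"DRUG": ["Aspiriin"]} hope it helps')
  expect_true(r2$parsed)
  expect_equal(r2$entities$class, "DRUG")

  r3 <- parse_response("I am sorry, I cannot help with that.")
  expect_false(r3$parsed)
  expect_equal(nrow(r3$entities), 0L)

  # scalar value becomes a one-element list; unknown keys warn
  r4 <- parse_response('{"DRUG": "Metforal"}')
  expect_equal(r4$entities$surface, "Metforal")
  expect_warning(parse_response('{"DRUG": [], "NOTES": ["x"], "SMOKING": ["suitsetab"]}'),
                 "NOTES")

  # a JSON object with no configured key does not count as parsed
  expect_false(suppressWarnings(parse_response('{"foo": 1}'))$parsed)

  # Estonian keys only when aliases are active
  est <- '{"RAVIM": ["Metforal"]}'
  expect_false(suppressWarnings(parse_response(est))$parsed)
  r5 <- parse_response(est, aliases = c(RAVIM = "DRUG"))
  expect_true(r5$parsed)
  expect_equal(r5$entities$class, "DRUG")
})

test_that("serializing entities and reparsing is the identity", {
  entities <- tibble::tibble(class = c("DRUG", "DISEASE", "DISEASE"),
                             surface = c("Metforal", "astma", "C50"))
  raw <- weakner:::entities_json(entities, ner_classes)
  back <- parse_response(raw)
  expect_true(back$parsed)
  expect_equal(dplyr::arrange(back$entities, class, surface),
               dplyr::arrange(entities, class, surface))
})

test_that("gazetteer annotation finds whole-token surfaces per class", {
  gaz <- list(DRUG = c("Metforal"), DISEASE = c("astma"), SMOKING = character())
  r <- gazetteer_annotate("Patsient võttis Metforal, astma anamneesis", gaz)
  expect_true(r$parsed)
  expect_setequal(r$entities$surface, c("Metforal", "astma"))
  # no partial-token hits
  r2 <- gazetteer_annotate("Metforalium ei sobi", gaz)
  expect_equal(nrow(r2$entities), 0L)
  # same surface in two classes is reported under both
  gaz2 <- list(DRUG = "ravim", PROCEDURE = "ravim")
  r3 <- gazetteer_annotate("see ravim toimib", gaz2)
  expect_equal(sort(r3$entities$class), c("DRUG", "PROCEDURE"))
  expect_error(gazetteer_annotate("x", list()), "non-empty")
})

test_that("zero noise reproduces the gold surfaces exactly", {
  g <- small_gold_fixture(n = 25, seed = 9)
  cfg <- noise_config(seed = 4)
  for (id in unique(g$gold$doc_id)[1:10]) {
    doc <- g$corpus[g$corpus$doc_id == id, ]
    gold <- g$gold[g$gold$doc_id == id, ]
    r <- perturb_annotations(gold, cfg, doc)
    expect_true(r$parsed)
    expect_setequal(paste(r$entities$class, r$entities$surface),
                    unique(paste(gold$class, gold$surface)))
  }
})

test_that("full drop empties every class and garbling is seed-stable", {
  g <- small_gold_fixture(n = 10, seed = 9)
  doc <- g$corpus[1, ]
  gold <- g$gold[g$gold$doc_id == doc$doc_id, ]
  r <- perturb_annotations(gold, noise_config(drop_prob = 1, seed = 3), doc)
  expect_true(r$parsed)
  expect_equal(nrow(r$entities), 0L)

  cfg <- noise_config(garble_prob = 0.5, seed = 13)
  flags1 <- vapply(g$corpus$doc_id, function(id) {
    perturb_annotations(g$gold[g$gold$doc_id == id, ], cfg,
                        g$corpus[g$corpus$doc_id == id, ])$parsed
  }, TRUE)
  flags2 <- vapply(g$corpus$doc_id, function(id) {
    perturb_annotations(g$gold[g$gold$doc_id == id, ], cfg,
                        g$corpus[g$corpus$doc_id == id, ])$parsed
  }, TRUE)
  expect_identical(flags1, flags2)
  expect_true(any(!flags1))
})

test_that("batch annotation preserves order, counts parses, survives failures", {
  g <- small_gold_fixture(n = 12, seed = 21)
  res <- batch_annotate(g$corpus, gazetteer_annotator(weakner:::default_vocab()))
  expect_equal(res$doc_id, g$corpus$doc_id)
  expect_equal(sum(res$parsed), nrow(g$corpus))

  flaky <- function(text, doc_id, prompt = NULL) {
    if (doc_id == g$corpus$doc_id[3]) stop("boom")
    '{"DRUG": []}'
  }
  res2 <- batch_annotate(g$corpus, flaky)
  expect_equal(sum(res2$parsed), nrow(g$corpus) - 1L)
  expect_false(res2$parsed[3])
})
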