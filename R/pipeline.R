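#' Configure an end-to-end annotation experiment
#'
#' Bundles the synthetic-corpus generator, named annotation-noise
#' profiles standing in for annotators of different quality, the
#' learning-curve ladder of training-set sizes, the history:procedure
#' batch ratio, and the held-out evaluation corpus. Defaults mirror the
#' reference experiment shapes: a 2:1 history:procedure batch mix, a
#' 15% validation split, an evaluation set of 300 documents split evenly
#' between the two document types, and a 250-4000 size ladder.
#'
#' @param generator A [generator_config()] for the training corpus; its
#'   `n` must be able to cover the largest ladder size at the batch
#'   ratio.
#' @param noise Named list of [noise_config()] profiles.
#' @param sizes Strictly increasing training-set sizes (documents).
#' @param batch_ratio Two positive numbers, history and procedure parts.
#' @param eval_n Evaluation corpus size (half per document type).
#' @param prop_validation Validation fraction of each training batch.
#' @param min_count Lexicon frequency floor for the downstream dictionary
#'   tagger (default 2): a (surface, class) chunk must recur in the weak
#'   labels before it is trusted, which suppresses one-off spurious
#'   annotations.
#' @param min_confidence Occurrence-confidence floor for the tagger
#'   lexicon (see [train_surface_tagger()]); default 0.25.
#' @param seed Global experiment seed.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(generator = generator_config(n = 4200, seed = 101L),
                              noise = list(
                                perfect = noise_config(seed = 11L),
                                gpt4_like = noise_config(drop_prob = 0.35,
                                                         spurious_prob = 0.8,
                                                         boundary_shift_prob = 0.05,
                                                         garble_prob = 0.01,
                                                         seed = 11L),
                                weak_local = noise_config(drop_prob = 0.6,
                                                          spurious_prob = 1.5,
                                                          boundary_shift_prob = 0.1,
                                                          garble_prob = 0.09,
                                                          seed = 11L)),
                              sizes = c(250, 500, 750, 1000, 2000, 4000),
                              batch_ratio = c(history = 2, procedure = 1),
                              eval_n = 300, prop_validation = 0.15,
                              min_count = 2, min_confidence = 0.25, seed = 1L) {
  if (any(diff(sizes) <= 0)) abort("`sizes` must be strictly increasing")
  if (length(batch_ratio) != 2 || any(batch_ratio <= 0)) {
    abort("`batch_ratio` must be two positive numbers")
  }
  structure(list(generator = generator, noise = noise, sizes = as.integer(sizes),
                 batch_ratio = batch_ratio, eval_n = as.integer(eval_n),
                 prop_validation = prop_validation, min_count = min_count,
                 min_confidence = min_confidence, seed = as.integer(seed)),
            class = "experiment_config")
}

# Generate the training corpus+gold and the disjoint gold evaluation set.
experiment_data <- function(cfg) {
  train <- generate_gold_corpus(cfg$generator, id_prefix = "train")
  eval_cfg <- cfg$generator
  eval_cfg$n <- cfg$eval_n
  eval_cfg$frac_history <- 0.5
  eval_cfg$seed <- derive_seed(cfg$seed, "evaluation-corpus")
  eval <- generate_gold_corpus(eval_cfg, id_prefix = "eval")
  eval_tokens <- tokenize_corpus(eval$corpus)
  gold_by_doc <- split(eval$gold, factor(eval$gold$doc_id, levels = eval$corpus$doc_id))
  eval_gold_tags <- dplyr::bind_rows(lapply(eval$corpus$doc_id, function(id) {
    toks <- eval_tokens[eval_tokens$doc_id == id, c("token", "start", "end")]
    spans_to_tags(toks, gold_by_doc[[id]] %||% eval$gold[0, ], doc_id = id)
  }))
  list(train = train, eval_corpus = eval$corpus, eval_tokens = eval_tokens,
       eval_gold_tags = eval_gold_tags)
}

#' Run a learning-curve experiment
#'
#' For each training-set size: draw a seeded batch of synthetic documents
#' at the configured history:procedure ratio, annotate it with the chosen
#' noise profile, align the responses into IOB2 training data, hold out
#' the validation fraction, train the dictionary tagger on the remainder,
#' and evaluate entity-level metrics on the held-out gold evaluation
#' corpus (disjoint from every training batch by construction; asserted
#' by id). Fully reproducible from the config seed.
#'
#' @param cfg An [experiment_config()].
#' @param profile Name of the noise profile in `cfg$noise` to use.
#' @return A `learning_curve` tibble: one row per (size, class) plus a
#'   micro row per size, with tp/fp/fn, precision and recall with Wilson
#'   CI bounds, F1, support, and the parsed-response count of the batch.
#' @export
run_learning_curve <- function(cfg, profile = "gpt4_like") {
  stopifnot(inherits(cfg, "experiment_config"))
  if (!profile %in% names(cfg$noise)) {
    abort(sprintf("unknown noise profile \"%s\"", profile))
  }
  dat <- experiment_data(cfg)
  corpus <- dat$train$corpus
  ratio <- cfg$batch_ratio / sum(cfg$batch_ratio)
  n_by_type <- table(corpus$doc_type)
  need_hist <- round(max(cfg$sizes) * ratio[1])
  if (need_hist > n_by_type[["medical_history"]] ||
      max(cfg$sizes) - need_hist > n_by_type[["procedure"]]) {
    abort("largest requested size exceeds the available corpus at the batch ratio")
  }
  stopifnot(length(intersect(corpus$doc_id, dat$eval_corpus$doc_id)) == 0)

  annotator <- noisy_annotator(dat$train$gold, cfg$noise[[profile]])
  responses <- batch_annotate(corpus, annotator)
  built <- build_training_set(corpus, responses)
  tags_by_doc <- split(built$tags, factor(built$tags$doc_id, levels = corpus$doc_id))
  hist_ids <- corpus$doc_id[corpus$doc_type == "medical_history"]
  proc_ids <- corpus$doc_id[corpus$doc_type == "procedure"]

  rows <- lapply(cfg$sizes, function(size) {
    n_hist <- round(size * ratio[1])
    batch_ids <- with_seed(derive_seed(cfg$seed, paste0("batch-", size)), {
      c(sample(hist_ids, n_hist), sample(proc_ids, size - n_hist))
    })
    batch_tags <- dplyr::bind_rows(tags_by_doc[batch_ids[batch_ids %in% names(tags_by_doc)]])
    parts <- split_train_validation(batch_tags, cfg$prop_validation,
                                    seed = derive_seed(cfg$seed, paste0("split-", size)))
    model <- train_surface_tagger(parts$train, min_count = cfg$min_count,
                                  min_confidence = cfg$min_confidence)
    pred <- predict(model, dat$eval_tokens)
    ev <- evaluate_ner(pred, dat$eval_gold_tags,
                       parsed_responses = sum(responses$parsed[responses$doc_id %in% batch_ids]))
    dplyr::mutate(dplyr::bind_rows(tidy(ev), ev$micro), size = size,
                  parsed_responses = ev$parsed_responses, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("learning_curve", class(out))
  out
}

#' @rdname run_learning_curve
#' @param object A `learning_curve` tibble.
#' @param ... Unused.
#' @export
autoplot.learning_curve <- function(object, ...) {
  df <- dplyr::filter(object, .data$class != "micro")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$f1,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "annotated synthetic training documents", y = "F1",
                  title = "Learning curve on the held-out evaluation corpus") +
    ggplot2::theme_minimal()
}

#' Compare prompt styles on an annotated reference corpus
#'
#' Annotates the corpus once per prompt style, aligns each response set
#' into tags, and evaluates against the gold tagging, reporting per-class
#' precision (with Wilson CI), recall (with CI), F1 and the
#' parsed-response count per style — the layout used to select the best
#' prompt before committing to large-scale annotation.
#'
#' @param corpus Corpus tibble.
#' @param gold_tags Gold tagged tibble for the corpus.
#' @param annotator Annotator function `(text, doc_id, prompt) -> raw`.
#' @param styles Prompt styles to compare.
#' @param classes Entity class labels.
#' @return A tibble with one row per (style, class) plus micro rows.
#' @export
run_prompt_comparison <- function(corpus, gold_tags, annotator,
                                  styles = prompt_styles, classes = ner_classes) {
  rows <- lapply(styles, function(style) {
    spec <- prompt_spec(style, classes = classes)
    responses <- batch_annotate(corpus, annotator, spec = spec, classes = classes)
    built <- build_training_set(corpus, responses, classes = classes)
    covered <- unique(built$tags$doc_id)
    ev <- evaluate_ner(built$tags,
                       gold_tags[gold_tags$doc_id %in% covered, , drop = FALSE],
                       classes = classes, parsed_responses = sum(responses$parsed))
    dplyr::mutate(dplyr::bind_rows(tidy(ev), ev$micro), style = style,
                  parsed_responses = ev$parsed_responses, .before = 1)
  })
  dplyr::bind_rows(rows)
}
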