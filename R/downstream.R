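#' Split a tagged corpus into training and validation parts
#'
#' Document-level seeded shuffle-then-split; by default 15% of documents
#' form the validation set. The parts are disjoint and their union is the
#' input.
#'
#' @param tagged A tibble with a `doc_id` column (tagged tokens or a
#'   corpus).
#' @param prop_validation Fraction of documents held out, in `(0, 1)`.
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `validation`.
#' @export
split_train_validation <- function(tagged, prop_validation = 0.15, seed = 1L) {
  if (prop_validation <= 0 || prop_validation >= 1) {
    abort("`prop_validation` must be in (0, 1)")
  }
  ids <- unique(tagged$doc_id)
  if (length(ids) < 2) abort("need at least 2 documents to split")
  n_val <- min(max(round(prop_validation * length(ids)), 1L), length(ids) - 1L)
  val_ids <- with_seed(seed, sample(ids, n_val))
  list(train = tagged[!tagged$doc_id %in% val_ids, , drop = FALSE],
       validation = tagged[tagged$doc_id %in% val_ids, , drop = FALSE])
}

#' Train a dictionary (gazetteer) tagger from weakly labeled data
#'
#' A desk-scale downstream model: chunks are extracted from the training
#' tags, each distinct surface token sequence is counted per class, and
#' every surface observed at least `min_count` times is stored with its
#' majority class (ties broken by class priority order). Lookup-based
#' tagging cannot use context, so it measures how much of the task the
#' weak labels' surface vocabulary alone solves — a transparent,
#' CPU-only stand-in for a fine-tuned transformer (the exported CoNLL
#' files keep that route open externally).
#'
#' @param train Tagged tibble (`doc_id`, `token`, `tag`).
#' @param min_count Minimum times a (surface, majority class) pair must
#'   be observed (default 1).
#' @param min_confidence Optional occurrence-confidence floor in `[0, 1)`
#'   (default 0, off): a surface is kept only if it was annotated in at
#'   least this fraction of its occurrences in the training text. Noisy
#'   weak labels occasionally tag common words; such surfaces occur far
#'   more often than they are tagged and are filtered out, while genuine
#'   entity surfaces are tagged at most of their occurrences.
#' @param classes Class priority order.
#' @return A `surface_tagger` model; see [predict.surface_tagger()].
#' @export
train_surface_tagger <- function(train, min_count = 1, min_confidence = 0,
                                 classes = ner_classes) {
  if (nrow(train) == 0) {
    lex <- tibble::tibble(surface = character(), class = character(), n = integer())
    return(structure(list(lexicon = lex, classes = classes, min_count = min_count),
                     class = "surface_tagger"))
  }
  chunks <- chunks_by_doc(train, classes)
  toks_by_doc <- split(train$token, factor(train$doc_id, levels = unique(train$doc_id)))
  lex <- tibble::tibble(surface = character(), class = character(), n = integer())
  if (nrow(chunks)) {
    chunks$surface <- vapply(seq_len(nrow(chunks)), function(i) {
      toks <- toks_by_doc[[chunks$doc_id[i]]]
      paste(toks[(chunks$start[i] + 1):chunks$end[i]], collapse = " ")
    }, "")
    lex <- chunks |>
      dplyr::count(.data$surface, .data$class, name = "n") |>
      dplyr::mutate(prio = match(.data$class, classes)) |>
      dplyr::arrange(.data$surface, dplyr::desc(.data$n), .data$prio) |>
      dplyr::distinct(.data$surface, .keep_all = TRUE) |>
      dplyr::filter(.data$n >= min_count) |>
      dplyr::select("surface", "class", "n")
    if (min_confidence > 0 && nrow(lex)) {
      occ <- count_ngram_occurrences(lex$surface, toks_by_doc)
      lex <- lex[lex$n / pmax(occ, lex$n) >= min_confidence, , drop = FALSE]
    }
  }
  structure(list(lexicon = lex, classes = classes, min_count = min_count),
            class = "surface_tagger")
}

# Count (overlapping) occurrences of each surface token sequence across
# the training documents' token streams.
count_ngram_occurrences <- function(surfaces, toks_by_doc) {
  surf_toks <- strsplit(surfaces, " ", fixed = TRUE)
  occ <- stats::setNames(integer(length(surfaces)), surfaces)
  for (len in sort(unique(lengths(surf_toks)))) {
    want <- surfaces[lengths(surf_toks) == len]
    counts <- table(unlist(lapply(toks_by_doc, function(toks) {
      n <- length(toks)
      if (n < len) return(character())
      if (len == 1) return(toks)
      grams <- toks[seq_len(n - len + 1)]
      for (j in seq_len(len - 1)) {
        grams <- paste(grams, toks[(1 + j):(n - len + 1 + j)])
      }
      grams
    }), use.names = FALSE))
    hit <- want %in% names(counts)
    occ[want[hit]] <- as.integer(counts[want[hit]])
  }
  occ
}

#' @export
print.surface_tagger <- function(x, ...) {
  cat(sprintf("<surface_tagger: %d surfaces over %d classes, min_count=%d>\n",
              nrow(x$lexicon), length(unique(x$lexicon$class)), x$min_count))
  invisible(x)
}

#' @rdname train_surface_tagger
#' @param x A `surface_tagger`.
#' @param ... Unused.
#' @export
tidy.surface_tagger <- function(x, ...) x$lexicon

#' Tag tokenized documents with a dictionary tagger
#'
#' Deterministic leftmost-longest scan: at each position the longest
#' stored surface starting there is matched and tagged IOB2, and the scan
#' resumes after it; unmatched tokens get `O`.
#'
#' @param object A `surface_tagger`.
#' @param tokens Token tibble (`doc_id`, `token`, `start`, `end`) from
#'   [tokenize_corpus()].
#' @param ... Unused.
#' @return A tagged tibble (`doc_id`, `token`, `start`, `end`, `tag`).
#' @export
predict.surface_tagger <- function(object, tokens, ...) {
  lex <- object$lexicon
  keys <- new.env(parent = emptyenv())
  key_toks <- strsplit(lex$surface, " ", fixed = TRUE)
  for (i in seq_along(key_toks)) assign(lex$surface[i], lex$class[i], envir = keys)
  max_len <- if (nrow(lex)) max(lengths(key_toks)) else 0L

  parts <- split(seq_len(nrow(tokens)),
                 factor(tokens$doc_id, levels = unique(tokens$doc_id)))
  tag <- rep("O", nrow(tokens))
  for (rows in parts) {
    toks <- tokens$token[rows]
    n <- length(toks)
    i <- 1L
    while (i <= n && max_len > 0) {
      matched <- 0L
      for (len in seq(min(max_len, n - i + 1L), 1L)) {
        key <- paste(toks[i:(i + len - 1L)], collapse = " ")
        cls <- get0(key, envir = keys)
        if (!is.null(cls)) {
          tag[rows[i]] <- paste0("B-", cls)
          if (len > 1) tag[rows[(i + 1L):(i + len - 1L)]] <- paste0("I-", cls)
          matched <- len
          break
        }
      }
      i <- i + max(matched, 1L)
    }
  }
  tibble::tibble(doc_id = tokens$doc_id, token = tokens$token,
                 start = tokens$start, end = tokens$end, tag = tag)
}

#' Serialize / restore a dictionary tagger as TSV
#'
#' Three tab-separated columns: class, surface, count.
#'
#' @param model A `surface_tagger`.
#' @param path File path.
#' @param classes Class priority order for the restored model.
#' @export
write_surface_tagger <- function(model, path) {
  lines <- sprintf("%s\t%s\t%d", model$lexicon$class, model$lexicon$surface,
                   model$lexicon$n)
  writeLines(enc2utf8(c("class\tsurface\tn", lines)), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_surface_tagger
#' @export
read_surface_tagger <- function(path, classes = ner_classes) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          encoding = "UTF-8", stringsAsFactors = FALSE)
  lex <- tibble::tibble(surface = as.character(df$surface),
                        class = as.character(df$class), n = as.integer(df$n))
  structure(list(lexicon = lex, classes = classes, min_count = 1L),
            class = "surface_tagger")
}
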