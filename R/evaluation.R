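#' Extract entity chunks from an IOB2 label sequence
#'
#' Chunking follows the lenient default of the standard sequence-labeling
#' evaluation convention: a chunk starts at `B-X`, or at `I-X` when the
#' previous token was `O` or belonged to a different class (so sequences
#' that violate strict IOB2 chaining are still read as entities); it ends
#' before `O`, any `B-`, or a class change.
#'
#' @param labels Character vector of IOB2 labels for one document.
#' @param classes Entity class labels (unknown labels are an error).
#' @return A tibble with columns `class`, `start`, `end` (token indices,
#'   0-based half-open), in order of occurrence.
#' @export
extract_chunks <- function(labels, classes = ner_classes) {
  check_labels(labels, classes)
  n <- length(labels)
  out0 <- tibble::tibble(class = character(), start = integer(), end = integer())
  if (n == 0) return(out0)
  pre <- substr(labels, 1, 1)
  typ <- ifelse(labels == "O", "", substring(labels, 3))
  is_ent <- pre != "O"
  prev_pre <- c("O", pre[-n])
  prev_typ <- c("", typ[-n])
  starts <- is_ent & (pre == "B" | prev_pre == "O" | prev_typ != typ)
  if (!any(is_ent)) return(out0)
  chunk_id <- cumsum(starts)
  chunk_id[!is_ent] <- NA
  idx <- which(is_ent)
  first <- tapply(idx, chunk_id[idx], min)
  last <- tapply(idx, chunk_id[idx], max)
  ord <- order(as.integer(names(first)))
  tibble::tibble(class = typ[first[ord]],
                 start = as.integer(first[ord] - 1L),
                 end = as.integer(last[ord]))
}

chunks_by_doc <- function(tags, classes) {
  parts <- split(tags$tag, factor(tags$doc_id, levels = unique(tags$doc_id)))
  out <- dplyr::bind_rows(lapply(names(parts), function(id) {
    ch <- extract_chunks(parts[[id]], classes)
    if (nrow(ch)) dplyr::mutate(ch, doc_id = id, .before = 1) else NULL
  }))
  if (nrow(out) == 0) {
    out <- tibble::tibble(doc_id = character(), class = character(),
                          start = integer(), end = integer())
  }
  out
}

#' Harmonic mean of precision and recall
#'
#' `2PR / (P + R)`, with 0 when both are 0 (the zero-division convention
#' used throughout the evaluation module). Vectorized.
#'
#' @param precision,recall Fractions in `[0, 1]`.
#' @return F1 score(s).
#' @export
f1_harmonic <- function(precision, recall) {
  s <- precision + recall
  ifelse(s == 0, 0, 2 * precision * recall / s)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' The Wilson interval has good coverage near 0 and 1, which matters for
#' entity classes with few mentions (e.g. smoking status). Vectorized;
#' bounds are clipped to `[0, 1]` and always contain the point estimate.
#'
#' @param successes,trials Nonnegative counts, `successes <= trials`,
#'   `trials >= 1`.
#' @param z Normal quantile; 1.96 gives a 95% interval.
#' @return A tibble with columns `low`, `high`.
#' @export
wilson_interval <- function(successes, trials, z = 1.96) {
  if (any(trials < 1)) abort("`trials` must be >= 1")
  if (any(successes < 0) || any(successes > trials)) {
    abort("`successes` must lie in [0, trials]")
  }
  p <- successes / trials
  z2 <- z^2
  denom <- 1 + z2 / trials
  center <- (p + z2 / (2 * trials)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / trials + z2 / (4 * trials^2))
  tibble::tibble(low = pmin(pmax(center - half, 0), 1),
                 high = pmin(pmax(center + half, 0), 1))
}

wilson_or_trivial <- function(successes, trials, z) {
  # trials == 0 (no predictions / no gold) carries no information
  low <- numeric(length(trials)); high <- numeric(length(trials))
  pos <- trials > 0
  if (any(pos)) {
    wi <- wilson_interval(successes[pos], trials[pos], z)
    low[pos] <- wi$low; high[pos] <- wi$high
  }
  high[!pos] <- 1
  tibble::tibble(low = low, high = high)
}

#' Entity-level evaluation of predicted against gold tags
#'
#' Chunks are extracted from both taggings ([extract_chunks()]) and a
#' true positive is an exact match of class and token span within the
#' same document. Per class and micro-averaged: precision `TP/(TP+FP)`,
#' recall `TP/(TP+FN)`, F1 (all 0 on 0/0), and Wilson confidence
#' intervals on precision and recall computed from chunk counts. Support
#' is the gold chunk count.
#'
#' @param pred,gold Tagged tibbles (`doc_id`, `token`, `tag`) over the
#'   same documents with identical token counts.
#' @param classes Entity class labels to report.
#' @param z Normal quantile for the confidence intervals (default 1.96,
#'   i.e. 95%).
#' @param parsed_responses Optional count of parsed annotator responses
#'   to carry in the report.
#' @return An object of class `ner_eval`; see [tidy.ner_eval()] and
#'   [glance.ner_eval()].
#' @export
evaluate_ner <- function(pred, gold, classes = ner_classes, z = 1.96,
                         parsed_responses = NA_integer_) {
  pn <- table(pred$doc_id); gn <- table(gold$doc_id)
  if (!setequal(names(pn), names(gn))) {
    abort("`pred` and `gold` must cover the same document ids")
  }
  bad <- names(gn)[pn[names(gn)] != gn]
  if (length(bad)) {
    abort(sprintf("token count mismatch for document %s", bad[1]))
  }
  pc <- chunks_by_doc(pred, classes)
  gc <- chunks_by_doc(gold, classes)
  tp_tbl <- if (nrow(pc) && nrow(gc)) {
    dplyr::count(dplyr::semi_join(pc, gc, by = c("doc_id", "class", "start", "end")),
                 .data$class, name = "tp")
  } else tibble::tibble(class = character(), tp = integer())
  per <- tibble::tibble(class = classes) |>
    dplyr::left_join(dplyr::count(pc, .data$class, name = "n_pred"), by = "class") |>
    dplyr::left_join(dplyr::count(gc, .data$class, name = "n_gold"), by = "class") |>
    dplyr::left_join(tp_tbl, by = "class") |>
    dplyr::mutate(dplyr::across(c("n_pred", "n_gold", "tp"),
                                ~ tidyr::replace_na(.x, 0L)))
  micro <- tibble::tibble(class = "micro", n_pred = sum(per$n_pred),
                          n_gold = sum(per$n_gold), tp = sum(per$tp))
  res <- dplyr::bind_rows(per, micro) |>
    dplyr::mutate(
      fp = .data$n_pred - .data$tp,
      fn = .data$n_gold - .data$tp,
      precision = ifelse(.data$n_pred == 0, 0, .data$tp / .data$n_pred),
      recall = ifelse(.data$n_gold == 0, 0, .data$tp / .data$n_gold),
      f1 = f1_harmonic(.data$precision, .data$recall),
      support = .data$n_gold)
  pci <- wilson_or_trivial(res$tp, res$n_pred, z)
  rci <- wilson_or_trivial(res$tp, res$n_gold, z)
  res$precision_low <- pci$low; res$precision_high <- pci$high
  res$recall_low <- rci$low; res$recall_high <- rci$high
  res <- res[c("class", "tp", "fp", "fn", "precision", "precision_low",
               "precision_high", "recall", "recall_low", "recall_high",
               "f1", "support")]
  structure(list(metrics = res[res$class != "micro", ],
                 micro = res[res$class == "micro", ],
                 parsed_responses = parsed_responses, z = z),
            class = "ner_eval")
}

#' @export
print.ner_eval <- function(x, ...) {
  cat("Entity-level NER evaluation (exact span + class match)\n")
  print(dplyr::bind_rows(x$metrics, x$micro))
  if (!is.na(x$parsed_responses)) {
    cat("Parsed responses:", x$parsed_responses, "\n")
  }
  invisible(x)
}

#' Tidiers for NER evaluation reports
#'
#' `tidy()` returns the per-class metric table (one row per class);
#' `glance()` returns the micro-averaged one-row summary with the
#' parsed-response count.
#'
#' @param x A `ner_eval` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ner_eval <- function(x, ...) x$metrics

#' @rdname tidy.ner_eval
#' @export
glance.ner_eval <- function(x, ...) {
  dplyr::mutate(x$micro, parsed_responses = x$parsed_responses)
}

#' @rdname tidy.ner_eval
#' @param object A `ner_eval` object.
#' @export
autoplot.ner_eval <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::transmute(object$metrics, class = .data$class, metric = "precision",
                     value = .data$precision, low = .data$precision_low,
                     high = .data$precision_high),
    dplyr::transmute(object$metrics, class = .data$class, metric = "recall",
                     value = .data$recall, low = .data$recall_low,
                     high = .data$recall_high),
    dplyr::transmute(object$metrics, class = .data$class, metric = "F1",
                     value = .data$f1, low = NA_real_, high = NA_real_))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$low, ymax = .data$high),
                             position = ggplot2::position_dodge(width = 0.5),
                             na.rm = TRUE) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "score",
                  title = "Entity-level precision / recall / F1",
                  subtitle = "bars: Wilson 95% CI on precision and recall") +
    ggplot2::theme_minimal()
}

#' Pairwise interannotator agreement as per-class F1
#'
#' Treats one annotator's tagging as reference and evaluates the other
#' against it; entity-level F1 is symmetric under exchanging the two (a
#' swap exchanges FP and FN, leaving F1 unchanged).
#'
#' @param a,b Tagged tibbles over the same documents and tokenization.
#' @param classes Entity class labels.
#' @return A tibble with columns `class`, `f1` (micro row included).
#' @export
interannotator_agreement <- function(a, b, classes = ner_classes) {
  ev <- evaluate_ner(a, b, classes = classes)
  dplyr::bind_rows(ev$metrics, ev$micro)[c("class", "f1")]
}
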