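#' Map reported entity surfaces to character spans in the source text
#'
#' Annotators return surface strings only, so spans must be recovered by
#' searching the original text. Each reported surface is
#' whitespace-normalized, tokenized, and matched as a contiguous
#' whole-token sequence (case-insensitively by default). Every occurrence
#' is annotated by default — a class-to-strings response carries no
#' per-occurrence information, so distant-supervision-style full
#' annotation is the only consistent reading. Surfaces with no occurrence
#' are dropped with reason `"not_found"` (the alignment never invents
#' text); empty surfaces with reason `"empty"`.
#'
#' @param doc A one-row corpus tibble (or list) with `doc_id`, `text`.
#' @param entities Entity tibble (`class`, `surface`), e.g. from a parsed
#'   response.
#' @param tokens Optional pre-computed token table for the document (as
#'   returned by [tokenize()]); computed when `NULL`.
#' @param case_insensitive Match surfaces ignoring case (default `TRUE`).
#' @param all_occurrences Annotate every occurrence (default) or only the
#'   first.
#' @param surface_tokens Optional named list caching tokenized
#'   (whitespace-normalized) surfaces; used by [build_training_set()].
#' @return A list with `mentions` (tibble `doc_id`, `class`, `surface`,
#'   `start`, `end`, `token_start`, `token_end`; char and token spans both
#'   0-based half-open; `surface` is the document-side text of the span)
#'   sorted by `(start, end)`, and `dropped` (tibble `class`, `surface`,
#'   `reason`).
#' @export
map_entities_to_spans <- function(doc, entities, tokens = NULL,
                                  case_insensitive = TRUE, all_occurrences = TRUE,
                                  surface_tokens = NULL) {
  doc_id <- doc$doc_id[[1]]
  text <- doc$text[[1]]
  if (is.null(tokens)) tokens <- .tokenize_one(text)
  fold <- if (case_insensitive) tolower else identity
  doc_toks <- fold(tokens$token)
  n_tok <- length(doc_toks)

  no_mentions <- tibble::tibble(doc_id = character(), class = character(),
                                surface = character(), start = integer(),
                                end = integer(), token_start = integer(),
                                token_end = integer())
  no_dropped <- tibble::tibble(class = character(), surface = character(),
                               reason = character())
  if (is.null(entities) || nrow(entities) == 0) {
    return(list(mentions = no_mentions, dropped = no_dropped))
  }

  m_cls <- character(); m_st <- integer(); m_len <- integer()
  d_cls <- character(); d_surf <- character(); d_reason <- character()
  for (i in seq_len(nrow(entities))) {
    cls <- entities$class[i]
    surf <- stringr::str_squish(entities$surface[i])
    stoks <- fold(surface_tokens[[surf]] %||% .tokenize_one(surf)$token)
    ls <- length(stoks)
    if (ls == 0) {
      d_cls <- c(d_cls, cls); d_surf <- c(d_surf, entities$surface[i])
      d_reason <- c(d_reason, "empty")
      next
    }
    hits <- integer()
    if (ls <= n_tok) {
      cand <- which(doc_toks == stoks[1])
      cand <- cand[cand + ls - 1 <= n_tok]
      for (st in cand) {
        if (ls == 1 || all(doc_toks[st:(st + ls - 1)] == stoks)) {
          hits <- c(hits, st)
          if (!all_occurrences) break
        }
      }
    }
    if (length(hits) == 0) {
      d_cls <- c(d_cls, cls); d_surf <- c(d_surf, entities$surface[i])
      d_reason <- c(d_reason, "not_found")
      next
    }
    m_cls <- c(m_cls, rep(cls, length(hits)))
    m_st <- c(m_st, hits)
    m_len <- c(m_len, rep(ls, length(hits)))
  }
  mentions <- no_mentions
  if (length(m_cls)) {
    cs <- tokens$start[m_st]; ce <- tokens$end[m_st + m_len - 1L]
    keep <- !duplicated(paste(m_cls, cs, ce))
    ord <- order(cs[keep], ce[keep])
    mentions <- tibble::tibble(
      doc_id = doc_id, class = m_cls[keep][ord],
      surface = substr(rep(text, sum(keep)), cs[keep] + 1L, ce[keep])[ord],
      start = cs[keep][ord], end = ce[keep][ord],
      token_start = (m_st - 1L)[keep][ord],
      token_end = (m_st + m_len - 1L)[keep][ord])
  }
  dropped <- if (length(d_cls)) {
    tibble::tibble(class = d_cls, surface = d_surf, reason = d_reason)
  } else no_dropped
  list(mentions = mentions, dropped = dropped)
}

#' Resolve overlapping mentions deterministically
#'
#' Token tags cannot represent overlapping entities, so conflicts are
#' resolved greedily: the longer character span wins; ties break toward
#' the earlier start, then by class priority order (DRUG, PROCEDURE,
#' DISEASE, SMOKING). The result is pairwise non-overlapping within each
#' document.
#'
#' @param mentions A mention tibble (per [map_entities_to_spans()]).
#' @param classes Class priority order.
#' @return The surviving mentions, sorted by `(doc_id, start, end)`.
#' @export
resolve_overlaps <- function(mentions, classes = ner_classes) {
  if (nrow(mentions) == 0) return(mentions)
  # fast path: already sorted by doc and start with no adjacent overlap
  n <- nrow(mentions)
  if (n == 1) return(mentions)
  same_doc <- mentions$doc_id[-1] == mentions$doc_id[-n]
  sorted <- all(!same_doc | mentions$start[-1] >= mentions$start[-n])
  if (sorted && all(!same_doc | mentions$start[-1] >= mentions$end[-n])) {
    return(mentions)
  }
  prio <- match(mentions$class, classes)
  prio[is.na(prio)] <- length(classes) + 1L
  keep_rows <- unlist(lapply(split(seq_len(nrow(mentions)), mentions$doc_id), function(idx) {
    m <- mentions[idx, ]
    ord <- order(-(m$end - m$start), m$start, prio[idx])
    kept <- integer()
    for (r in ord) {
      if (!any(m$start[r] < m$end[kept] & m$end[r] > m$start[kept])) {
        kept <- c(kept, r)
      }
    }
    idx[kept]
  }), use.names = FALSE)
  dplyr::arrange(mentions[sort(keep_rows), ], .data$doc_id, .data$start, .data$end)
}

#' Convert non-overlapping mentions to IOB2 token tags
#'
#' Every token whose character span overlaps a mention's span is covered:
#' the first such token gets `B-<class>`, the rest `I-<class>`, all other
#' tokens `O`. A mention ending mid-token covers that whole token.
#'
#' @param tokens Token table for one document ([tokenize()]).
#' @param mentions Non-overlapping mention tibble for the same document
#'   (overlaps are an error; resolve first).
#' @param doc_id Document id stamped on the output.
#' @return A tagged tibble (`doc_id`, `token`, `start`, `end`, `tag`)
#'   satisfying the IOB2 chaining invariant.
#' @export
spans_to_tags <- function(tokens, mentions, doc_id = NA_character_) {
  n <- nrow(tokens)
  tag <- rep("O", n)
  if (nrow(mentions)) {
    m <- dplyr::arrange(mentions, .data$start, .data$end)
    if (any(m$start[-1] < m$end[-nrow(m)])) {
      abort("mentions overlap; run resolve_overlaps() first")
    }
    for (i in seq_len(nrow(m))) {
      cov <- which(tokens$start < m$end[i] & tokens$end > m$start[i])
      if (length(cov) == 0) next
      tag[cov[1]] <- paste0("B-", m$class[i])
      if (length(cov) > 1) tag[cov[-1]] <- paste0("I-", m$class[i])
    }
  }
  tibble::tibble(doc_id = doc_id, token = tokens$token,
                 start = tokens$start, end = tokens$end, tag = tag)
}

#' Build an IOB2 training set from annotation responses
#'
#' Composes span mapping, overlap resolution, and tagging for every
#' parsed response: the pipeline step that turns class-to-strings weak
#' annotations into token-classification training data. Unparsed
#' responses are skipped and logged; dropped surfaces are logged with
#' their reason.
#'
#' @param corpus Corpus tibble.
#' @param responses Response tibble from [batch_annotate()]; its
#'   `doc_id`s must all occur in the corpus.
#' @param case_insensitive,all_occurrences Matching policy, see
#'   [map_entities_to_spans()].
#' @param classes Class priority order for overlap resolution.
#' @return A list: `tags` (tagged tibble over all parsed documents, every
#'   token of each document present), `dropped` (tibble `doc_id`,
#'   `class`, `surface`, `reason`), `skipped` (ids of unparsed
#'   documents).
#' @export
build_training_set <- function(corpus, responses, case_insensitive = TRUE,
                               all_occurrences = TRUE, classes = ner_classes) {
  assert_corpus(corpus)
  missing <- setdiff(responses$doc_id, corpus$doc_id)
  if (length(missing)) {
    abort(sprintf("responses reference unknown document(s): %s",
                  paste(head(missing, 3), collapse = ", ")))
  }
  toks_all <- tokenize_corpus(corpus)
  toks_by_doc <- split(toks_all[c("token", "start", "end")], toks_all$doc_id)
  text_by_doc <- stats::setNames(corpus$text, corpus$doc_id)
  # tokenize each distinct reported surface once across the whole corpus
  all_surf <- unique(stringr::str_squish(
    unlist(lapply(responses$entities[responses$parsed], `[[`, "surface"),
           use.names = FALSE) %||% character()))
  surf_cache <- stats::setNames(lapply(all_surf, function(s) .tokenize_one(s)$token),
                                all_surf)

  skipped <- responses$doc_id[!responses$parsed]
  parsed <- responses[responses$parsed, , drop = FALSE]
  tag_rows <- list(); drop_rows <- list()
  for (i in seq_len(nrow(parsed))) {
    id <- parsed$doc_id[i]
    toks <- toks_by_doc[[id]] %||% tokenize(text_by_doc[[id]])
    al <- map_entities_to_spans(list(doc_id = id, text = text_by_doc[[id]]),
                                parsed$entities[[i]], tokens = toks,
                                case_insensitive = case_insensitive,
                                all_occurrences = all_occurrences,
                                surface_tokens = surf_cache)
    if (nrow(al$dropped)) {
      drop_rows[[length(drop_rows) + 1]] <- dplyr::mutate(al$dropped, doc_id = id,
                                                          .before = 1)
    }
    resolved <- resolve_overlaps(al$mentions, classes = classes)
    tag_rows[[length(tag_rows) + 1]] <- spans_to_tags(toks, resolved, doc_id = id)
  }
  tags <- if (length(tag_rows)) dplyr::bind_rows(tag_rows) else
    tibble::tibble(doc_id = character(), token = character(),
                   start = integer(), end = integer(), tag = character())
  dropped <- if (length(drop_rows)) dplyr::bind_rows(drop_rows) else
    tibble::tibble(doc_id = character(), class = character(),
                   surface = character(), reason = character())
  list(tags = tags, dropped = dropped, skipped = skipped)
}
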