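#' Tokenize text into words and punctuation with character offsets
#'
#' Splits on whitespace, then peels leading and trailing punctuation
#' characters off each whitespace-delimited chunk into tokens of their own
#' (interior punctuation, as in `"e.g"` or `"C50.9"`, is kept inside the
#' token). Character offsets are 0-based half-open, so
#' `substr(text, start + 1, end)` reproduces each token surface exactly.
#'
#' The rule is deliberately simple and fully deterministic: it defines the
#' word level at which originality scores are computed, annotation surfaces
#' are aligned, and tags are assigned, and it is idempotent on token
#' surfaces (re-tokenizing the tokens joined by single spaces yields the
#' same surfaces).
#'
#' @param text A single character string (may be empty).
#' @return A tibble with columns `token`, `start`, `end`.
#' @examples
#' tokenize("Metforal 500mg.")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  tibble::as_tibble(.tokenize_one(text))
}

# Lean single-text tokenizer (plain list, no tibble overhead) for hot
# paths; same rule as tokenize_corpus(), asserted equivalent in tests.
.tokenize_one <- function(text) {
  none <- list(token = character(), start = integer(), end = integer())
  if (is.na(text) || !nzchar(text)) return(none)
  m <- gregexpr("\\S+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(none)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  chunks <- substring(text, starts, starts + lens - 1L)
  punct <- grepl("^\\p{P}|\\p{P}$", chunks, perl = TRUE)
  if (!any(punct)) {
    return(list(token = chunks, start = starts - 1L, end = starts - 1L + lens))
  }
  token <- vector("list", length(chunks))
  tstart <- vector("list", length(chunks))
  for (i in seq_along(chunks)) {
    if (!punct[i]) {
      token[[i]] <- chunks[i]
      tstart[[i]] <- starts[i] - 1L
      next
    }
    p <- regmatches(chunks[i], regexec("^(\\p{P}*)(.*?)(\\p{P}*)$", chunks[i],
                                       perl = TRUE))[[1]]
    toks <- c(if (nzchar(p[2])) strsplit(p[2], "", fixed = TRUE)[[1]],
              if (nzchar(p[3])) p[3],
              if (nzchar(p[4])) strsplit(p[4], "", fixed = TRUE)[[1]])
    token[[i]] <- toks
    tstart[[i]] <- starts[i] - 1L + cumsum(c(0L, nchar(toks)[-length(toks)]))
  }
  token <- unlist(token, use.names = FALSE)
  tstart <- as.integer(unlist(tstart, use.names = FALSE))
  list(token = token, start = tstart, end = tstart + nchar(token))
}

#' Tokenize every document in a corpus
#'
#' @param corpus A data frame with columns `doc_id` and `text`.
#' @return A tibble with columns `doc_id`, `token`, `start`, `end` (offsets
#'   0-based half-open into the document text), in document order.
#' @export
tokenize_corpus <- function(corpus) {
  assert_corpus(corpus)
  empty <- tibble::tibble(doc_id = character(), token = character(),
                          start = integer(), end = integer())
  if (nrow(corpus) == 0) return(empty)
  ms <- gregexpr("\\S+", corpus$text, perl = TRUE)
  n_chunks <- vapply(ms, function(m) if (m[1] == -1L) 0L else length(m), 0L)
  if (sum(n_chunks) == 0) return(empty)
  doc_of <- rep(corpus$doc_id, n_chunks)
  starts1 <- unlist(lapply(ms, function(m) if (m[1] == -1L) integer() else as.integer(m)))
  lens <- unlist(lapply(ms, function(m) if (m[1] == -1L) integer() else attr(m, "match.length")))
  chunks <- substring(rep(corpus$text, n_chunks), starts1, starts1 + lens - 1L)

  parts <- regmatches(chunks, regexec("^(\\p{P}*)(.*?)(\\p{P}*)$", chunks, perl = TRUE))
  lead <- vapply(parts, `[`, "", 2L)
  core <- vapply(parts, `[`, "", 3L)
  trail <- vapply(parts, `[`, "", 4L)

  piece_tokens <- function(lead, core, trail) {
    c(if (nzchar(lead)) strsplit(lead, "", fixed = TRUE)[[1]],
      if (nzchar(core)) core,
      if (nzchar(trail)) strsplit(trail, "", fixed = TRUE)[[1]])
  }
  toks <- mapply(piece_tokens, lead, core, trail,
                 SIMPLIFY = FALSE, USE.NAMES = FALSE)
  n_tok <- lengths(toks)
  tok <- unlist(toks, use.names = FALSE)
  tok_nchar <- nchar(tok)
  # offsets: tokens within a chunk are contiguous
  chunk_start0 <- rep(starts1 - 1L, n_tok)
  off_in_chunk <- unlist(lapply(n_tok, seq_len), use.names = FALSE)
  # cumulative char offset of each token inside its chunk
  cum <- unlist(lapply(split(tok_nchar, rep(seq_along(n_tok), n_tok)),
                       function(x) cumsum(c(0L, x[-length(x)]))),
                use.names = FALSE)
  start <- chunk_start0 + cum
  tibble::tibble(doc_id = rep(doc_of, n_tok), token = tok,
                 start = as.integer(start), end = as.integer(start + tok_nchar))
}

doc_fields <- c("doc_id", "doc_type", "age_group", "gender", "diagnosis_code", "text")
doc_types <- c("medical_history", "procedure")

#' Read / write a JSONL corpus
#'
#' One JSON object per line with fields `doc_id`, `text` and the optional
#' metadata header fields `doc_type`, `age_group`, `gender`,
#' `diagnosis_code` (missing metadata is filled with `"unknown"`). Files
#' are UTF-8. `write_corpus_jsonl()` followed by `read_corpus_jsonl()` is
#' the identity on all fields.
#'
#' @param path File path.
#' @return `read_corpus_jsonl()` returns a corpus tibble in file order.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(obj) || !is.list(obj)) {
      abort(sprintf("malformed JSON on line %d of %s", i, path))
    }
    if (is.null(obj$doc_id) || !nzchar(obj$doc_id)) {
      abort(sprintf("line %d of %s: missing \"doc_id\"", i, path))
    }
    if (is.null(obj$text) || !nzchar(obj$text)) {
      abort(sprintf("line %d of %s: missing or empty \"text\"", i, path))
    }
    meta <- setdiff(doc_fields, c("doc_id", "text"))
    vals <- lapply(meta, function(f) {
      v <- obj[[f]]
      if (is.null(v) || is.na(v) || !nzchar(v)) "unknown" else as.character(v)
    })
    names(vals) <- meta
    if (!vals$doc_type %in% c(doc_types, "unknown")) {
      abort(sprintf("line %d of %s: doc_type must be one of %s", i, path,
                    paste(doc_types, collapse = ", ")))
    }
    tibble::tibble(doc_id = as.character(obj$doc_id), doc_type = vals$doc_type,
                   age_group = vals$age_group, gender = vals$gender,
                   diagnosis_code = vals$diagnosis_code,
                   text = as.character(obj$text))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::as_tibble(stats::setNames(rep(list(character()), 6), doc_fields))
  }
  assert_corpus(out)
  out
}

#' @param corpus A corpus data frame (`doc_id`, `text`, optional metadata).
#' @rdname read_corpus_jsonl
#' @export
write_corpus_jsonl <- function(corpus, path) {
  assert_corpus(corpus)
  for (f in setdiff(doc_fields, names(corpus))) corpus[[f]] <- "unknown"
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(as.list(corpus[i, doc_fields]), auto_unbox = TRUE)
  }, "")
  writeLines(enc2utf8(lines), path, useBytes = TRUE)
  invisible(path)
}

#' Read / write tagged token sequences as CoNLL-style TSV
#'
#' Two tab-separated columns (`token`, `tag`), one token per line, a blank
#' line terminating each document. Character offsets are not serialized;
#' `read_conll()` assigns fresh sequential document ids. Reading back a
#' written file preserves every (token, tag) pair.
#'
#' @param tags A tagged tibble with columns `doc_id`, `token`, `tag`; tags
#'   are IOB2 labels over `classes`.
#' @param path File path.
#' @param classes Entity class labels admitted in tags.
#' @export
write_conll <- function(tags, path, classes = ner_classes) {
  stopifnot(all(c("doc_id", "token", "tag") %in% names(tags)))
  check_labels(tags$tag, classes)
  out <- unlist(lapply(split(tags, factor(tags$doc_id, levels = unique(tags$doc_id))),
                       function(d) c(paste0(d$token, "\t", d$tag), "")),
                use.names = FALSE)
  writeLines(enc2utf8(out), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_conll
#' @return `read_conll()` returns a tibble with columns `doc_id`, `token`,
#'   `tag`.
#' @export
read_conll <- function(path, classes = ner_classes) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  blank <- !nzchar(trimws(lines))
  doc_no <- cumsum(c(TRUE, blank[-length(blank)]))[!blank]
  keep <- which(!blank)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    abort(sprintf("line %d of %s: expected \"token<TAB>tag\"", keep[bad[1]], path))
  }
  token <- vapply(parts, `[`, "", 1L)
  tag <- vapply(parts, `[`, "", 2L)
  ok <- tag %in% valid_labels(classes)
  if (!all(ok)) {
    abort(sprintf("line %d of %s: unknown tag \"%s\"",
                  keep[which(!ok)[1]], path, tag[which(!ok)[1]]))
  }
  doc_ids <- sprintf("doc_%05d", doc_no)
  tibble::tibble(doc_id = doc_ids, token = token, tag = tag)
}

valid_labels <- function(classes) {
  c("O", paste0("B-", classes), paste0("I-", classes))
}

check_labels <- function(tags, classes) {
  bad <- setdiff(unique(tags), valid_labels(classes))
  if (length(bad)) {
    abort(sprintf("unknown tag label(s): %s", paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Check the IOB2 chaining invariant
#'
#' A label vector is strict IOB2 when every `I-X` is preceded by `B-X` or
#' `I-X` of the same class.
#'
#' @param labels Character vector of IOB2 labels for one document.
#' @param classes Entity class labels.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_iob2 <- function(labels, classes = ner_classes) {
  check_labels(labels, classes)
  if (length(labels) == 0) return(TRUE)
  pre <- substr(labels, 1, 1)
  typ <- ifelse(labels == "O", "", substring(labels, 3))
  prev_pre <- c("O", pre[-length(pre)])
  prev_typ <- c("", typ[-length(typ)])
  !any(pre == "I" & !(prev_pre %in% c("B", "I") & prev_typ == typ))
}
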