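#' Longest common subsequence length of two token sequences
#'
#' Classic dynamic-programming LCS over word tokens; symmetric in its
#' arguments. The LCS is the backbone of the originality score used to
#' detect generated texts that copy the generator's training data even
#' when individual words were replaced, deleted, or inserted.
#'
#' @param a,b Character vectors of tokens.
#' @return Nonnegative integer.
#' @export
lcs_length <- function(a, b) {
  codes <- encode_pair(a, b)
  cpp_lcs_length(codes$a, codes$b)
}

#' Longest common contiguous run of two token sequences
#'
#' Length of the longest common substring at the token level. Diagnostic
#' companion to [penalized_lcs_score()]: with penalty length `k = 1`,
#' the penalized score behaves approximately (not exactly — a chain of two
#' long runs can out-score the single longest run under the subtract-one
#' rule) like this quantity divided by `length(a)`.
#'
#' @inheritParams lcs_length
#' @return Nonnegative integer.
#' @export
longest_common_run <- function(a, b) {
  codes <- encode_pair(a, b)
  cpp_longest_common_run(codes$a, codes$b)
}

#' LCS originality score of a generated text against a training text
#'
#' `lcs_length(gen, train) / length(gen)`: 0 means the texts share no
#' ordered tokens (unique), 1 means every token of the generated text
#' occurs in order in the training text (identical or fully contained).
#'
#' @param gen Token sequence of the generated text (non-empty).
#' @param train Token sequence of a training text.
#' @return A fraction in `[0, 1]`.
#' @export
lcs_score <- function(gen, train) {
  if (length(gen) == 0) abort("`gen` must be a non-empty token sequence")
  lcs_length(gen, train) / length(gen)
}

#' Gap-penalized LCS originality score
#'
#' Plain LCS rewards matches scattered across hundreds of tokens that do
#' not represent continuous expressions. The penalized score subtracts,
#' for each pair of consecutive matched tokens, a penalty
#' `min(gap / k, 1)` where `gap` is the larger of the number of tokens
#' skipped in the two sequences (adjacent matched tokens give gap 0, so a
#' contiguous verbatim copy is not penalized at all; a gap of `k` or more
#' costs a full matched token). The returned value is the maximum over all
#' common-subsequence chains of `(L - total penalty) / length(gen)`,
#' clamped below at 0.
#'
#' The default `mode = "optimal"` maximizes the penalized objective by its
#' own dynamic program over match pairs, so the reported score does not
#' depend on an arbitrary LCS backtrace. `mode = "classic_path"` instead
#' penalizes the single canonical classic-LCS chain (dynamic-programming
#' ties broken toward contiguity), mimicking a post-hoc penalty on a
#' standard LCS implementation; it can only be lower.
#'
#' @inheritParams lcs_score
#' @param k Positive penalty length; larger `k` forgives larger gaps.
#'   Default 20, effective at removing scattered matches without being
#'   overly restrictive.
#' @param mode `"optimal"` (default) or `"classic_path"`.
#' @return A fraction in `[0, 1]`.
#' @export
penalized_lcs_score <- function(gen, train, k = 20, mode = c("optimal", "classic_path")) {
  mode <- match.arg(mode)
  if (length(gen) == 0) abort("`gen` must be a non-empty token sequence")
  if (!is.numeric(k) || length(k) != 1 || k < 1) abort("`k` must be a number >= 1")
  codes <- encode_pair(gen, train)
  raw <- if (mode == "optimal") {
    cpp_penalized_best(codes$a, codes$b, as.numeric(k))
  } else {
    cpp_penalized_classic_path(codes$a, codes$b, as.numeric(k))
  }
  max(raw, 0) / length(gen)
}

#' Originality report of generated texts against a training corpus
#'
#' For each generated document, tokenizes both corpora, computes the plain
#' LCS score against every training document, selects the best-matching
#' training document (ties broken by first occurrence in corpus order),
#' and computes the penalized score against that same best match.
#'
#' @param generated,training Corpus tibbles (`doc_id`, `text`); `training`
#'   must be non-empty and every generated text must tokenize to at least
#'   one token.
#' @param k Penalty length passed to [penalized_lcs_score()].
#' @param case_sensitive Compare tokens case-sensitively (default) or
#'   after lower-casing.
#' @param mode Penalized-score mode, see [penalized_lcs_score()].
#' @return A tibble with one row per generated document: `doc_id`,
#'   `best_training_id`, `lcs_score`, `penalized_score`, `k`.
#' @export
originality_score <- function(generated, training, k = 20, case_sensitive = TRUE,
                              mode = c("optimal", "classic_path")) {
  mode <- match.arg(mode)
  assert_corpus(generated, "generated")
  assert_corpus(training, "training")
  if (nrow(training) == 0) abort("`training` corpus is empty")
  if (!is.numeric(k) || length(k) != 1 || k < 1) abort("`k` must be a number >= 1")

  gt <- tokenize_corpus(generated)
  tt <- tokenize_corpus(training)
  fold <- function(x) if (case_sensitive) x else tolower(x)
  lev <- unique(c(gt$token <- fold(gt$token), tt$token <- fold(tt$token)))
  gt_codes <- split(match(gt$token, lev), factor(gt$doc_id, levels = generated$doc_id))
  tt_codes <- split(match(tt$token, lev), factor(tt$doc_id, levels = training$doc_id))
  empty_gen <- generated$doc_id[lengths(gt_codes) == 0]
  if (length(empty_gen)) {
    abort(sprintf("generated document(s) with no tokens: %s",
                  paste(head(empty_gen, 3), collapse = ", ")))
  }

  rows <- lapply(generated$doc_id, function(id) {
    gen <- gt_codes[[id]]
    lens <- cpp_lcs_length_many(gen, tt_codes)
    best <- which.max(lens)  # first occurrence wins ties
    train <- tt_codes[[best]]
    raw <- if (mode == "optimal") cpp_penalized_best(gen, train, as.numeric(k))
           else cpp_penalized_classic_path(gen, train, as.numeric(k))
    tibble::tibble(doc_id = id, best_training_id = training$doc_id[best],
                   lcs_score = lens[best] / length(gen),
                   penalized_score = max(raw, 0) / length(gen), k = k)
  })
  dplyr::bind_rows(rows)
}

#' Best-matching training text for one generated document
#'
#' Single-document convenience wrapper around [originality_score()].
#'
#' @param gen A one-row corpus tibble (the generated document).
#' @inheritParams originality_score
#' @return A one-row originality report tibble.
#' @export
best_match <- function(gen, training, k = 20, case_sensitive = TRUE,
                       mode = c("optimal", "classic_path")) {
  stopifnot(nrow(gen) == 1)
  originality_score(gen, training, k = k, case_sensitive = case_sensitive,
                    mode = match.arg(mode))
}

#' Partition generated texts into kept and removed by originality score
#'
#' Documents whose chosen score is at or above the threshold are treated
#' as near-verbatim copies of the training data and removed; relative
#' order is preserved. The threshold is a required choice (there is no
#' universally safe default: it trades privacy against corpus yield).
#'
#' @param reports An originality report tibble from [originality_score()].
#' @param threshold Removal threshold in `(0, 1]`.
#' @param score_field `"penalized"` (default) or `"plain"`.
#' @return A list with character vectors `kept` and `removed` of document
#'   ids, partitioning `reports$doc_id`.
#' @export
filter_corpus <- function(reports, threshold, score_field = c("penalized", "plain")) {
  score_field <- match.arg(score_field)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    abort("`threshold` must be a single number in (0, 1]")
  }
  if (nrow(reports) == 0) return(list(kept = character(), removed = character()))
  score <- if (score_field == "penalized") reports$penalized_score else reports$lcs_score
  rm <- score >= threshold
  list(kept = reports$doc_id[!rm], removed = reports$doc_id[rm])
}

encode_pair <- function(a, b) {
  stopifnot(is.character(a) || length(a) == 0, is.character(b) || length(b) == 0)
  lev <- unique(c(a, b))
  list(a = match(as.character(a), lev), b = match(as.character(b), lev))
}
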