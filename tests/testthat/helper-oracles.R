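# Independent oracles used to validate the package's dynamic programs and
# metrics. Each is written as a direct transcription of the defining
# property (enumeration, root finding, per-token state machine) and shares
# no code with the implementation it checks.

# --- LCS by exhaustive subsequence enumeration (lengths <= ~10) ---------

oracle_is_subseq <- function(x, y) {
  j <- 1L
  for (t in x) {
    while (j <= length(y) && y[j] != t) j <- j + 1L
    if (j > length(y)) return(FALSE)
    j <- j + 1L
  }
  TRUE
}

oracle_lcs_length <- function(a, b) {
  n <- length(a)
  if (n == 0 || length(b) == 0) return(0L)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    sel <- a[bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) > 0]
    if (length(sel) > best && oracle_is_subseq(sel, b)) best <- length(sel)
  }
  best
}

# --- penalized LCS by enumeration over all common-subsequence chains ----

oracle_penalized_score <- function(a, b, k) {
  pairs <- which(outer(a, b, "=="), arr.ind = TRUE)
  if (nrow(pairs) == 0) return(0)
  best <- 0
  recurse <- function(pi, pj, val) {
    if (val > best) best <<- val
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      if (i > pi && j > pj) {
        pen <- if (pi == 0) 0 else min(max(i - pi - 1, j - pj - 1) / k, 1)
        recurse(i, j, val + 1 - pen)
      }
    }
  }
  recurse(0L, 0L, 0)
  max(best, 0) / length(a)
}

# --- Wilson interval by numeric root finding on the score equation ------

oracle_wilson <- function(s, n, z = 1.96) {
  phat <- s / n
  f <- function(p) (phat - p)^2 - z^2 * p * (1 - p) / n
  eps <- 1e-9  # step inside [0, 1] so the bracket has a strict sign change
  low <- if (s == 0) 0 else stats::uniroot(f, c(0, min(phat, 1 - eps)), tol = 1e-12)$root
  high <- if (s == n) 1 else stats::uniroot(f, c(max(phat, eps), 1), tol = 1e-12)$root
  c(low = low, high = high)
}

# --- chunk extraction and metrics, transcribed from the reference -------
# sequence-evaluation library's default (lenient) scheme ------------------

oracle_chunk_start <- function(prev_tag, tag, prev_type, type) {
  tag == "B" ||
    (prev_tag == "O" && tag == "I") ||
    (tag != "O" && prev_type != type)
}

oracle_chunk_end <- function(prev_tag, tag, prev_type, type) {
  (prev_tag == "B" && tag == "B") ||
    (prev_tag == "B" && tag == "O") ||
    (prev_tag == "I" && tag %in% c("B", "O")) ||
    (prev_tag != "O" && prev_type != type)
}

# seqs: list of label vectors; returns set of "type:start:end" with global
# 0-based half-open offsets (documents separated by an O sentinel)
oracle_entities <- function(seqs) {
  labels <- unlist(lapply(seqs, function(s) c(s, "O")), use.names = FALSE)
  out <- character()
  prev_tag <- "O"; prev_type <- ""; begin <- 0L
  for (i in seq_along(labels)) {
    tag <- substr(labels[i], 1, 1)
    type <- if (labels[i] == "O") "" else substring(labels[i], 3)
    if (prev_tag != "O" && oracle_chunk_end(prev_tag, tag, prev_type, type)) {
      out <- c(out, sprintf("%s:%d:%d", prev_type, begin, i - 1L))
    }
    if (tag != "O" && oracle_chunk_start(prev_tag, tag, prev_type, type)) {
      begin <- i - 1L
    }
    prev_tag <- tag; prev_type <- type
  }
  out
}

oracle_class_metrics <- function(pred_seqs, gold_seqs, classes) {
  pe <- oracle_entities(pred_seqs)
  ge <- oracle_entities(gold_seqs)
  out <- lapply(classes, function(cl) {
    p <- pe[startsWith(pe, paste0(cl, ":"))]
    g <- ge[startsWith(ge, paste0(cl, ":"))]
    tp <- length(intersect(p, g))
    prec <- if (length(p) == 0) 0 else tp / length(p)
    rec <- if (length(g) == 0) 0 else tp / length(g)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# --- random fixtures ----------------------------------------------------

random_token_seq <- function(max_len = 8, vocab = letters[1:4]) {
  n <- sample(0:max_len, 1)
  if (n == 0) character() else sample(vocab, n, replace = TRUE)
}

random_label_seq <- function(n, classes = ner_classes) {
  sample(c("O", paste0("B-", classes), paste0("I-", classes)), n,
         replace = TRUE, prob = c(8, rep(1.5, length(classes)), rep(1, length(classes))))
}

random_tag_tbl <- function(n_docs, len_range = 4:12, classes = ner_classes) {
  dplyr::bind_rows(lapply(seq_len(n_docs), function(d) {
    n <- sample(len_range, 1)
    tibble::tibble(doc_id = sprintf("d%03d", d),
                   token = sprintf("t%d", seq_len(n)),
                   tag = random_label_seq(n, classes))
  }))
}

small_gold_fixture <- function(n = 30, seed = 42) {
  generate_gold_corpus(generator_config(n = n, seed = seed))
}

gold_tags_for <- function(corpus, gold) {
  toks <- tokenize_corpus(corpus)
  dplyr::bind_rows(lapply(corpus$doc_id, function(id) {
    spans_to_tags(toks[toks$doc_id == id, c("token", "start", "end")],
                  gold[gold$doc_id == id, , drop = FALSE], doc_id = id)
  }))
}

chunk_key <- function(tags) {
  ch <- dplyr::bind_rows(lapply(split(tags, factor(tags$doc_id, levels = unique(tags$doc_id))),
                                function(d) {
    out <- extract_chunks(d$tag)
    if (nrow(out)) out$doc_id <- d$doc_id[1]
    out
  }))
  if (nrow(ch) == 0) return(character())
  with(ch, paste(doc_id, class, start, end))
}
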