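default_display <- list(
  english = c(DRUG = "drug named entity", PROCEDURE = "procedure named entity",
              DISEASE = "disease named entity", SMOKING = "smoking named entity"),
  estonian = c(RAVIM = "ravimite nimeolemid", PROTSEDUUR = "protseduuride nimeolemid",
               HAIGUS = "haiguste nimeolemid", SUITS = "suitsetamiste nimeolemid")
)

default_definitions <- c(
  DRUG = "any names or active ingredients of drugs, including abbreviations; no quantities",
  PROCEDURE = paste0("any mentions of procedures, analyses etc, including also cites ",
                     "(e.g. “ajupiirkonna mrt”); no single blood analyses, ",
                     "only overall mentions of blood analyses"),
  DISEASE = "names of diseases, ICD-10 codes",
  SMOKING = "any mentions of smoking, smoking status, both negative and positive"
)

# Invented example pairs for the few-shot style (the texts are synthetic
# clinical-style snippets in the generator's pseudo-Estonian vocabulary).
default_few_shot_examples <- list(
  list(input = "Patsient kasutab Metforal 500mg kaks korda päevas.",
       output = "{\"DRUG\": [\"Metforal\"], \"PROCEDURE\": [], \"DISEASE\": [], \"SMOKING\": []}"),
  list(input = "Teostatud rindkere röntgen, leid normis.",
       output = "{\"DRUG\": [], \"PROCEDURE\": [\"rindkere röntgen\"], \"DISEASE\": [], \"SMOKING\": []}"),
  list(input = "Anamneesis rinnavähk C50, patsient ei suitseta.",
       output = "{\"DRUG\": [], \"PROCEDURE\": [], \"DISEASE\": [\"rinnavähk\", \"C50\"], \"SMOKING\": [\"ei suitseta\"]}"),
  list(input = "Suitsetab, määratud Enalapriil, plaanis vere analüüs.",
       output = "{\"DRUG\": [\"Enalapriil\"], \"PROCEDURE\": [\"vere analüüs\"], \"DISEASE\": [], \"SMOKING\": [\"Suitsetab\"]}"),
  list(input = "Kaebused puuduvad, kontrollil seisund stabiilne.",
       output = "{\"DRUG\": [], \"PROCEDURE\": [], \"DISEASE\": [], \"SMOKING\": []}")
)

prompt_styles <- c("zero_shot", "estonian", "definitions", "few_shot")

#' Specify one of the four annotation prompt styles
#'
#' The four styles probed in prompt selection: a plain zero-shot
#' instruction, the same instruction translated to Estonian (with
#' Estonian JSON keys RAVIM/PROTSEDUUR/HAIGUS/SUITS), a variant carrying
#' per-class annotation guidelines, and a few-shot variant carrying
#' example input/output pairs (five by default).
#'
#' @param style One of `"zero_shot"`, `"estonian"`, `"definitions"`,
#'   `"few_shot"`.
#' @param definitions Named character vector `class -> guideline text`;
#'   required for the definitions style (defaults to the packaged
#'   guidelines). Must cover every class.
#' @param examples List of `list(input =, output =)` pairs; required for
#'   the few-shot style (defaults to the five packaged synthetic pairs).
#' @param classes Canonical entity class labels.
#' @return A `prompt_spec` object.
#' @export
prompt_spec <- function(style = c("zero_shot", "estonian", "definitions", "few_shot"),
                        definitions = NULL, examples = NULL, classes = ner_classes) {
  style <- match.arg(style)
  if (style == "definitions") {
    definitions <- definitions %||% default_definitions[classes]
    if (length(definitions) == 0 || !all(classes %in% names(definitions))) {
      abort("definitions style requires a guideline for every class")
    }
  }
  if (style == "few_shot") {
    examples <- examples %||% default_few_shot_examples
    ok <- length(examples) >= 1 &&
      all(vapply(examples, function(e) all(c("input", "output") %in% names(e)), TRUE))
    if (!ok) abort("few_shot style requires a non-empty list of input/output example pairs")
  }
  structure(list(style = style, classes = classes,
                 definitions = definitions, examples = examples),
            class = "prompt_spec")
}

#' Render an annotation prompt for one document
#'
#' Pure function: identical spec and text give identical bytes. The
#' payload text is appended on its own line after the closing
#' `"Text below:"` (`"Tekst on järgmine:"` for the Estonian style).
#'
#' @param spec A [prompt_spec()].
#' @param text Document text to annotate.
#' @return A single string.
#' @export
render_prompt <- function(spec, text) {
  stopifnot(inherits(spec, "prompt_spec"), is.character(text), length(text) == 1)
  classes <- spec$classes
  disp <- default_display$english[classes]
  key_lines <- paste0(classes, " for ", disp, ",")
  key_lines[length(key_lines)] <- sub(",$", ".", key_lines[length(key_lines)])
  json_block <- c("Format the output in JSON with the following keys:", key_lines)
  head_list <- paste0(paste(disp, collapse = ", "), ".")

  body <- switch(spec$style,
    zero_shot = c(
      "In the text below, give the list of:", head_list,
      "Words need to be in exactly the same format as in input text.",
      json_block, "Text below:"),
    estonian = {
      est_keys <- names(default_display$estonian)
      est_disp <- unname(default_display$estonian)
      est_lines <- paste0(est_keys, " ", sub("d$", "te", est_disp), " jaoks,")
      est_lines[length(est_lines)] <- sub(",$", ".", est_lines[length(est_lines)])
      c("Loetle järgnevas tekstis järgmiseid nimeolemeid:",
        paste0(paste(est_disp, collapse = ", "), "."),
        "Sõnad päevad olema täpselt samal kujul kui sisendtekstis.",
        "Vorminda väljund JSON kujul järgnevate võtmetega:",
        est_lines, "Tekst on järgmine:")
    },
    definitions = {
      if (is.null(spec$definitions)) abort("definitions style requires definitions")
      c("In the text below, give the list of", head_list,
        "Words need to be in exactly the same format as in input text.",
        "The annotation guidelines are the following:",
        paste0(classes, " - ", spec$definitions[classes]),
        json_block, "Text below:")
    },
    few_shot = {
      if (is.null(spec$examples)) abort("few_shot style requires examples")
      ex <- unlist(lapply(spec$examples, function(e) c(e$input, e$output)))
      c("In the text below, give the list of:", head_list,
        "Words need to be in exactly the same format as in input text.",
        json_block, "Here are a few examples:", ex, "Text below:")
    })
  paste(c(body, text), collapse = "\n")
}

new_ner_response <- function(doc_id = NA_character_, entities = NULL,
                             parsed = FALSE, raw = "") {
  if (is.null(entities)) {
    entities <- tibble::tibble(class = character(), surface = character())
  }
  structure(list(doc_id = doc_id, entities = entities, parsed = parsed, raw = raw),
            class = "ner_response")
}

#' @export
print.ner_response <- function(x, ...) {
  cat(sprintf("<ner_response doc=%s parsed=%s entities=%d>\n",
              x$doc_id, x$parsed, nrow(x$entities)))
  invisible(x)
}

# First balanced-brace candidate scanned left to right that parses as
# strict JSON; brace tracking is string-aware so braces inside quoted
# values do not confuse the scan.
extract_first_json <- function(raw) {
  chars <- strsplit(raw, NULL)[[1]]
  n <- length(chars)
  opens <- which(chars == "{")
  for (i in opens) {
    depth <- 0L; in_str <- FALSE; esc <- FALSE
    for (j in i:n) {
      ch <- chars[j]
      if (in_str) {
        if (esc) esc <- FALSE
        else if (ch == "\\") esc <- TRUE
        else if (ch == "\"") in_str <- FALSE
      } else if (ch == "\"") in_str <- TRUE
      else if (ch == "{") depth <- depth + 1L
      else if (ch == "}") {
        depth <- depth - 1L
        if (depth == 0L) {
          cand <- paste(chars[i:j], collapse = "")
          obj <- tryCatch(jsonlite::fromJSON(cand, simplifyVector = FALSE),
                          error = function(e) NULL)
          if (!is.null(obj) && is.list(obj) && !is.null(names(obj))) return(obj)
          break
        }
      }
    }
  }
  NULL
}

#' Parse an annotator response under the JSON contract
#'
#' Annotators are asked to reply with a JSON object whose keys are the
#' entity classes and whose values are lists of surface strings copied
#' from the input text. Hosted models often wrap the object in prose, so
#' the first balanced-brace candidate (scanned left to right) that parses
#' as JSON is extracted. The response counts as parsed when at least one
#' configured class key (or accepted alias) is present; unknown keys are
#' ignored with a warning; scalar values are promoted to one-element
#' lists. Parsing never throws: failure is encoded as `parsed = FALSE`
#' with an empty entity table.
#'
#' @param raw Raw response text.
#' @param classes Canonical entity class labels.
#' @param aliases Named character vector mapping alternative response keys
#'   to canonical classes (e.g. the Estonian keys when the Estonian prompt
#'   style is in use); `NULL` to accept canonical keys only.
#' @param doc_id Optional document id recorded on the response.
#' @return A `ner_response`: fields `doc_id`, `entities` (tibble with
#'   columns `class`, `surface`), `parsed`, `raw`.
#' @export
parse_response <- function(raw, classes = ner_classes, aliases = NULL,
                           doc_id = NA_character_) {
  if (!is.character(raw) || length(raw) != 1 || is.na(raw)) {
    return(new_ner_response(doc_id, raw = ""))
  }
  obj <- extract_first_json(raw)
  if (is.null(obj)) return(new_ner_response(doc_id, raw = raw))
  key_map <- stats::setNames(classes, classes)
  if (!is.null(aliases)) key_map <- c(key_map, aliases[aliases %in% classes])
  known <- names(obj)[names(obj) %in% names(key_map)]
  unknown <- setdiff(names(obj), names(key_map))
  if (length(unknown)) {
    warn(sprintf("ignoring unknown response key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (length(known) == 0) return(new_ner_response(doc_id, raw = raw))
  rows <- lapply(known, function(key) {
    vals <- obj[[key]]
    vals <- unlist(vals, use.names = FALSE)
    vals <- as.character(vals[!is.na(vals) & nzchar(vals)])
    if (length(vals) == 0) return(NULL)
    tibble::tibble(class = unname(key_map[key]), surface = vals)
  })
  entities <- dplyr::bind_rows(rows)
  if (nrow(entities) == 0) {
    entities <- tibble::tibble(class = character(), surface = character())
  } else {
    entities <- dplyr::distinct(entities)
    entities$class <- as.character(entities$class)
  }
  new_ner_response(doc_id, entities = entities, parsed = TRUE, raw = raw)
}

#' Deterministic gazetteer annotation of one text
#'
#' Reports every gazetteer surface that occurs in the text as a
#' contiguous whole-token match, once per class. A deterministic
#' stand-in for a hosted model: useful as a perfect annotator when the
#' gazetteer equals the generator vocabulary.
#'
#' @param text Document text.
#' @param gazetteer Named list `class -> character vector of surfaces`.
#' @param doc_id Optional document id for the response.
#' @param gaz_tokens Optional pre-tokenized gazetteer (internal cache used
#'   by [gazetteer_annotator()] to avoid re-tokenizing surfaces per call).
#' @return A `ner_response` with `parsed = TRUE`.
#' @export
gazetteer_annotate <- function(text, gazetteer, doc_id = NA_character_,
                               gaz_tokens = NULL) {
  if (length(gazetteer) == 0) abort("`gazetteer` must be non-empty")
  if (is.null(gaz_tokens)) gaz_tokens <- tokenize_gazetteer(gazetteer)
  toks <- .tokenize_one(text)$token
  rows <- lapply(names(gazetteer), function(cls) {
    hits <- gazetteer[[cls]][vapply(gaz_tokens[[cls]], function(s) {
      has_token_subseq(toks, s)
    }, TRUE)]
    if (length(hits) == 0) return(NULL)
    tibble::tibble(class = cls, surface = unname(hits))
  })
  entities <- dplyr::bind_rows(rows)
  if (nrow(entities) == 0) {
    entities <- tibble::tibble(class = character(), surface = character())
  }
  new_ner_response(doc_id, entities = entities, parsed = TRUE,
                   raw = entities_json(entities, names(gazetteer)))
}

tokenize_gazetteer <- function(gazetteer) {
  lapply(gazetteer, function(surfs) lapply(surfs, function(s) .tokenize_one(s)$token))
}

has_token_subseq <- function(toks, sub) {
  ls <- length(sub); lt <- length(toks)
  if (ls == 0 || ls > lt) return(FALSE)
  for (i in seq_len(lt - ls + 1)) {
    if (all(toks[i:(i + ls - 1)] == sub)) return(TRUE)
  }
  FALSE
}

entities_json <- function(entities, classes) {
  lst <- lapply(classes, function(cls) {
    as.list(entities$surface[entities$class == cls])
  })
  names(lst) <- classes
  as.character(jsonlite::toJSON(lst, auto_unbox = TRUE))
}

#' Annotation-noise configuration
#'
#' Parameterizes the error modes real LLM annotators exhibit: omitted
#' mentions, spurious mentions, one-token boundary slips, and responses
#' that fail to parse at all. All randomness is reproducible from `seed`
#' (each document draws from a stream derived from the seed and its id,
#' so results do not depend on processing order).
#'
#' @param drop_prob Probability each gold mention is omitted.
#' @param spurious_prob Expected number of spurious mentions per document
#'   (Poisson rate); spurious surfaces are random 1-2-token snippets of
#'   the document text with a random class.
#' @param boundary_shift_prob Probability a reported surface is truncated
#'   or extended by one token.
#' @param garble_prob Probability the whole response is unparseable prose.
#' @param seed Integer seed.
#' @return A `noise_config` object.
#' @export
noise_config <- function(drop_prob = 0, spurious_prob = 0,
                         boundary_shift_prob = 0, garble_prob = 0, seed = 1L) {
  probs <- c(drop_prob, boundary_shift_prob, garble_prob)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (spurious_prob < 0) abort("`spurious_prob` must be >= 0")
  structure(list(drop_prob = drop_prob, spurious_prob = spurious_prob,
                 boundary_shift_prob = boundary_shift_prob,
                 garble_prob = garble_prob, seed = as.integer(seed)),
            class = "noise_config")
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Perturb gold annotations with a seeded noise model
#'
#' Applies, in order: whole-response garbling, independent mention drops,
#' one-token boundary shifts, and Poisson-distributed spurious mentions
#' drawn as random token snippets of the document text. With all rates at
#' zero the response lists exactly the gold surfaces.
#'
#' @param gold Gold mention tibble for this document (columns `class`,
#'   `surface`, `start`, `end`, `token_start`, `token_end`).
#' @param cfg A [noise_config()].
#' @param doc A one-row corpus tibble (or list) with `doc_id` and `text`.
#' @param classes Entity class labels for spurious draws and the JSON raw
#'   form.
#' @return A `ner_response`.
#' @export
perturb_annotations <- function(gold, cfg, doc, classes = ner_classes) {
  stopifnot(inherits(cfg, "noise_config"))
  doc_id <- doc$doc_id[[1]]
  text <- doc$text[[1]]
  with_seed(derive_seed(cfg$seed, doc_id), {
    if (runif(1) < cfg$garble_prob) {
      return(new_ner_response(doc_id, parsed = FALSE,
                              raw = "Sorry, I cannot annotate this text."))
    }
    toks <- .tokenize_one(text)
    n_tok <- length(toks$token)
    keep <- if (nrow(gold)) runif(nrow(gold)) >= cfg$drop_prob else logical()
    kept <- gold[keep, , drop = FALSE]
    surfaces <- character(); cls_out <- character()
    if (nrow(kept)) {
      for (i in seq_len(nrow(kept))) {
        ts <- kept$token_start[i]; te <- kept$token_end[i]  # 0-based half-open
        if (runif(1) < cfg$boundary_shift_prob) {
          if (te - ts > 1 && runif(1) < 0.5) te <- te - 1
          else if (te < n_tok) te <- te + 1
          else if (te - ts > 1) te <- te - 1
        }
        surf <- substr(text, toks$start[ts + 1] + 1, toks$end[te])
        surfaces <- c(surfaces, surf); cls_out <- c(cls_out, kept$class[i])
      }
    }
    n_sp <- rpois(1, cfg$spurious_prob)
    word_pos <- which(!grepl("^\\p{P}+$", toks$token, perl = TRUE))
    if (n_sp > 0 && length(word_pos) > 0) {
      for (s in seq_len(n_sp)) {
        # spurious surfaces are word snippets (models misreport words,
        # not stray punctuation)
        len <- min(sample(1:2, 1), n_tok)
        st <- word_pos[sample(length(word_pos), 1)]
        if (st + len - 1 > n_tok || grepl("^\\p{P}+$", toks$token[st + len - 1], perl = TRUE)) {
          len <- 1
        }
        surf <- substr(text, toks$start[st] + 1, toks$end[st + len - 1])
        surfaces <- c(surfaces, surf)
        cls_out <- c(cls_out, sample(classes, 1))
      }
    }
    entities <- tibble::tibble(class = cls_out, surface = surfaces)
    entities <- dplyr::distinct(entities)
    new_ner_response(doc_id, entities = entities, parsed = TRUE,
                     raw = entities_json(entities, classes))
  })
}

#' Build annotator closures for [batch_annotate()]
#'
#' An annotator is any function `(text, doc_id, prompt) -> raw response
#' string`; an adapter for a hosted model would send `prompt` over an API
#' and return the body. `gazetteer_annotator()` answers from a dictionary;
#' `noisy_annotator()` corrupts gold annotations under a
#' [noise_config()], emulating annotators of different quality.
#'
#' @param gazetteer Named list `class -> surfaces`.
#' @return A function `(text, doc_id, prompt) -> raw string`.
#' @export
gazetteer_annotator <- function(gazetteer) {
  force(gazetteer)
  gaz_tokens <- tokenize_gazetteer(gazetteer)
  function(text, doc_id = NA_character_, prompt = NULL) {
    gazetteer_annotate(text, gazetteer, doc_id = doc_id, gaz_tokens = gaz_tokens)$raw
  }
}

#' @param gold Gold mention tibble with a `doc_id` column covering the
#'   corpus to annotate.
#' @param cfg A [noise_config()].
#' @param classes Entity class labels.
#' @rdname gazetteer_annotator
#' @export
noisy_annotator <- function(gold, cfg, classes = ner_classes) {
  force(gold); force(cfg); force(classes)
  gold_by_doc <- split(gold, gold$doc_id)
  empty <- gold[0, , drop = FALSE]
  function(text, doc_id, prompt = NULL) {
    g <- gold_by_doc[[doc_id]] %||% empty
    perturb_annotations(g, cfg, list(doc_id = doc_id, text = text),
                        classes = classes)$raw
  }
}

#' Annotate a corpus with an annotator function
#'
#' Renders the prompt (when a [prompt_spec()] is given), calls the
#' annotator on every document, and parses each raw response under the
#' JSON contract. An annotator error on one document yields
#' `parsed = FALSE` for that document and processing continues. The
#' Estonian response keys are accepted as aliases when the prompt style is
#' `"estonian"`.
#'
#' @param corpus Corpus tibble (`doc_id`, `text`).
#' @param annotator Function `(text, doc_id, prompt) -> raw string`.
#' @param spec Optional [prompt_spec()].
#' @param classes Entity class labels.
#' @return A tibble with one row per document, in corpus order: `doc_id`,
#'   `parsed`, `raw`, and list-column `entities` (each a tibble with
#'   columns `class`, `surface`). The parsed-response count is
#'   `sum(out$parsed)`.
#' @export
batch_annotate <- function(corpus, annotator, spec = NULL, classes = ner_classes) {
  assert_corpus(corpus)
  aliases <- if (!is.null(spec) && spec$style == "estonian") estonian_class_keys else NULL
  rows <- lapply(seq_len(nrow(corpus)), function(i) {
    id <- corpus$doc_id[i]; text <- corpus$text[i]
    prompt <- if (!is.null(spec)) render_prompt(spec, text) else text
    raw <- tryCatch(annotator(text, id, prompt), error = function(e) NA_character_)
    r <- parse_response(raw, classes = classes, aliases = aliases, doc_id = id)
    tibble::tibble(doc_id = id, parsed = r$parsed,
                   raw = if (is.na(raw %||% NA_character_)) "" else raw,
                   entities = list(r$entities))
  })
  dplyr::bind_rows(rows)
}
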