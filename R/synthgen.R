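# Invented pseudo-Estonian vocabularies. Surfaces are synthetic stand-ins
# for the private clinical vocabularies; tokens are unique to their class
# (no surface of one class is a token-boundary substring of another) so
# that dictionary annotation of generated text is exact.
default_vocab <- function() {
  list(
    DRUG = c("Metforal", "Kardiprex", "Dolvanol", "Aspiriin", "Paratsetamool",
             "Ibuprofeen", "Enalapriil", "Metoprolool", "Amoksitsilliin",
             "Doksütsükliin", "Varfariin", "Letrosool", "Tamoksifeen",
             "Omeprasool", "Simvastatiin", "Losartaan", "Furosemiid",
             "Prednisoloon", "Diklofenak", "Tramadool", "Bisoprolool",
             "Klaritromütsiin", "Melatoniin", "Ranitidiin"),
    PROCEDURE = c("rindkere röntgen", "vere analüüs", "ultraheli uuring",
                  "kompuutertomograafia", "mammograafia", "biopsia", "EKG",
                  "operatsioon", "kiiritusravi", "keemiaravi", "MRT uuring",
                  "palpatsioon", "punktsioon", "sonograafia", "endoskoopia",
                  "kolonoskoopia", "spirograafia", "vaktsineerimine",
                  "füsioteraapia", "densitomeetria"),
    DISEASE = c("C50", "rinnavähk", "hüpertoonia", "diabeet", "astma",
                "kopsupõletik", "gastriit", "artriit", "osteoporoos",
                "migreen", "depressioon", "aneemia", "I10", "E11", "J45",
                "bronhiit", "türeoidiit", "kasvaja"),
    SMOKING = c("suitsetab", "ei suitseta", "endine suitsetaja",
                "suitsetamine", "loobus suitsetamisest",
                "passiivne suitsetaja", "mittesuitsetaja")
  )
}

# Sentence templates: character vectors of words, "{CLASS}" marks the slot.
# Template words are disjoint from every entity vocabulary token.
default_templates <- function() {
  list(
    DRUG = list(
      c("Määratud", "{DRUG}", "üks", "tablett", "päevas", "."),
      c("Patsient", "kasutab", "{DRUG}", "regulaarselt", "."),
      c("Alustatud", "raviskeemi", "{DRUG}", "annusega", "."),
      c("Jätkata", "{DRUG}", "senises", "annuses", "."),
      c("Kõrvaltoimeid", "{DRUG}", "foonil", "pole", "täheldatud", ".")),
    PROCEDURE = list(
      c("Teostatud", "{PROCEDURE}", ",", "leid", "normis", "."),
      c("Plaanis", "{PROCEDURE}", "järgmisel", "visiidil", "."),
      c("Tehtud", "{PROCEDURE}", "ilma", "tüsistusteta", "."),
      c("Patsient", "suunatud", "{PROCEDURE}", "uuringule", "."),
      c("Korratud", "{PROCEDURE}", "kahe", "nädala", "pärast", ".")),
    DISEASE = list(
      c("Anamneesis", "{DISEASE}", "."),
      c("Diagnoositud", "{DISEASE}", "eelmisel", "aastal", "."),
      c("Põhidiagnoos", "on", "{DISEASE}", "."),
      c("Kaasuvalt", "esineb", "{DISEASE}", "."),
      c("Perekonnas", "esinenud", "{DISEASE}", ".")),
    SMOKING = list(
      c("Patsient", "{SMOKING}", "."),
      c("Elustiil", ":", "{SMOKING}", "."),
      c("Märkus", ":", "{SMOKING}", ".")),
    filler_history = list(
      c("Üldseisund", "rahuldav", ",", "kaebused", "puuduvad", "."),
      c("Enesetunne", "viimasel", "ajal", "paranenud", "."),
      c("Patsient", "käis", "kontrollil", "plaanipäraselt", "."),
      c("Soovitatud", "jälgimine", "ja", "kordusvisiit", "."),
      c("Seisund", "püsib", "stabiilne", ".")),
    filler_procedure = list(
      c("Protseduur", "talutud", "hästi", "."),
      c("Tüsistusi", "ei", "esinenud", "."),
      c("Patsient", "lahkus", "osakonnast", "samal", "päeval", "."),
      c("Kontrollanalüüsid", "jäävad", "ootele", "."))
  )
}

# Disjoint background wording for training-pool "fresh" documents: shares
# no template or filler token with the default set (entity vocabularies
# are still the shared ones).
background_templates <- function() {
  list(
    DRUG = list(
      c("Retseptile", "lisatud", "{DRUG}", "pikaajaliselt", ";"),
      c("Tarvitab", "{DRUG}", "igal", "hommikul", ";")),
    PROCEDURE = list(
      c("Broneeritud", "{PROCEDURE}", "kevadeks", ";"),
      c("Registreeritud", "{PROCEDURE}", "tulemus", "ootel", ";")),
    DISEASE = list(
      c("Varasemalt", "poetud", "{DISEASE}", ";"),
      c("Registris", "märgitud", "{DISEASE}", ";")),
    SMOKING = list(
      c("Harjumused", "-", "{SMOKING}", ";")),
    filler_history = list(
      c("Dokument", "koostatud", "perearsti", "poolt", ";"),
      c("Lisainfo", "saadaval", "registratuurist", ";")),
    filler_procedure = list(
      c("Protokoll", "salvestatud", "infosüsteemi", ";"),
      c("Aparatuur", "töötas", "korrektselt", ";"))
  )
}

default_age_bands <- function() {
  lo <- seq(15, 75, by = 5)
  sprintf("%d-%d", lo, lo + 4)
}

#' Configure the synthetic-corpus generator
#'
#' The generator emulates short Estonian-EHR-like documents of two types
#' (medical histories and procedure notes) assembled from sentence
#' templates with typed slots filled from per-class vocabularies. Per
#' document, the number of mentions of each class is Poisson-distributed
#' around the configured mean. Defaults: two thirds of documents are
#' medical histories; per-class means 0.438 (drug), 1.286 (procedure),
#' 0.644 (disease), 0.116 (smoking) mentions per document, matching the
#' class mix of a 500-document expert-annotated reference set (219 drug,
#' 643 procedure, 322 disease, 58 smoking mentions); 13 five-year age
#' bands spanning ages 15-80; breast-cancer diagnosis code C50.
#'
#' @param n Number of documents.
#' @param frac_history Fraction of documents of type `medical_history`
#'   (the rest are `procedure`); counts are rounded.
#' @param mean_mentions Named numeric vector of per-document mention
#'   means per class.
#' @param vocab Named list `class -> character vector of surfaces`;
#'   non-empty for every class with a positive mean.
#' @param templates Sentence template set (see source for the format).
#' @param age_bands,genders,diagnosis_codes Metadata header vocabularies.
#' @param seed Integer seed; the whole corpus is reproducible from it.
#' @return A `generator_config` object.
#' @export
generator_config <- function(n = 500, frac_history = 2 / 3,
                             mean_mentions = c(DRUG = 0.438, PROCEDURE = 1.286,
                                               DISEASE = 0.644, SMOKING = 0.116),
                             vocab = default_vocab(),
                             templates = default_templates(),
                             age_bands = default_age_bands(),
                             genders = c("F", "M"),
                             diagnosis_codes = "C50",
                             seed = 1L) {
  if (frac_history < 0 || frac_history > 1) abort("`frac_history` must be in [0, 1]")
  active <- names(mean_mentions)[mean_mentions > 0]
  empty <- active[!vapply(active, function(cl) length(vocab[[cl]]) > 0, TRUE)]
  if (length(empty)) {
    abort(sprintf("empty vocabulary for active class(es): %s",
                  paste(empty, collapse = ", ")))
  }
  structure(list(n = as.integer(n), frac_history = frac_history,
                 mean_mentions = mean_mentions, vocab = vocab,
                 templates = templates, age_bands = age_bands,
                 genders = genders, diagnosis_codes = diagnosis_codes,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a gold-annotated synthetic corpus
#'
#' Fills sentence templates from the configured vocabularies and records
#' every inserted mention's character and token span at insertion time
#' (gold truth is never recovered by string search, so it can serve as an
#' independent reference when testing alignment). Seeded and fully
#' reproducible: the same config yields a byte-identical corpus.
#'
#' @param cfg A [generator_config()].
#' @param id_prefix Prefix for generated document ids.
#' @return A list with `corpus` (document tibble with metadata columns)
#'   and `gold` (mention tibble: `doc_id`, `class`, `surface`, `start`,
#'   `end`, `token_start`, `token_end`; spans 0-based half-open,
#'   non-overlapping, exactly matching the text).
#' @export
generate_gold_corpus <- function(cfg, id_prefix = "doc") {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    n_hist <- round(cfg$n * cfg$frac_history)
    types <- c(rep("medical_history", n_hist), rep("procedure", cfg$n - n_hist))
    classes <- names(cfg$mean_mentions)
    docs <- vector("list", cfg$n); golds <- vector("list", cfg$n)
    for (i in seq_len(cfg$n)) {
      id <- sprintf("%s_%05d", id_prefix, i)
      type <- types[i]
      counts <- stats::setNames(rpois(length(classes), cfg$mean_mentions), classes)
      # one sentence per mention, plus 1-2 filler sentences
      sent_cls <- rep(classes, counts)
      filler_key <- if (type == "medical_history") "filler_history" else "filler_procedure"
      sent_cls <- c(sent_cls, rep(filler_key, sample(1:2, 1)))
      sent_cls <- sample(sent_cls)

      words <- character(); m_cls <- character(); m_surf <- character()
      m_ts <- integer(); m_te <- integer()
      for (sc in sent_cls) {
        tmpl <- cfg$templates[[sc]][[sample(length(cfg$templates[[sc]]), 1)]]
        slot <- which(tmpl == paste0("{", sc, "}"))
        if (length(slot)) {
          surf <- sample(cfg$vocab[[sc]], 1)
          surf_toks <- strsplit(surf, " ", fixed = TRUE)[[1]]
          before <- tmpl[seq_len(slot - 1)]
          after <- if (slot < length(tmpl)) tmpl[(slot + 1):length(tmpl)] else character()
          m_ts <- c(m_ts, length(words) + length(before))       # 0-based
          m_te <- c(m_te, length(words) + length(before) + length(surf_toks))
          m_cls <- c(m_cls, sc); m_surf <- c(m_surf, surf)
          words <- c(words, before, surf_toks, after)
        } else {
          words <- c(words, tmpl)
        }
      }
      text <- paste(words, collapse = " ")
      docs[[i]] <- tibble::tibble(
        doc_id = id, doc_type = type,
        age_group = sample(cfg$age_bands, 1),
        gender = sample(cfg$genders, 1),
        diagnosis_code = sample(cfg$diagnosis_codes, 1),
        text = text)
      if (length(m_cls)) {
        # char offsets: word w (0-based) starts at sum(nchar(words[1:w])) + w
        wstart <- cumsum(c(0L, nchar(words) + 1L))
        golds[[i]] <- tibble::tibble(
          doc_id = id, class = m_cls, surface = m_surf,
          start = as.integer(wstart[m_ts + 1]),
          end = as.integer(wstart[m_te + 1] - 1L),
          token_start = m_ts, token_end = m_te)
      }
    }
    corpus <- dplyr::bind_rows(docs)
    gold <- dplyr::bind_rows(golds)
    if (nrow(gold) == 0) {
      gold <- tibble::tibble(doc_id = character(), class = character(),
                             surface = character(), start = integer(),
                             end = integer(), token_start = integer(),
                             token_end = integer())
    } else {
      gold <- dplyr::arrange(gold, .data$doc_id, .data$start)
    }
    list(corpus = corpus, gold = gold)
  })
}

#' Build a training pool with controlled verbatim and mutated copies
#'
#' Constructs the adversarial case an originality filter must catch: a
#' pool of "training" documents consisting of fresh documents (generated
#' from a disjoint background template set, so they share wording with
#' the corpus only through entity vocabularies) plus, for a fraction of
#' the corpus, copies whose tokens are independently substituted at a
#' given rate. Provenance records which pool document copies which corpus
#' document, giving ground truth for filter evaluation.
#'
#' @param corpus Corpus tibble to copy from.
#' @param copy_fraction Fraction of corpus documents copied into the pool.
#' @param mutation_rate Per-token substitution probability for copies
#'   (0 = verbatim).
#' @param seed Integer seed.
#' @param n_fresh Number of fresh background documents (default
#'   `nrow(corpus)`).
#' @return A list with `pool` (corpus tibble) and `provenance` (tibble
#'   `pool_id`, `source_id`, `kind` = `"fresh"`/`"copy"`,
#'   `mutation_rate`).
#' @export
make_training_pool <- function(corpus, copy_fraction = 0.5, mutation_rate = 0,
                               seed = 1L, n_fresh = NULL) {
  assert_corpus(corpus)
  if (copy_fraction < 0 || copy_fraction > 1) abort("`copy_fraction` must be in [0, 1]")
  if (mutation_rate < 0 || mutation_rate > 1) abort("`mutation_rate` must be in [0, 1]")
  n_fresh <- n_fresh %||% nrow(corpus)
  sub_vocab <- c("asendus", "sõna", "muudetud", "vahetatud", "teistsugune",
                 "juhuslik", "moonutus", "variatsioon")
  with_seed(seed, {
    fresh_cfg <- generator_config(n = n_fresh, seed = sample.int(2^30, 1),
                                  templates = background_templates())
    fresh <- generate_gold_corpus(fresh_cfg, id_prefix = "pool_fresh")$corpus
    n_copy <- round(copy_fraction * nrow(corpus))
    src_idx <- if (n_copy > 0) sort(sample(nrow(corpus), n_copy)) else integer()
    copies <- lapply(seq_along(src_idx), function(j) {
      src <- corpus[src_idx[j], ]
      toks <- strsplit(src$text, " ", fixed = TRUE)[[1]]
      mut <- runif(length(toks)) < mutation_rate
      if (any(mut)) toks[mut] <- sample(sub_vocab, sum(mut), replace = TRUE)
      dplyr::mutate(src, doc_id = sprintf("pool_copy_%05d", j),
                    text = paste(toks, collapse = " "))
    })
    pool <- dplyr::bind_rows(fresh, dplyr::bind_rows(copies))
    provenance <- dplyr::bind_rows(
      tibble::tibble(pool_id = fresh$doc_id, source_id = NA_character_,
                     kind = "fresh", mutation_rate = NA_real_),
      tibble::tibble(pool_id = sprintf("pool_copy_%05d", seq_along(src_idx)),
                     source_id = corpus$doc_id[src_idx], kind = "copy",
                     mutation_rate = mutation_rate))
    list(pool = pool, provenance = provenance)
  })
}
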