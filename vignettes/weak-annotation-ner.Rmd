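---
title: "Weakly supervised clinical NER from synthetic text: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised clinical NER from synthetic text: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weakner)
library(dplyr)
```

## The problem

Clinical free text is rich in drugs, procedures, diseases and lifestyle
facts, but training a named entity recognition (NER) model on it normally
requires expert annotation of sensitive records — doubly hard for
low-resource languages such as Estonian, where neither annotated corpora
nor domain-specific pretrained models exist. A privacy-preserving
alternative is a three-stage pipeline:

1. **Generate** synthetic clinical-style documents with a locally trained
   language model, so that no real record ever leaves the secure
   environment.
2. **Annotate** the synthetic documents with a large language model (LLM)
   that is asked, via a prompt, to list the entity mentions of each class
   as a JSON object.
3. **Train** a local downstream tagger on the weakly labeled synthetic
   corpus and apply it to real records on-site.

`weakner` implements the measurable machinery of that pipeline: the
originality filter that keeps leaked training text out of the synthetic
corpus, prompt construction and response parsing, the alignment of
reported surface strings to character spans and IOB2 token tags,
entity-level evaluation with Wilson confidence intervals, a downstream
dictionary tagger, and an experiment harness. Because the real clinical
corpus and the hosted commercial models are inherently private, the
package also ships a seeded synthetic-corpus generator with gold
annotations and mock annotators with a controllable noise model; these
stand in for the private components so every stage is testable
end-to-end.

## Originality filtering with a penalized LCS

A generative model trained on real records can emit verbatim or
near-verbatim copies of its training data. Exact-match screening misses
copies that differ by one word, and fixed-length n-gram screening
(e.g. 13-grams) is defeated by a single synonym substitution. The filter
here scores each generated text `x` against every training text by the
longest common subsequence (LCS) at the word-token level, takes the best
match, and normalizes by the length of `x`: 0 means unique, 1 means every
token of `x` appears in order in some training text.

On long texts, plain LCS rewards matches scattered across hundreds of
tokens. The penalized variant therefore subtracts, for each pair of
consecutive matched tokens, `min(gap / k, 1)`, where `gap` is the larger
of the number of tokens skipped in the two texts and `k` is the penalty
length. Adjacent matches cost nothing, so a contiguous verbatim copy is
never penalized; a gap of `k` or more forfeits a full matched token.
`k = 20` is the default: small enough to dissolve scattered matches,
large enough not to split ordinary paraphrases.

Two design points deserve a note:

* **The penalized score is maximized by its own dynamic program** over
  match pairs, rather than applied post hoc to one arbitrary backtrace of
  the classic LCS table, whose tie-breaking is implementation-defined.
  `mode = "classic_path"` provides the post-hoc variant (ties broken
  toward contiguity) for comparison; it can only score lower.
* **`k = 1` approximates, but does not equal, longest-run matching.**
  Under the subtract-one rule a chain of two long contiguous runs can
  out-score the single longest run, so the often-stated equivalence with
  "longest common n-gram" holds only approximately.
  [longest_common_run()] is provided as the exact diagnostic companion.

The filter threshold is deliberately a required argument: it trades
privacy (remove more) against corpus yield (keep more), and no default
can make that call. The penalized score is computed against the training
text with the best *plain* LCS score — the candidate-selection step and
the scoring step are decoupled, which keeps the scan over a large
training pool cheap; re-maximizing the penalized score over all training
texts would only matter when two candidates tie on plain LCS but differ
in scatter.

Both dynamic programs are implemented in C++ (via Rcpp): scoring is
quadratic per text pair and runs over every generated-by-training pair,
so this is where the field's packages would reach for compiled code too.

## Prompts, the JSON contract, and parsing

Four prompt styles are reproduced: a zero-shot instruction; the same
instruction in Estonian (with Estonian JSON keys
RAVIM/PROTSEDUUR/HAIGUS/SUITS); a variant with per-class annotation
guidelines; and a few-shot variant carrying five example input/output
pairs. The shipped few-shot examples are synthetic (the original pairs
are not public); both the guidelines and the examples are replaceable
per [prompt_spec()].

LLMs are unreliable at reporting character indexes, so the contract asks
only for surface strings per class, as a JSON object. Hosted models wrap
JSON in prose, so the parser extracts the first balanced-brace candidate
(scanned left to right, string-aware) that parses as strict JSON; a
response counts as parsed when at least one configured class key is
present. Parsing never throws — failure is data (`parsed = FALSE`),
which is what the parsed-response accounting in evaluation reports
needs. A reported surface that does not occur in the document is kept at
this stage and dropped (with a logged reason) at alignment, mirroring
the pipeline order of span recovery.

## From surfaces to IOB2 tags

Alignment searches each reported surface in the source text as a
contiguous whole-token sequence, after whitespace normalization,
case-insensitively by default. A class-to-strings response carries no
per-occurrence information, so *every* occurrence is annotated — the
standard distant-supervision choice; both the case policy and the
all-occurrences policy are switches. Overlaps (e.g. one surface nested
in another, or one span claimed by two classes) cannot be expressed in
token tags, so they are resolved greedily and deterministically: longer
span wins, then earlier start, then the fixed class priority
DRUG > PROCEDURE > DISEASE > SMOKING (specificity first). Tokens
overlapping a mention's span get `B-`/`I-` tags; a span ending mid-token
claims the whole token. The result is always strict IOB2.

## Evaluation

Metrics are entity-level: a true positive is an exact match of class and
token span. Chunk extraction follows the default *lenient* convention of
the standard sequence-evaluation library — a chunk also starts at an
`I-X` that follows `O` or a different class — so evaluations of
possibly ill-formed taggings match what practitioners report.
Zero-denominator precision/recall/F1 are reported as 0, again following
that library's default. Precision and recall carry Wilson score 95%
confidence intervals computed from chunk counts (successes = exact
matches; trials = predicted or gold chunks); the Wilson interval keeps
honest coverage for rare classes such as smoking status. Interannotator
agreement is pairwise entity-level F1 with one side taken as reference;
F1 is symmetric under swapping the annotators.

The test suite gates the evaluator against an independently coded
transcription of the reference chunking scheme (a per-token state
machine) on hundreds of random tag-pair corpora, to six decimals.

## The synthetic generator and what it does (not) emulate

The generator assembles documents of two types — medical histories
(two thirds by default) and procedure notes — from sentence templates
with typed slots filled from invented pseudo-Estonian vocabularies.
Metadata headers (13 five-year age bands spanning 15–80, gender, an
ICD-10 code defaulting to C50) emulate the conditioning header of the
text generator it stands in for. Per document, each class's mention
count is Poisson with means 0.438 / 1.286 / 0.644 / 0.116 (drug /
procedure / disease / smoking), the class mix of a 500-document
expert-annotated reference set (219 / 643 / 322 / 58 mentions). Gold
spans are recorded at insertion time, never recovered by search, so the
generator is a valid independent reference for alignment tests. Entity
vocabularies are token-disjoint from template wording, making the
zero-noise pipeline exactly invertible.

What it does **not** emulate: real lexical diversity and ambiguity
(shorthand, inflection, misspellings), contextual cues, mentions unseen
in any dictionary, or annotator disagreement about span boundaries.
Consequently a passing zero-noise identity test certifies the plumbing
(annotate → align → tag → extract is lossless), not clinical
performance; absolute scores on synthetic corpora are optimistic and are
not comparable to scores on real records.

For leakage tests, [make_training_pool()] builds a provenance-labelled
pool: verbatim or token-mutated copies of corpus documents plus fresh
documents generated from a disjoint background template set. The
disjoint wording makes "fresh" operational: a fresh document can overlap
a corpus document only through entity vocabulary, which stays far below
any sensible filter threshold.

## Annotation noise model

[noise_config()] has four rates, chosen to span the observed error modes
of real LLM annotators: `drop_prob` (missed mentions), `spurious_prob`
(invented mentions, drawn as random 1–2-word snippets of the document),
`boundary_shift_prob` (one-token truncation/extension), and
`garble_prob` (whole response unparseable). Each document's perturbation
is seeded from the configuration seed and the document id, so results
are reproducible and independent of processing order. The named
profiles in [experiment_config()] (`perfect`, `gpt4_like`,
`weak_local`) are illustrative quality tiers — a strong hosted model
drops about a third of mentions and garbles ~1% of responses; a weak
local model drops most mentions and fails to parse ~9% — and are
documentation aids, not calibrated reproductions of any specific model.

## Downstream tagger

The downstream model is a dictionary (gazetteer) tagger: chunk surfaces
are counted per class from the weak labels, each surface keeps its
majority class (ties to the priority order), surfaces below `min_count`
are dropped, and tagging is a deterministic leftmost-longest scan. This
is a transparent, CPU-only stand-in for transformer fine-tuning, which
is out of scope here; the CoNLL TSV export keeps the fine-tuning route
open externally. A dictionary cannot use context, so it measures exactly
how much of the task the weak labels' surface vocabulary solves.

Noisy weak labels occasionally tag common words; with enough data those
recur and pass any absolute `min_count`. The tagger therefore offers an
occurrence-confidence floor (`min_confidence`): a surface is kept only
if it was annotated in at least that fraction of its occurrences in the
training text. Genuine entity surfaces are annotated at most of their
occurrences (≈ 1 − drop rate), while a spuriously tagged common word is
annotated at a vanishing fraction of its occurrences, so the floor is
scale-invariant. The experiment harness uses `min_count = 2` with
`min_confidence = 0.25`; the bare [train_surface_tagger()] defaults to
the permissive `min_count = 1`, `min_confidence = 0` so that the
perfect-label identity property holds exactly.

## Experiment harness and problem sizes

[run_learning_curve()] draws training batches at a 2:1
history:procedure ratio for each size on the ladder (default 250, 500,
750, 1000, 2000, 4000 from a 4200-document corpus), annotates with the
chosen noise profile, aligns, holds out 15% of each batch for
validation, trains the tagger and evaluates on a held-out gold
evaluation corpus of 300 documents, half per document type, generated
from a separate seed and asserted disjoint from every batch by id. All
randomness derives from the experiment seed, and two runs of the same
configuration are byte-identical. [run_prompt_comparison()] evaluates
one annotator under each of the four prompt styles and reports the
per-class table (precision and recall with Wilson CIs, F1,
parsed-response count).

The test suite exercises these sizes: enumeration oracles run on
hundreds of random token sequences of length ≤ 8 (exhaustive chain
enumeration is exponential, so oracle lengths stay small while the
implementation is also checked for scale on longer sequences via
invariants); the end-to-end identity and noise-recovery checks use
500-document corpora (≥ 1000 gold mentions, so binomial checks at
3 standard deviations are sharp); the reproducibility check runs the
full default ladder twice.

## Numerical choices and degenerate inputs

* Character and token spans are 0-based half-open everywhere; all
  serialization is UTF-8.
* Tokenization splits on whitespace and peels leading/trailing
  punctuation into their own tokens; interior punctuation stays. It is
  deterministic, idempotent on token surfaces, and shared by every
  module, which is what makes word-level LCS, span alignment and
  chunk-level evaluation commensurable.
* LCS and penalized scores of an empty generated text are an error (the
  normalization is undefined); an empty training text scores 0.
* Wilson intervals require at least one trial; evaluation rows with zero
  predicted (or gold) chunks report a point estimate of 0 with the
  uninformative interval [0, 1].
* Best-match ties go to the first training text in corpus order;
  dictionary-surface class ties go to the fixed class priority; both are
  chosen for determinism, not semantics.
* The training/validation split rounds the validation share to the
  nearest document and clamps it to leave at least one document on each
  side.

## Known limitations

* The dictionary tagger cannot generalize beyond surfaces seen in the
  weak labels; its learning curves saturate once the vocabulary is
  covered, earlier than a contextual model would.
* Alignment is exact (token-boundary, whitespace-normalized,
  case-folded); no fuzzy matching, so inflected variants of a reported
  surface are not found — visible in the alignment log as `not_found`.
* Overlapping and nested entities are out of scope by construction of
  the IOB2 target representation.
* Synthetic corpora are templated: they validate mechanics and
  statistical behavior of the pipeline, not clinical realism; absolute
  metric values on them should never be quoted as model performance on
  real records.
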