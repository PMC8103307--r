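---
title: "Methods: hybrid family-history extraction in famhx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid family-history extraction in famhx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famhx)
```

## Problem and data model

`famhx` extracts structured family-history (FH) information from
free-text clinical notes: mentions of family members, observations
(diseases) and living-status phrases, and the two relation types that
connect them (family member–living status, scored on an ordinal 0/2/4
scale, and family member–observation, flagged for negation).

All coordinates are 0-based, half-open character offsets into the
original note, chosen for internal consistency: a `Token`, `Sentence`
or `Entity` span `[start, end)` always satisfies
`text == substring(doc_text, start + 1, end)`, and this identity is
asserted across the test suite. Annotation files use a pinned
tab-separated dialect (see `?write_annotations`) that stores
document-level tuples; it is a declared stand-in, since shared-task
interchange formats vary and offsets are not needed for tuple-level
scoring.

Preprocessing is deterministic: sentences split at `.`/`!`/`?` before
whitespace and at newlines; tokens are maximal alphabetic or numeric
runs, possessive `'s`, or single punctuation marks. Part-of-speech
tags come from a small hand-built lexicon-plus-suffix tagger over the
Penn Treebank tagset. It is not a general-purpose tagger; it is built
to make the distinctions the rules need — reliably separating noun
uses of kin terms (`NN`, `NNP`, `NNS`) from verb uses ("they will
*father* a child"), which it does with a modal/infinitive context
rule. No installed R package provides clinical POS tagging, and a
statistical tagger would add nondeterminism without helping the
downstream rules.

## Entity identification

Two routes produce entity candidates, mirroring the two submitted
system styles (`use_rule_fm` in `pipeline_config()`):

**Rule-based family members.** Every token whose lowercase form is in
the kin dictionary and whose POS tag is a noun becomes a
single-token `FamilyMember` mention. Excluded kin (spouse, nephew,
niece) are absent from the dictionary by construction.

**Recurrent BIO tagging.** Sentences are encoded with BIO tags over
the three categories (the tagger's alphabet deliberately includes
`LivingStatus`; treating all three categories uniformly in one
sequence model is the simplest consistent reading of the task).
The tagger is a bidirectional Elman-style recurrent network written in
RcppArmadillo; per token it concatenates:

* a trainable word embedding (default 50 dimensions, vocabulary from
  the training corpus, index 1 reserved for unknown words);
* fixed "provider" features: by default a 20-bucket hashed
  character-trigram vector (L2-normalized counts), a deterministic,
  vocabulary-free channel that gives sub-word generalization; a
  `word_vector_provider()` can add pretrained vectors in the word2vec
  text dialect, but nothing in the package requires one;
* one trainable 10-dimensional embedding per auxiliary concept
  channel (below).

Defaults in `tagger_config()`: 30 epochs, Nadam (adaptive moments
with Nesterov momentum, step size 0.01), 50% dropout applied as a
per-sentence mask on the recurrent outputs feeding the softmax layer,
32 hidden units per direction. Epochs, optimizer family and the
dropout rate are the regime the ensemble design assumes; hidden width
and embedding sizes are declared desk-scale defaults (the method does
not pin them), chosen so that training hundreds of synthetic
documents takes seconds on one CPU. Training is sentence-level SGD
with per-sentence gradient computation (backpropagation through time)
and masked empty sentences; it is exactly reproducible for a fixed
seed and intentionally *not* reproducible across seeds (weight
initialization and shuffling differ), which is the property the
voting ensemble exploits.

**External concept channels.** An `fh_concept_tagger` is any function
from a document to concept mentions. Real clinical concept systems
are license-restricted, so the package ships dictionary-based mocks:
one emits UMLS-style semantic types over the disease vocabulary (plus
a deliberately unaligned decoy type), the other emits problem
concepts directly. Mentions pass through a semantic-type map built
from training data: for each type, the fraction of its mentions
sharing at least one character with a gold observation; types with
probability *strictly greater than* 0.70 are kept (the filter is a
strict inequality — "over 70%" — so a type at exactly 0.70 is
dropped). Kept mentions are re-encoded as `B-`/`I-Observation` BIO
channels. Alignment is defined as any character overlap; the method
does not define "aligned" more precisely, and one shared character is
the weakest contract that is still deterministic.

## Voting ensemble

`train_ensemble()` trains N taggers (default 10) identical up to
seed; `collect_votes()` tallies exact (document, category, span)
candidates; `rank_models()` ranks members by mean pairwise F1 against
the other members (F1 is symmetric under swapping system and
reference, so the matrix is symmetric; ties break by model index).
`resolve_entities()` keeps candidates with `votes >= threshold` and
resolves overlapping same-category survivors by: more votes first;
then the candidate whose best-ranked voter outranks the other's; then
the earlier span.

Two interpretation points were genuinely open and are fixed as
follows. The threshold is *inclusive* (`>=`): a sweep up to threshold
N of N models is only meaningful if a unanimous candidate can survive
at threshold N. "Produced by the higher-ranking model" is read as
comparing the best (minimum) rank among each candidate's voters,
which is well defined for any vote pattern. The ranking is computed
on whatever prediction set is supplied — the package does not pin
training-time versus test-time ranking. Resolution is implemented as
greedy acceptance in preference order; the test suite checks it
against an independent eliminate-the-loser oracle on fuzzed vote
tables. Cross-category overlaps are left alone.

## Relation extraction

Candidate pairs cross every family member with every living-status
and observation mention of the same document. Training labels come
from gold tuples; negative pairs separated by a newline are dropped,
and the same pruning is applied at prediction time — the method
specifies the filter for training negatives only, but pruning test
pairs keeps the input distribution consistent with training, at the
cost of never finding cross-line relations (a documented limitation
of the newline heuristic itself).

Features are sparse indicators hashed into `2^18` dimensions
(FNV-1a): words in each mention, exactly 7 context tokens on each
side (truncated at document edges), words between the pair, and the
count of family members strictly between the pair, bucketed
categorically at 0/1/2/3+. Two binary online-gradient-descent
logistic classifiers (one per relation type) train for 100 passes
with per-example updates, learning rate `0.5 / sqrt(t)` over the
running update count, and seeded shuffling per pass — the documented
defaults of the online-learning library family this emulates; exact
replication of any particular library is not contractual. The
analytic gradient is finite-difference checked to 1e-6 relative
error in the tests. The decision threshold is 0.5 with ties counted
as related (so a zero-weight model predicts everything related — the
recall-preserving degenerate behavior).

Positive pairs are assembled into relations with rule-based
attributes: the living-status score of the phrase (each related
living-status mention is scored independently; when one family
member has several living-status mentions the method does not say
whether scores attach per relation or per entity, and per-relation
is the information-preserving choice), and ConText-style negation
over the observation's sentence. Duplicate tuples collapse.

## Attribute heuristics

* **Normalization**: lowercase, strip digits and number words, look
  up the kin dictionary. A preceding kin token modifies the target
  only in possessive (`mother's sister`) or subject-of-have
  (`mother has [a] sister`) position; the composition table then maps
  (Mother, Sister) to Aunt, (Father, Father) to Grandfather, (Uncle,
  Daughter) to Cousin, and so on. Restricting to those two syntactic
  positions prevents coordination ("Mother and father…") from
  composing. Terms outside the dictionary are surfaced as
  unnormalizable rather than guessed, and such mentions cannot enter
  document-level tuples.
* **Family side**: first-degree relatives never carry a side. For
  second-degree relatives, cues are searched inside the mention, then
  across the sentence; no cue means `NA` (the method defines no other
  fallback). Cue matching is lowercase substring with one refinement:
  the match must start at a word boundary, so the Maternal cue
  "mother's" cannot fire inside "grandmother's". If both sides' cues
  appear, Paternal wins as a fixed tie-break.
* **Living status**: not-alive cues are checked *before* healthy cues
  (forced by the if/else ordering of the rule), so a phrase
  containing both scores 0; no cue scores 2.
* **Negation**: trigger phrases matched as token sequences; each
  opens a forward scope to the sentence end, a termination
  conjunction (but/however/although) or a 6-token window, whichever
  comes first. The scope length and termination set are conventional
  ConText-style defaults, fixed here because the underlying
  algorithm's configuration is not part of the contract. The shipped
  trigger and cue inventories (YAML under `inst/extdata/`,
  overridable) are supersets of the documented examples and are meant
  to be edited.

## Evaluation

Scoring is micro-averaged precision/recall/F1 in percent with
2-decimal rounding in reports, zero by convention on empty
denominators. Matching is document-level and tuple-based: family
members on (document, normalized name, side), living-status relations
on (document, family member tuple, score), observation matching by at
least one shared lowercase alphanumeric word, assigned greedily
one-to-one in document order — the official assignment policy is not
published, and greedy-in-order is the simplest deterministic choice.
Tuples are deduplicated at the full-attribute level even when an
attribute is ignored by a `match_spec()`, which is what makes
attribute ablation monotone (ignoring an attribute can only add
matches); a greedy word-overlap assignment can in principle lose a
match when ablation merges matching groups with asymmetric overlaps,
but this requires adversarial observation vocabularies and does not
arise in the tested domains. Subtask-1 entity scoring covers family
members and observations only, following the task definition (the
source reporting also lists a living-status row under subtask 1;
that labeling is noted as a discrepancy and not reproduced).
`attribute_accuracy()` evaluates each heuristic on gold concepts, and
`sweep_thresholds()` re-resolves and re-scores the ensemble at every
threshold.

## Synthetic corpus

The real FH shared-task corpora are access-restricted, so
`generate_corpus()` produces template-based notes with gold
character-offset annotations that are exact by construction (a
language-model generator could not guarantee offsets). Templates
cover the phenomena each rule needs: possessives and numeric
modifiers, nested kinship, paternal/maternal cues, all three
living-status score classes, negation triggers with scope
terminators, unrelated observations, and entity pairs split across a
newline. The disease vocabulary is a fixed 32-term list — enough
lexical variety to train the tagger without memorizing a handful of
strings. Rates are configurable; defaults are one-time choices meant
to resemble a real FH training corpus: about 23% of observations
participate in no relation (matching a corpus with roughly
978 observation entities and 753 observation relations), a 15%
negation rate among related observations, 60% side-cue coverage for
second-degree relatives, and 10% each for numeric modifiers, nested
kinship and cross-line pairs. Generation uses an explicit integer
seed and restores the caller's RNG state.

What the generator does *not* emulate — misspellings,
de-identification artifacts, section headers, coreference across
sentences, kin terms whose literal reading differs from the true
relationship ("brother" meaning the parent's brother) — bounds what
green tests mean: passing the recovery bars shows the pipeline's
machinery is correct and well-calibrated on distribution-matched
data, not that it reaches any particular accuracy on real clinical
notes, where published systems of this design lose 15–30 F1 points
to such phenomena.

## Numerical and degenerate-input choices

* Malformed BIO (leading `I-`) is repaired to `B-` rather than
  dropped — recall-preserving and standard practice.
* Unseen tokens map to a reserved unknown-embedding index; empty
  sentences produce empty tag sequences; prediction never errors on
  out-of-vocabulary input.
* Softmax is computed with max-subtraction; training loss clips
  probabilities at 1e-12 before the log.
* `gen_config()` validates probabilities; `fh_entities()` /
  `fh_relations()` validate enums and the 0/2/4 score set at
  construction, and the annotation reader reports the offending line
  number.
* Problem sizes in the test suite are the package's own calibration:
  property suites fuzz a few hundred cases per contract; recovery
  tests train one tagger per seed on 200 generated documents and
  score 50 held-out documents, averaged over 3 seeds. These sizes
  make the whole suite run in a few minutes on one CPU while keeping
  the stochastic bars (held-out entity F1 at least 0.90, end-to-end
  relation F1 at least 0.85) meaningful.

## Known limitations

* Cross-sentence and cross-line relations are invisible to the
  classifier by design of the newline pruning.
* The negation model covers the negation dimension only (no
  uncertainty or experiencer attributes) and only forward scopes.
* The POS tagger and concept taggers are deliberately small,
  deterministic stand-ins behind pluggable interfaces; swapping in
  production components changes tagging quality but not any
  contract in this package.
* Statistical significance testing between system variants is out of
  scope (the comparison procedure is not specified by the method
  this package implements).
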