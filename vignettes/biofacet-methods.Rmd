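---
title: "Event annotation and faceted literature search: models and design"
author: "biofacet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event annotation and faceted literature search: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofacet)
```

## The problem

Keyword search over PubMed-scale literature returns thousands of abstracts
sorted by date. A researcher asking a focused question — say, which genes
co-occur with cholesterol metabolism and a particular disease — has to read
them all. The remedy implemented here couples *information extraction* with
*faceted retrieval*: every abstract is annotated offline with entity
mentions (genes/proteins, chemicals, diseases) and with the biomolecular
*event types* its sentences describe; those annotations become facet fields
of a full-text index, so a free-text query can be narrowed click by click
("gene: hepatic lipase", then "disease: hyperthyroidism") with exact result
counts shown for every candidate refinement.

The package implements the full desk-scale pipeline: XML ingestion and
sentence splitting (`read_medline_xml()`, `split_sentences()`), dictionary
entity tagging (`annotate_sentence()`), sentence-level event classification
(`train_nb()`, `train_nb_em()`, `train_maxent()`), trigger-phrase tagging
with a linear-chain CRF (`train_crf()`, `viterbi_tag()`), span evaluation
(`span_prf()`, `coverage()`), the faceted index (`build_index()`,
`search_index()`, `tag_cloud()`, `autocomplete()`), and a deterministic
synthetic-corpus generator (`generate_corpus()`) that makes every stage
testable without downloading any external corpus.

## Event classes and features

Sentences are classified into nine event types (declaration order matters —
classifier ties and the BIO label alphabet follow it):
Phosphorylation, Protein_catabolism, Gene_expression, Localization,
Transcription, Binding, Regulation, Positive_regulation,
Negative_regulation.

Sentence features are TF-IDF bags of words. Tokens are lowercased; tokens
whose first character is not a letter are discarded (so a numeric artefact
like "−300" vanishes while a symbol like "p55" stays). With $N$ training
sentences and $df(t)$ the number containing token $t$,

$$ w(t) \;=\; tf(t)\,\ln\!\frac{N}{df(t)}, $$

with no smoothing of the idf term — a token present in every sentence gets
weight zero. Each vector is normalised to unit Euclidean length; the
pre-normalisation norm is retained as an attribute (see below).

Two optional *boosts* strengthen tokens that demarcate event types:
all gene tokens of a sentence are removed and their summed weight is pooled
into a single feature named `protein`, which is then multiplied by 2.0; and
tokens found in a per-class trigger-word lexicon (built from training data,
stop-words removed, ordered by descending class frequency with
lexicographic tie-break) are multiplied by 2.0. The vector is re-normalised
afterwards, so boosting with both factors at 1.0 is the identity.

## Classifiers

**Multinomial naive Bayes** (single label; multi-label training sentences
contribute their first label only). Class priors and word probabilities use
Laplace (+1) smoothing. A deliberate design point: the +1 pseudo-count is a
*count*, so the evidence it is added to must live on a count scale.
Unit-normalised vectors (all entries below 1) would be drowned by it and
the posterior would collapse onto the class priors. The estimator therefore
consumes each sentence's tf-idf mass on its natural (pre-normalisation)
scale, restored from the stored norm; the unit vector remains the
representation used everywhere else. Prediction is the maximum-posterior
class, ties resolved by declaration order; an empty feature vector falls
back to the prior alone.

**Semi-supervised EM.** Naive Bayes is initialised on the labelled set
(over the vocabulary of the whole corpus), then alternates an E-step
(class responsibilities of unlabelled sentences) and an M-step
(re-estimation from one-hot plus fractional counts). Because the M-step
applies the same +1 smoothing, it maximises a *posterior*, and the quantity
that is provably non-decreasing is the MAP objective — observed-data
log-likelihood plus the matching Dirichlet log-prior. That is the quantity
`train_nb_em()` traces and the tests assert on; the raw likelihood has no
such guarantee under MAP updates. Iteration stops when the objective
improves by less than `tol` (default 1e-6) or after `max_iter` (default
50). Multi-label output emits every class with posterior at least
$\max(1/9, \text{top}/2)$, so at least one label is always produced.

**Maximum entropy** (multinomial logistic regression), trained by L-BFGS on
the L2-penalised conditional log-likelihood with analytic gradients,
gradient-norm tolerance 1e-5, at most 200 iterations, deterministic zero
initialisation. The Gaussian prior has variance $\sigma^2 = 10$ and is
applied to the full parameter vector, intercepts included. The variance was
a genuinely open choice: with $\sigma^2 = 1$ a class holding only a couple
of percent of the training data can never attain positive margin on a
token unique to it — on the synthetic preset below, training accuracy
plateaus near 0.99 after full convergence however long the optimiser runs.
$\sigma^2 = 10$ (the same prior variance the CRF uses) removes that
ceiling while still regularising; we treat one shared prior across the
discriminative models as the cleaner design.

## Trigger tagging with a linear-chain CRF

Trigger phrases are tagged over a 19-label BIO alphabet (`O` first, then
`B-`/`I-` per event type). Per-token observations comprise the token
identity, 17 declared orthographic indicator regexes (case shapes, digit
shapes, hyphen positions, punctuation, Roman numerals, spelled Greek
letters — the exact list is data, `orthographic_features()`), 3/4-gram
prefixes and suffixes computed only when the token is long enough,
membership in hand-prepared lexicons (a Greek-letter list ships with the
package; a trigger dictionary can be supplied), and copies of the
neighbouring tokens' features at offsets −1/+1 with boundary markers.

The model is a conditionally trained linear chain: emission weights per
(feature, label) and transition weights per label pair, with structurally
forbidden transitions (`I-T` only after `B-T`/`I-T`; no initial `I-T`)
excluded by $-\infty$ scores rather than learned. Training maximises the
L2-penalised conditional log-likelihood ($\sigma^2 = 10$) by L-BFGS with
exact forward–backward gradients, zero-initialised and therefore fully
deterministic; the forward–backward/Viterbi recursions are compiled (Rcpp),
and `crf_log_partition()` / `crf_path_score()` expose them so tests can
compare against exhaustive path enumeration. Viterbi ties resolve to the
first label in declaration order, which makes the all-zero model decode to
all-`O`.

## Evaluation protocols

*Sentence level*: a prediction is correct iff it equals the modal gold
event of the sentence; when several events tie at the maximal multiplicity
the prediction is correct if it matches any of them. Per-class counts
derive from the correctness-resolved confusion; for a wrong prediction the
false negative is charged to the first modal gold event in declaration
order (the tie had to be broken somehow; this rule is deterministic and
documented).

*Span level*: exact boundary matching requires identical token interval and
event type; soft matching allows each boundary to move by at most one
token. Matching is greedy per sentence (gold spans in order, first
unmatched matching prediction) — deterministic and auditable; on instances
whose soft windows do not overlap it coincides with optimal bipartite
matching, which is what the tests check. Coverage is the percentage of
gold spans matched; soft coverage can never be below exact coverage.
Reports give per-class precision/recall/F1 in percent with an unweighted
(macro) average row — the table layout `format_class_report()` prints is
the same shape used for externally annotated data.

## The faceted index

Documents enter the index with their facet fields (genes, diseases,
drugs/chemicals, cell lines, event types — the field list is
`FACET_FIELDS`). Multi-term queries use AND semantics and facet filters are
conjunctive, which is what makes refinement monotone: adding a filter can
never grow the result set. Ranking is TF-IDF cosine between query and
title+abstract with doc-id tie-break. Facet counts are computed over the
*complete* candidate set, never a sample — this underwrites the
click-through contract the tests enforce: refining by any displayed facet
value returns exactly the displayed count. Tag clouds take the top-k facet
values by count (ties lexicographic) weighted relative to the top value;
autocomplete matches the lowercased prefix against text terms and facet
values, ordered by collection frequency. An empty query with no filters is
browsing mode and returns the whole collection.

## The synthetic corpus

`generate_corpus()` builds abstracts whose sentences are synthetic token
strings: a capitalised sentence opener, background tokens, zero to two
planted event-trigger words (classes drawn with the 9-class imbalance of
the shared-task test set — Positive_regulation most frequent, 220:17
against Protein_catabolism at the extremes), and entity surfaces from
generated gene/chemical/disease lexicons at recorded character offsets.
Every gold artefact (labels, trigger token spans, entity spans) is recorded
at generation time, and the corpus is emitted in the exact input formats of
every other module. A fixed seed fully determines the output.

The `genia-like-small` preset mimics, at one-tenth scale, a standard
event-annotated corpus: 80 training / 15 development / 26 test abstracts at
roughly 9.4 sentences each.

Design of the background vocabulary was a genuine decision. Because the
generator's stated purpose is *diagnostic* — classifiers under test are
bag-of-words learners, and statistical mimicry of real token distributions
is a non-goal — the background is 60 words drawn uniformly, each therefore
frequent enough (hundreds of occurrences) that its class-conditional
distribution is estimated accurately and contributes almost nothing to any
class decision, while idf automatically discounts it. An earlier candidate
design with a few hundred background words put most of them in the 5–30
occurrence range, where their class assignments are pure sampling noise
amplified by idf; that noise, not trigger separability, then dominated
classifier error. In disjoint-trigger mode each event class keeps trigger
words unique to it, which is what licenses the parameter-recovery tests
(naive Bayes test accuracy, CRF span F1, MaxEnt separable training
accuracy).

What passing these tests shows — and does not. They establish that the
estimators, decoders and index are *correct*: they recover structure that
is genuinely present, match brute-force oracles, and respect their
invariants. They do not establish robustness to real biomedical text,
where triggers are ambiguous ("expression of" may or may not mark
Gene_expression), entity mentions correlate with events, and boundaries
are fuzzy; scoring against a real annotated corpus requires supplying that
corpus to the evaluation harness.

## Numerical choices and degenerate inputs

* idf is $\ln(N/df)$ without +1; a document is a sentence.
* All classifier/CRF optimisations initialise at zero and are
  deterministic; stochastic routines (the generator, property tests) take
  explicit seeds, default 17.
* Ties: classifier posteriors and Viterbi break ties by declaration order;
  trigger-lexicon and tag-cloud orderings break count ties
  lexicographically; greedy span matching is first-come.
* Empty inputs: an empty abstract yields no sentences; a sentence with no
  lexicon hits yields no mentions; an empty feature vector predicts from
  the prior; an empty result set yields an empty tag cloud.
* Sentence splitting is rule-based (terminal `.!?` followed by whitespace
  and an upper-case letter or digit) with a shipped abbreviation whitelist
  ("E.", "Fig.", "et al.", …); offsets are 0-based half-open in Unicode
  code points and all input text is normalised to UTF-8 NFC.
* Entity matching is greedy longest-match over token n-grams (n ≤ 6) with
  class priority gene > dna > rna > cell_line > cell_type > chemical >
  disease as the tie-break at equal length; surfaces of four characters or
  fewer match case-exactly (protecting short symbols like p53), longer
  surfaces case-insensitively.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the parameter-recovery
studies on the `genia-like-small` preset over 10 seeds, with the CRF
trained for 20 L-BFGS iterations — on this separable corpus the objective
is already flat there, and the span F1 it reaches equals the
fully-converged value on every seed we examined. Oracle comparisons use
sequences of at most five tokens (exhaustive enumeration over up to
$19^5$ paths) and corpora of at most 100 documents (linear scans). The
walkthrough study uses a 40-document corpus.

## Known limitations

* Dictionary NER only: no statistical entity tagger is trained, and no
  normalisation to database identifiers is attempted (mentions carry the
  lexicon's canonical id verbatim).
* The part-of-speech feature variant is declared but unimplemented (no POS
  tagger dependency).
* The single-label reduction (first label wins) loses information for
  multi-label sentences in NB/MaxEnt training.
* Greedy span matching is not globally optimal when soft windows of
  several gold spans overlap; the tests restrict the optimality claim to
  non-ambiguous instances.
* The index is in-memory with a JSON persistence layout; it targets
  desk-scale collections, not distributed deployments.
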