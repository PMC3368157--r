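# biofacet

Faceted search and biomolecular event annotation over biomedical abstracts,
in R.

A plain keyword search over the biomedical literature returns thousands of
abstracts with no way to drill down. `biofacet` implements the alternative:
annotate every abstract offline — dictionary-tagged entity mentions
(genes/proteins, chemicals/drugs, diseases) and the nine biomolecular event
types its sentences describe (Gene_expression, Transcription,
Protein_catabolism, Phosphorylation, Localization, Binding, Regulation,
Positive_regulation, Negative_regulation) — then serve the collection
through a faceted full-text index in which every candidate refinement is
shown with its exact result count, so a query narrows click by click
(*cholesterol* → gene: *hepatic lipase* → disease: *hyperthyroidism*)
without restarting the search.

It is aimed at text-mining researchers and tool builders who want a
self-contained, fully testable reference pipeline: every component is pure
R (plus compiled CRF recursions), every stage has an oracle-backed test,
and a deterministic synthetic-corpus generator stands in for corpora that
cannot be redistributed.

## What is inside

| Stage | Functions | Method |
|---|---|---|
| Ingestion | `read_medline_xml`, `split_sentences`, `store_documents` | Medline-style XML (plain/gz), rule-based sentence splitter with abbreviation whitelist, token-indexed store |
| Entity tagging | `load_lexicon`, `annotate_sentence`, `annotate_corpus` | greedy longest-match dictionary tagging over token n-grams, class-priority tie-breaks |
| Event classification | `train_nb`, `train_nb_em`, `train_maxent` | TF-IDF features with gene/trigger boosting; multinomial naive Bayes, semi-supervised EM, L2-penalised multinomial logistic regression |
| Trigger tagging | `extract_features`, `train_crf`, `viterbi_tag`, `decode_spans` | linear-chain CRF over 19 BIO labels, orthographic/affix/lexicon features, exact forward–backward training |
| Evaluation | `eval_single_label`, `span_prf`, `coverage` | modal-event sentence protocol; exact and 1-word-window (soft) span boundary matching; per-class P/R/F1 with macro average |
| Faceted search | `build_index`, `search_index`, `refine`, `tag_cloud`, `autocomplete` | conjunctive AND retrieval, TF-IDF cosine ranking, complete facet counts, count-normalised tag clouds, prefix autocomplete |
| Synthetic data | `generate_corpus`, `scale_preset`, `write_corpus_files` | seeded generator of abstracts with planted triggers, entities and gold spans, emitted in every module's input format |

The sentence representation is TF-IDF with idf $= \ln(N/df)$ over
sentences, L2-normalised; boosting pools gene tokens into a single
`protein` feature (×2.0) and multiplies trigger-lexicon tokens (×2.0). The
CRF maximises the L2-penalised conditional log-likelihood
$\sum_i \log p_\lambda(y_i \mid x_i) - \lVert\lambda\rVert^2 / 2\sigma^2$
with $\sigma^2 = 10$, decoded by Viterbi with structurally forbidden BIO
transitions.

## Worked example

```r
library(biofacet)

co <- generate_corpus(scale_preset("genia-like-small", seed = 17))
#> <synthetic_corpus> 121 docs, 1158 sentences, 920 labelled

train <- corpus_split(co, "train"); test <- corpus_split(co, "test")
nb <- train_nb(train$labeled, features = "bow+gene+trigger")
mean(vapply(test$labeled, function(r) predict_nb(nb, r) %in% r$labels, logical(1)))
#> NB test accuracy: 0.985

lex  <- c(crf_default_lexicons(), list(trigger = tolower(unlist(co$trigger_vocab))))
seqs <- lapply(train$bio, function(r) list(obs = extract_features(r$tokens, lex),
                                           labels = r$labels))
crf  <- train_crf(seqs, crf_hyper(max_iter = 20))
# decode the held-out documents, then score the spans:
coverage(pred, gold, "exact")
#> CRF exact coverage: 100.0%

idx <- build_index(indexed_documents(co$documents,
                                     annotate_corpus(store_documents(co$documents),
                                                     co$lexicons)))
r0 <- search_index(idx, "bkg0001")
r0$total                        #> 95 hits
tag_cloud(r0, "genes", 3)
#>     value count    weight
#> 1 GENE:10    14 1.0000000
#> 2 GENE:13    14 1.0000000
#> 3 GENE:11    13 0.9285714
search_index(idx, refine(query("bkg0001"), "genes", "GENE:13"))$total
#> 14   — exactly the count the tag cloud displayed
```

The numbers mean: on the trigger-separable synthetic preset the naive
Bayes classifier recovers the planted sentence labels on held-out
documents (98.5% here), the CRF recovers every planted trigger span with
exact boundaries, and the facet machinery honours its core contract —
clicking a tag-cloud entry yields exactly the advertised number of
documents.

## Scope notes

Dictionary-based tagging does not attempt entity normalisation to external
database identifiers; the part-of-speech feature variant is declared but
not implemented; and the synthetic generator aims at diagnostic
separability, not statistical mimicry of real corpora — see the methods
vignette (`vignettes/biofacet-methods.Rmd`) for the models, the design
decisions and what the shipped checks do and do not establish.
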